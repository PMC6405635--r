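#' Collapse probe-level rows to gene level
#'
#' Maps probe rows to genes and replaces the probes of each gene by their
#' arithmetic mean, the standard treatment of duplicated array probes.
#' Probes without a gene assignment are dropped: they carry no annotation
#' and would be invisible to every downstream, category-driven step.
#'
#' @param probes Probe-level log2 expression: a numeric matrix with probe ids
#'   as rownames, or a data frame whose first column is the probe id.
#' @param probe_map Data frame with columns `probe_id`, `gene_id`
#'   (many probes to one gene; empty or `NA` gene_id marks an unmapped
#'   probe). Each probe may map to at most one gene.
#' @param samples Sample annotation table (see [expression_dataset()]).
#' @return An [expression_dataset()] with one row per mapped gene, genes
#'   sorted by gene id.
#' @examples
#' m <- matrix(c(2, 4, 1, 3, 5, 7), 3, 2, byrow = FALSE,
#'             dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
#' map <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
#'                       gene_id = c("geneA", "geneA", "geneB"))
#' meta <- tibble::tibble(sample_id = c("s1", "s2"), cohort = "c1",
#'                        response = c("RD", "CR"))
#' expr_values(collapse_probes(m, map, meta))
#' @export
collapse_probes <- function(probes, probe_map, samples) {
  probes <- as_probe_matrix(probes)
  probe_map <- as_tibble(probe_map)
  if (!all(c("probe_id", "gene_id") %in% names(probe_map))) {
    abort("`probe_map` needs columns probe_id and gene_id.")
  }
  if (anyDuplicated(probe_map$probe_id)) {
    abort("`probe_map` assigns some probe to more than one gene.")
  }
  map <- probe_map %>%
    mutate(gene_id = as.character(.data$gene_id)) %>%
    filter(!is.na(.data$gene_id), .data$gene_id != "") %>%
    filter(.data$probe_id %in% rownames(probes))
  if (nrow(map) == 0) {
    abort("No probe in `probe_map` maps to a gene present in `probes`.")
  }
  x <- probes[map$probe_id, , drop = FALSE]
  collapsed <- rowsum(x, group = map$gene_id) /
    as.vector(table(map$gene_id)[sort(unique(map$gene_id))])
  collapsed <- collapsed[order(rownames(collapsed)), , drop = FALSE]
  expression_dataset(collapsed, samples)
}

as_probe_matrix <- function(probes) {
  if (is.matrix(probes)) {
    if (is.null(rownames(probes))) abort("Probe matrix needs rownames.")
    return(probes)
  }
  probes <- as.data.frame(probes)
  ids <- as.character(probes[[1]])
  m <- as.matrix(probes[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Batch-adjust an expression dataset across cohorts
#'
#' Within each cohort independently, each gene row is median-centered and
#' then divided by its within-cohort population standard deviation, the
#' standard median-center + z-score treatment of batch effects in merged
#' multi-cohort expression matrices. A gene that is constant within a cohort
#' becomes all-zero for that cohort's samples.
#'
#' @param ds An [expression_dataset()]. Every cohort must have at least two
#'   samples (the standard deviation is undefined otherwise).
#' @return An [expression_dataset()] of identical shape.
#' @export
batch_normalize <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  values <- expr_values(ds)
  info <- sample_info(ds)
  out <- values
  for (ch in unique(info$cohort)) {
    cols <- which(info$cohort == ch)
    if (length(cols) < 2) {
      abort(paste0("Cohort '", ch, "' has a single sample; the ",
                   "within-cohort standard deviation is undefined."))
    }
    x <- values[, cols, drop = FALSE]
    med <- apply(x, 1, median)
    s <- row_sd_pop(x)
    centered <- x - med
    z <- centered / ifelse(s == 0, 1, s)
    z[s == 0, ] <- 0
    out[, cols] <- z
  }
  expression_dataset(out, info)
}

#' Merge cohort datasets over their common genes
#'
#' Sample-wise concatenation over the intersection of gene ids, preserving
#' cohort labels and input sample order. Used to assemble a multi-cohort
#' discovery set from per-cohort gene-level datasets.
#'
#' @param ds_list A list of [expression_dataset()] objects (a single dataset
#'   is returned unchanged up to gene subsetting).
#' @return An [expression_dataset()].
#' @export
merge_cohorts <- function(ds_list) {
  if (inherits(ds_list, "expression_dataset")) ds_list <- list(ds_list)
  stopifnot(length(ds_list) >= 1,
            all(vapply(ds_list, inherits, TRUE, "expression_dataset")))
  genes <- Reduce(intersect, lapply(ds_list, gene_ids))
  if (length(genes) == 0) {
    abort("The merged datasets share no gene ids.")
  }
  values <- do.call(cbind, lapply(ds_list, function(d) {
    expr_values(d)[genes, , drop = FALSE]
  }))
  samples <- bind_rows(lapply(ds_list, sample_info))
  expression_dataset(values, samples)
}
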