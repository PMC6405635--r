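#' Gene-level expression dataset with sample annotations
#'
#' The substrate of every pipeline stage: a genes-by-samples matrix of
#' log2-scale expression values plus a per-sample annotation table giving
#' the cohort, the treatment-response label (`RD` = residual disease,
#' nonresponder; `CR` = complete response, responder) and the ER status
#' (`POS`, `NEG` or `UNKNOWN`).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids, unique),
#'   samples in columns (colnames = sample ids, unique). All values must be
#'   finite.
#' @param samples Data frame with columns `sample_id`, `cohort`, `response`
#'   (values `RD`/`CR`; `pCR` is accepted as an alias of `CR`) and optionally
#'   `er_status` (`POS`/`NEG`/`UNKNOWN`, default `UNKNOWN`). Must cover the
#'   matrix columns; rows are reordered to match the matrix.
#' @return An object of class `expression_dataset`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- tibble::tibble(sample_id = paste0("s", 1:4), cohort = "c1",
#'                        response = c("RD", "RD", "CR", "CR"))
#' ds <- expression_dataset(m, meta)
#' ds
#' @export
expression_dataset <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have rownames (gene ids) and colnames (sample ids).")
  }
  if (anyDuplicated(rownames(values))) {
    abort("Duplicated gene ids in `values` rownames.")
  }
  if (anyDuplicated(colnames(values))) {
    abort("Duplicated sample ids in `values` colnames.")
  }
  if (!all(is.finite(values))) {
    abort("`values` contains non-finite entries.")
  }
  samples <- as_tibble(samples)
  required <- c("sample_id", "cohort", "response")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("`samples` is missing column(s): ", cat_label(missing_cols)))
  }
  if (!"er_status" %in% names(samples)) samples$er_status <- "UNKNOWN"
  samples$response <- normalize_response(samples$response)
  samples$er_status <- toupper(as.character(samples$er_status))
  bad_er <- setdiff(unique(samples$er_status), c("POS", "NEG", "UNKNOWN"))
  if (length(bad_er) > 0) {
    abort(paste0("Invalid er_status value(s): ", cat_label(bad_er)))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("Duplicated sample ids in `samples`.")
  }
  missing_meta <- setdiff(colnames(values), samples$sample_id)
  if (length(missing_meta) > 0) {
    abort(paste0("Samples without metadata: ", cat_label(missing_meta)))
  }
  samples <- samples[match(colnames(values), samples$sample_id),
                     c("sample_id", "cohort", "response", "er_status",
                       setdiff(names(samples),
                               c("sample_id", "cohort", "response",
                                 "er_status")))]
  if (anyNA(samples$response) || anyNA(samples$cohort)) {
    abort("Every sample needs a response label and a cohort.")
  }
  structure(list(values = values, samples = samples),
            class = "expression_dataset")
}

normalize_response <- function(x) {
  x <- toupper(as.character(x))
  x[x == "PCR"] <- "CR"
  bad <- setdiff(unique(x[!is.na(x)]), c("RD", "CR"))
  if (length(bad) > 0) {
    abort(paste0("Invalid response label(s): ", cat_label(bad),
                 " (expected RD, CR or pCR)"))
  }
  x
}

#' @export
print.expression_dataset <- function(x, ...) {
  s <- x$samples
  cat("<expression_dataset> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  cohorts:  ", cat_label(sprintf("%s (%d)", names(table(s$cohort)),
                                        as.integer(table(s$cohort)))), "\n",
      sep = "")
  cat("  response: RD = ", sum(s$response == "RD"), ", CR = ",
      sum(s$response == "CR"), "\n", sep = "")
  invisible(x)
}

#' Accessors for expression datasets
#'
#' @param ds An `expression_dataset`.
#' @return `expr_values()` the genes-by-samples matrix; `sample_info()` the
#'   sample annotation tibble; `gene_ids()`/`sample_ids()` character vectors.
#' @name expression-accessors
NULL

#' @rdname expression-accessors
#' @export
expr_values <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  ds$values
}

#' @rdname expression-accessors
#' @export
sample_info <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  ds$samples
}

#' @rdname expression-accessors
#' @export
gene_ids <- function(ds) rownames(expr_values(ds))

#' @rdname expression-accessors
#' @export
sample_ids <- function(ds) colnames(expr_values(ds))

#' Subset an expression dataset
#'
#' @param ds An `expression_dataset`.
#' @param samples Character vector of sample ids (order preserved), or for
#'   `filter_samples()` an expression on the sample annotation columns.
#' @param genes Character vector of gene ids.
#' @return A new `expression_dataset`.
#' @export
subset_samples <- function(ds, samples) {
  missing <- setdiff(samples, sample_ids(ds))
  if (length(missing) > 0) {
    abort(paste0("Unknown sample id(s): ", cat_label(head(missing, 5))))
  }
  expression_dataset(ds$values[, samples, drop = FALSE],
                     ds$samples[match(samples, ds$samples$sample_id), ])
}

#' @rdname subset_samples
#' @export
filter_samples <- function(ds, samples) {
  keep <- eval_tidy(enquo(samples), data = ds$samples)
  subset_samples(ds, ds$samples$sample_id[keep])
}

#' @rdname subset_samples
#' @export
subset_genes <- function(ds, genes) {
  missing <- setdiff(genes, gene_ids(ds))
  if (length(missing) > 0) {
    abort(paste0("Unknown gene id(s): ", cat_label(head(missing, 5))))
  }
  expression_dataset(ds$values[genes, , drop = FALSE], ds$samples)
}

#' @export
as_tibble.expression_dataset <- function(x, ...) {
  bind_cols(tibble(gene_id = rownames(x$values)),
            as_tibble(x$values, .name_repair = "minimal"))
}

# counts of samples per response class
response_counts <- function(ds) {
  s <- sample_info(ds)
  c(CR = sum(s$response == "CR"), RD = sum(s$response == "RD"))
}
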