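#' Specification of the synthetic multi-cohort benchmark
#'
#' Describes a multi-cohort expression study with planted ground truth:
#' several discovery cohorts plus a validation cohort, class-imbalanced
#' RD/CR labels, per-cohort additive batch offsets, functional categories
#' of realistic sizes, and a planted subset of differentially expressed
#' signature genes per category. Defaults mirror the reference study's
#' four-cohort ER+ discovery design: ~4,000 genes, category sizes
#' apoptosis 186, cell adhesion 56, cell cycle 84, DNA damage & repair 56,
#' immune response 104, phosphorylation 77, 30 planted genes per category.
#'
#' @param cohort_sizes Integer vector of discovery-cohort sizes.
#' @param validation_sizes Integer vector of validation-cohort sizes.
#' @param regime `"er_pos"` or `"er_neg"`; sets the ER label and the
#'   admissible RD:CR imbalance range (3-10 for ER+, 0.7-1.4 for ER-).
#' @param rd_cr_ratio RD:CR ratio in every cohort (default 4 for ER+,
#'   1 for ER-). Must lie in the regime's range.
#' @param n_genes Total number of genes.
#' @param categories Named integer vector of category sizes.
#' @param planted_per_category Number of planted (truly differential)
#'   signature genes per category.
#' @param effect_size Mean RD-CR shift of a planted gene, in units of the
#'   within-class standard deviation.
#' @param decoy_effect_size RD-CR shift of the non-planted category members
#'   ("decoys"), in within-class SD units. Functional categories relevant to
#'   treatment response are enriched in mildly responsive genes, which is
#'   what puts them in the differential-expression pool in the first place;
#'   decoys model that mild, non-signature-grade signal. Default
#'   `0.25 * effect_size`, so a null benchmark (`effect_size = 0`) stays
#'   fully null. Genes outside every category are class-independent.
#' @param batch_offset_sd SD of the per-cohort, per-gene additive batch
#'   offset.
#' @param noise_sd Within-class SD of a gene (log2 scale).
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline
#'   log2 expression.
#' @return A `benchmark_spec` list.
#' @export
benchmark_spec <- function(cohort_sizes = c(120, 90, 60, 150),
                           validation_sizes = 120,
                           regime = c("er_pos", "er_neg"),
                           rd_cr_ratio = NULL,
                           n_genes = 4000,
                           categories = c(apoptosis = 186,
                                          cell_adhesion = 56,
                                          cell_cycle = 84,
                                          dna_damage_repair = 56,
                                          immune_response = 104,
                                          phosphorylation = 77),
                           planted_per_category = 30,
                           effect_size = 1.5,
                           decoy_effect_size = NULL,
                           batch_offset_sd = 1,
                           noise_sd = 1,
                           baseline_mean = 8,
                           baseline_sd = 2) {
  regime <- arg_match(regime)
  if (is.null(rd_cr_ratio)) {
    rd_cr_ratio <- if (regime == "er_pos") 4 else 1
  }
  range_ok <- if (regime == "er_pos") {
    rd_cr_ratio >= 3 && rd_cr_ratio <= 10
  } else {
    rd_cr_ratio >= 0.7 && rd_cr_ratio <= 1.4
  }
  if (!range_ok) {
    abort(sprintf(
      "rd_cr_ratio %.2f is outside the %s regime range.", rd_cr_ratio,
      regime))
  }
  if (is.null(names(categories)) || any(names(categories) == "")) {
    abort("`categories` must be a named vector of sizes.")
  }
  categories <- setNames(as.integer(categories), names(categories))
  if (any(planted_per_category > categories)) {
    abort("planted_per_category exceeds a category size.")
  }
  if (sum(categories) > n_genes) {
    abort("Category sizes exceed the total gene count.")
  }
  if (is.null(decoy_effect_size)) decoy_effect_size <- 0.25 * effect_size
  if (decoy_effect_size > effect_size) {
    abort("decoy_effect_size must not exceed effect_size.")
  }
  structure(list(cohort_sizes = as.integer(cohort_sizes),
                 validation_sizes = as.integer(validation_sizes),
                 regime = regime, rd_cr_ratio = rd_cr_ratio,
                 n_genes = as.integer(n_genes),
                 categories = categories,
                 planted_per_category = as.integer(planted_per_category),
                 effect_size = effect_size,
                 decoy_effect_size = decoy_effect_size,
                 batch_offset_sd = batch_offset_sd, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd),
            class = "benchmark_spec")
}

#' Generate a synthetic benchmark with planted ground truth
#'
#' Unannotated background genes are class-independent Gaussians on the log2
#' scale; planted genes are shifted between RD and CR by `effect_size`
#' within-class SDs (random direction per gene); category decoy genes are
#' shifted by the much smaller `decoy_effect_size`; every cohort adds a
#' per-gene offset drawn from `Normal(0, batch_offset_sd)`. The annotation
#' table assigns each category its planted genes plus decoy genes drawn
#' from the non-planted background, so some decoys belong to several
#' categories (exercising the many-to-many partition). Fully deterministic
#' under the master seed.
#'
#' @param spec A [benchmark_spec()].
#' @param seed Master seed.
#' @return An `mss_benchmark` list: `dataset` (all cohorts, unnormalized),
#'   `annotation` (tibble `gene_id`, `category`), `truth` (planted genes
#'   per category, per-gene shift directions, batch offsets,
#'   discovery/validation cohort ids and the spec).
#' @export
generate_benchmark <- function(spec = benchmark_spec(), seed = 1) {
  stopifnot(inherits(spec, "benchmark_spec"))
  with_seed(seed, {
    gene_id <- sprintf("G%05d", seq_len(spec$n_genes))
    cats <- names(spec$categories)
    planted_all <- sample(gene_id, spec$planted_per_category * length(cats))
    planted <- split(planted_all,
                     rep(cats, each = spec$planted_per_category))
    planted <- lapply(planted, sort)
    non_planted <- setdiff(gene_id, planted_all)
    annotation <- bind_rows(lapply(cats, function(ct) {
      decoys <- sample(non_planted,
                       spec$categories[[ct]] - spec$planted_per_category)
      tibble(gene_id = sort(c(planted[[ct]], decoys)), category = ct)
    })) %>% arrange(.data$category, .data$gene_id)
    direction <- setNames(sample(c(-1, 1), spec$n_genes, replace = TRUE),
                          gene_id)
    effect <- setNames(rep(0, spec$n_genes), gene_id)
    effect[planted_all] <- spec$effect_size * spec$noise_sd *
      direction[planted_all]
    decoy_genes <- setdiff(unique(annotation$gene_id), planted_all)
    effect[decoy_genes] <- spec$decoy_effect_size * spec$noise_sd *
      direction[decoy_genes]

    n_disc <- length(spec$cohort_sizes)
    cohort_names <- c(sprintf("discovery%d", seq_len(n_disc)),
                      sprintf("validation%d",
                              seq_along(spec$validation_sizes)))
    sizes <- c(spec$cohort_sizes, spec$validation_sizes)
    baseline <- rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
    batch <- matrix(rnorm(spec$n_genes * length(sizes), 0,
                          spec$batch_offset_sd),
                    spec$n_genes, length(sizes),
                    dimnames = list(gene_id, cohort_names))
    values <- NULL
    samples <- list()
    offset <- 0
    for (ci in seq_along(sizes)) {
      n <- sizes[ci]
      n_rd <- round(n * spec$rd_cr_ratio / (1 + spec$rd_cr_ratio))
      n_cr <- n - n_rd
      response <- sample(c(rep("RD", n_rd), rep("CR", n_cr)))
      ids <- sprintf("S%05d", offset + seq_len(n))
      offset <- offset + n
      # RD shifted by +effect/2, CR by -effect/2: class separation = effect
      shift <- outer(effect / 2, ifelse(response == "RD", 1, -1))
      x <- baseline + batch[, ci] + shift +
        matrix(rnorm(spec$n_genes * n, 0, spec$noise_sd), spec$n_genes, n)
      colnames(x) <- ids
      rownames(x) <- gene_id
      values <- cbind(values, x)
      samples[[ci]] <- tibble(
        sample_id = ids, cohort = cohort_names[ci], response = response,
        er_status = if (spec$regime == "er_pos") "POS" else "NEG")
    }
    dataset <- expression_dataset(values, bind_rows(samples))
    structure(list(
      dataset = dataset,
      annotation = annotation,
      truth = list(planted = planted, direction = direction,
                   batch_offsets = batch, spec = spec,
                   discovery_cohorts = cohort_names[seq_len(n_disc)],
                   validation_cohorts = cohort_names[-seq_len(n_disc)])),
      class = "mss_benchmark")
  })
}

#' @export
print.mss_benchmark <- function(x, ...) {
  cat("<mss_benchmark>\n")
  print(x$dataset)
  cat("  categories: ", cat_label(names(x$truth$spec$categories)), "\n",
      sep = "")
  cat("  planted:    ", x$truth$spec$planted_per_category,
      " genes/category, effect ", x$truth$spec$effect_size, " SD\n",
      sep = "")
  invisible(x)
}

#' Split a benchmark into discovery and validation datasets
#'
#' @param benchmark An [generate_benchmark()] result.
#' @return List with `discovery` and `validation` [expression_dataset()]s.
#' @export
split_benchmark <- function(benchmark) {
  stopifnot(inherits(benchmark, "mss_benchmark"))
  ds <- benchmark$dataset
  info <- sample_info(ds)
  list(discovery = subset_samples(
         ds, info$sample_id[info$cohort %in%
                              benchmark$truth$discovery_cohorts]),
       validation = subset_samples(
         ds, info$sample_id[info$cohort %in%
                              benchmark$truth$validation_cohorts]))
}

#' Fraction of planted signature genes recovered
#'
#' @param truth The `truth` element of a benchmark (or the benchmark).
#' @param signatures An `mss_signature` tibble.
#' @return Tibble `category`, `n_planted`, `n_recovered`, `recovered_frac`.
#' @export
recovery_metrics <- function(truth, signatures) {
  if (inherits(truth, "mss_benchmark")) truth <- truth$truth
  cats <- unique(signatures$category)
  unknown <- setdiff(cats, names(truth$planted))
  if (length(unknown) > 0) {
    abort(paste0("Unknown categor(ies): ", cat_label(unknown)))
  }
  bind_rows(lapply(cats, function(ct) {
    planted <- truth$planted[[ct]]
    found <- unique(signatures$gene_id[signatures$category == ct])
    tibble(category = ct, n_planted = length(planted),
           n_recovered = length(intersect(found, planted)),
           recovered_frac = length(intersect(found, planted)) /
             length(planted))
  }))
}

#' Write a benchmark to disk as plain-text files
#'
#' Writes `expr.tsv` (gene-level matrix), `meta.tsv` (sample metadata),
#' `annotation.tsv` and `truth.json` into `dir`.
#'
#' @param benchmark An [generate_benchmark()] result.
#' @param dir Output directory (created if needed).
#' @export
write_benchmark <- function(benchmark, dir) {
  stopifnot(inherits(benchmark, "mss_benchmark"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_tsv(benchmark$dataset, file.path(dir, "expr.tsv"))
  write_sample_metadata(benchmark$dataset, file.path(dir, "meta.tsv"))
  readr::write_tsv(benchmark$annotation, file.path(dir, "annotation.tsv"),
                   progress = FALSE)
  truth <- benchmark$truth
  jsonlite::write_json(
    list(planted = truth$planted,
         discovery_cohorts = truth$discovery_cohorts,
         validation_cohorts = truth$validation_cohorts,
         spec = unclass(truth$spec)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
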