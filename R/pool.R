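#' Differential-expression gene pool by subsampled t-tests
#'
#' The original pool rule: a gene enters the pool if a two-sample Welch
#' t-test between a random draw of `n_resp` responders (CR) and `n_nonresp`
#' nonresponders (RD) yields p < `alpha` in at least `min_hits` of `iters`
#' independent draws. Draws are without replacement within an iteration.
#'
#' @param ds A normalized [expression_dataset()] with both response classes.
#' @param n_resp,n_nonresp Number of CR / RD samples drawn per iteration.
#'   The CR:RD draw ratio can be relaxed (30:70 up to 30:120) without
#'   changing downstream behaviour.
#' @param iters Number of random draws.
#' @param alpha Per-test significance threshold.
#' @param min_hits Minimum number of draws with p < `alpha` for a gene to
#'   enter the pool.
#' @param seed Seed for the draws (`NULL` uses the current RNG state).
#' @return A `gene_pool` tibble with columns `gene_id`, `pass_count`,
#'   `p_value` (median p over the draws), ordered by pass count, then p,
#'   then gene id. The attribute `all_stats` records pass counts for every
#'   gene.
#' @export
subsample_de_pool <- function(ds, n_resp = 30, n_nonresp = 70, iters = 100,
                              alpha = 0.05, min_hits = 80, seed = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  cnt <- response_counts(ds)
  if (cnt["CR"] < n_resp || cnt["RD"] < n_nonresp) {
    abort(sprintf(
      "Need >= %d CR and >= %d RD samples; have %d CR and %d RD.",
      n_resp, n_nonresp, cnt["CR"], cnt["RD"]))
  }
  values <- expr_values(ds)
  info <- sample_info(ds)
  cr_cols <- which(info$response == "CR")
  rd_cols <- which(info$response == "RD")
  run <- function() {
    pmat <- matrix(NA_real_, nrow(values), iters)
    for (it in seq_len(iters)) {
      a <- sample(cr_cols, n_resp)
      b <- sample(rd_cols, n_nonresp)
      pmat[, it] <- row_welch_p(values, a, b)
    }
    pmat
  }
  pmat <- if (is.null(seed)) run() else with_seed(seed, run())
  pass <- rowSums(pmat < alpha)
  stats <- tibble(gene_id = rownames(values),
                  pass_count = as.integer(pass),
                  p_value = apply(pmat, 1, median)) %>%
    arrange(dplyr::desc(.data$pass_count), .data$p_value, .data$gene_id)
  pool <- filter(stats, .data$pass_count >= min_hits)
  new_gene_pool(pool, mode = "subsample", all_stats = stats,
                params = list(n_resp = n_resp, n_nonresp = n_nonresp,
                              iters = iters, alpha = alpha,
                              min_hits = min_hits))
}

#' Differential-expression gene pool by top-k t-test ranking
#'
#' The optimized pool rule: one two-sample Welch t-test per gene on all
#' samples, keeping the `k` smallest p-values (ties broken by gene id).
#' Selecting the 300-500 most significant genes serves the same purpose as
#' the subsampled rule while removing its hyperparameters.
#'
#' @param ds A normalized [expression_dataset()] with both response classes.
#' @param k Pool size.
#' @return A `gene_pool` tibble with columns `gene_id`, `pass_count`
#'   (`NA` for this rule), `p_value`.
#' @export
top_k_de_pool <- function(ds, k = 500) {
  stopifnot(inherits(ds, "expression_dataset"))
  cnt <- response_counts(ds)
  if (any(cnt == 0)) abort("Both response classes must be present.")
  values <- expr_values(ds)
  info <- sample_info(ds)
  p <- row_welch_p(values, which(info$response == "CR"),
                   which(info$response == "RD"))
  if (k > nrow(values)) {
    abort(sprintf("k = %d exceeds the %d testable genes.", k, nrow(values)))
  }
  stats <- tibble(gene_id = rownames(values), pass_count = NA_integer_,
                  p_value = p) %>%
    arrange(.data$p_value, .data$gene_id)
  new_gene_pool(stats[seq_len(k), ], mode = "topk", all_stats = stats,
                params = list(k = k))
}

new_gene_pool <- function(tab, mode, all_stats = NULL, params = list()) {
  structure(tab, class = c("gene_pool", class(tibble())),
            mode = mode, all_stats = all_stats, params = params)
}

#' Partition a gene pool into functional-category subpools
#'
#' Assigns pool genes to annotation categories "with replacement": a gene
#' annotated to several categories appears in every matching subpool.
#' Unannotated pool genes appear in none.
#'
#' @param pool A `gene_pool` tibble (or a character vector of gene ids).
#' @param annotation Gene-to-category table with columns `gene_id`,
#'   `category` (many-to-many; repeated gene ids allowed).
#' @param categories Categories to keep (default: all categories present in
#'   `annotation`, sorted).
#' @param signature_size Minimum subpool size; a category with fewer pool
#'   genes cannot seed a random gene set of that size and raises an error.
#' @return A `go_subpools` tibble with columns `category`, `gene_id`, genes
#'   sorted within category.
#' @export
partition_by_go <- function(pool, annotation, categories = NULL,
                            signature_size = 30) {
  genes <- if (is.character(pool)) pool else pool$gene_id
  annotation <- as_tibble(annotation)
  if (nrow(annotation) == 0) abort("`annotation` is empty.")
  if (is.null(categories)) categories <- sort(unique(annotation$category))
  sub <- annotation %>%
    filter(.data$category %in% categories, .data$gene_id %in% genes) %>%
    distinct(.data$category, .data$gene_id) %>%
    arrange(.data$category, .data$gene_id)
  sizes <- table(factor(sub$category, levels = categories))
  short <- names(sizes)[sizes < signature_size]
  if (length(short) > 0) {
    abort(paste0(
      "Categories with fewer than ", signature_size, " pool genes ",
      "(cannot sample a ", signature_size, "-gene RGS): ",
      cat_label(short)))
  }
  structure(sub, class = c("go_subpools", class(tibble())),
            signature_size = signature_size)
}

#' @export
print.gene_pool <- function(x, ...) {
  cat("<gene_pool> ", nrow(x), " genes (mode: ", attr(x, "mode"), ")\n",
      sep = "")
  NextMethod()
}

# genes of one category from a subpools table (sorted by gene id)
subpool_genes <- function(subpools, category) {
  if (is.character(subpools)) return(sort(subpools))
  g <- subpools$gene_id[subpools$category == category]
  if (length(g) == 0) {
    abort(paste0("No genes for category '", category, "'."))
  }
  sort(g)
}
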