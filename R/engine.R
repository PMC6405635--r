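#' Draw one random gene set (RGS)
#'
#' Uniform draw without replacement of `size` genes from a subpool.
#'
#' @param subpool Character vector of gene ids, or a one-category slice of a
#'   [partition_by_go()] table.
#' @param size Gene-set size (30 in the reference configuration).
#' @param seed Seed (`NULL` uses the current RNG state).
#' @return Character vector of `size` distinct gene ids.
#' @export
sample_rgs <- function(subpool, size = 30, seed = NULL) {
  genes <- if (is.character(subpool)) subpool else unique(subpool$gene_id)
  if (length(genes) < size) {
    abort(sprintf("Subpool has %d genes; cannot draw %d without replacement.",
                  length(genes), size))
  }
  draw <- function() sample(genes, size)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Draw a list of random patient sets (RPS)
#'
#' Each random patient set holds `n_cr` responders and `n_rd` nonresponders
#' drawn without replacement (the reference configuration is 25 CR / 55 RD,
#' repeated 40 times; the CR:RD ratio should stay around 1:2 to 1:5). If the
#' dataset has fewer samples than requested, both counts are scaled down
#' proportionally, preserving the ratio.
#'
#' @param ds An [expression_dataset()].
#' @param n_cr,n_rd Samples per class per set.
#' @param n_sets Number of sets.
#' @param seed Seed (`NULL` uses the current RNG state).
#' @return An `mss_rps_list`: a list of `n_sets` elements, each with
#'   character vectors `cr` and `rd`.
#' @export
sample_rps_list <- function(ds, n_cr = 25, n_rd = 55, n_sets = 40,
                            seed = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  cnt <- response_counts(ds)
  f <- min(1, cnt["CR"] / n_cr, cnt["RD"] / n_rd)
  use_cr <- floor(n_cr * f)
  use_rd <- floor(n_rd * f)
  if (use_cr < 2 || use_rd < 2) {
    abort(sprintf(
      "Too few samples for patient sets: scaled draw would be %d CR / %d RD.",
      use_cr, use_rd))
  }
  if (f < 1) {
    inform(sprintf(
      "Patient-set draw scaled down from %d CR / %d RD to %d CR / %d RD.",
      n_cr, n_rd, use_cr, use_rd))
  }
  info <- sample_info(ds)
  cr_ids <- info$sample_id[info$response == "CR"]
  rd_ids <- info$sample_id[info$response == "RD"]
  draw <- function() {
    lapply(seq_len(n_sets), function(i) {
      list(cr = sample(cr_ids, use_cr), rd = sample(rd_ids, use_rd))
    })
  }
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(out, class = "mss_rps_list", n_cr = use_cr, n_rd = use_rd)
}

# 0-based column-index matrices for an RPS list, relative to `ids`
rps_index_matrices <- function(rps_list, ids) {
  n_cr <- attr(rps_list, "n_cr")
  n_rd <- attr(rps_list, "n_rd")
  cr <- vapply(rps_list, function(s) match(s$cr, ids) - 1L, integer(n_cr))
  rd <- vapply(rps_list, function(s) match(s$rd, ids) - 1L, integer(n_rd))
  list(cr = matrix(as.integer(cr), n_cr, length(rps_list)),
       rd = matrix(as.integer(rd), n_rd, length(rps_list)))
}

#' Score a random gene set by cluster-label enrichment
#'
#' For each random patient set, the samples are clustered into two groups by
#' K-means (k = 2, Euclidean) on the gene set's expression vectors, and a
#' two-sided Fisher exact test on the 2x2 cluster-by-response table measures
#' how strongly the clustering enriches responders or nonresponders. If a
#' cluster is empty the test contributes p = 1; every p is floored at
#' 1e-300. The enrichment score is the reciprocal of the mean p over all
#' patient sets.
#'
#' @param rgs Character vector of gene ids (one random gene set).
#' @param rps_list An [sample_rps_list()] result.
#' @param ds The [expression_dataset()] the indices refer to.
#' @param seed Seed for the clustering restarts.
#' @param nrestart,maxit K-means restarts (k-means++ initialised) and
#'   iteration cap.
#' @param fuzzy Use fuzzy c-means (fuzzifier 2, hard assignment by maximum
#'   membership) instead of hard K-means.
#' @return An `mss_scored_rgs` list: `genes`, `fisher_ps` (one p per patient
#'   set), `enrichment_score`.
#' @export
score_rgs <- function(rgs, rps_list, ds, seed = 1, nrestart = 2, maxit = 25,
                      fuzzy = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"))
  missing <- setdiff(rgs, gene_ids(ds))
  if (length(missing) > 0) {
    abort(paste0("Gene(s) absent from the dataset: ", cat_label(missing)))
  }
  expr <- expr_values(ds)[rgs, , drop = FALSE]
  idx <- rps_index_matrices(rps_list, sample_ids(ds))
  res <- cpp_score_given(expr,
                         matrix(seq_along(rgs) - 1L, ncol = 1),
                         idx$cr, idx$rd, as.double(seed),
                         as.integer(nrestart), as.integer(maxit),
                         isTRUE(fuzzy), TRUE)
  structure(list(genes = rgs, fisher_ps = as.vector(res$p_mat),
                 enrichment_score = res$scores[1]),
            class = "mss_scored_rgs")
}

# -- signature construction helpers -----------------------------------------

# rank genes over a gilded collection; genes = subpool gene ids (sorted),
# gilded_idx = 0-based gene indices (size x K), scores = per-set scores
signature_from_gilded <- function(genes, gilded_idx, scores, signature_size,
                                  category, list_id = 1L) {
  S <- length(genes)
  flat <- as.vector(gilded_idx) + 1L
  freq <- tabulate(flat, nbins = S)
  sumsc <- rep(0, S)
  agg <- rowsum(rep(scores, each = nrow(gilded_idx)), group = flat)
  sumsc[as.integer(rownames(agg))] <- agg[, 1]
  ord <- order(-freq, -sumsc, genes)
  keep <- ord[seq_len(signature_size)]
  new_signature_tibble(tibble(
    category = category, list_id = as.integer(list_id),
    gene_id = genes[keep], frequency = as.integer(freq[keep]),
    rank = seq_len(signature_size)))
}

new_signature_tibble <- function(tab, config = NULL, ...) {
  if (!"list_id" %in% names(tab)) tab$list_id <- 1L
  tab <- as_tibble(tab)[, c("category", "list_id", "gene_id", "frequency",
                            "rank")]
  structure(tab, class = c("mss_signature", class(tibble())),
            config = config, ...)
}

#' @export
print.mss_signature <- function(x, ...) {
  v <- distinct(as_tibble(x)[, c("category", "list_id")])
  cat("<mss_signature> ", nrow(v), " voter(s), ",
      max(x$rank), " genes each\n", sep = "")
  NextMethod()
}

#' @export
tidy.mss_signature <- function(x, ...) as_tibble(x)

#' @export
glance.mss_signature <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(n_voters = nrow(distinct(as_tibble(x)[, c("category", "list_id")])),
         signature_size = max(x$rank),
         mode = cfg$mode %||% NA_character_,
         n_scored = cfg$n_scored %||% NA_real_,
         seed = cfg$seed %||% NA_real_)
}

engine_inputs <- function(ds, subpool, size, n_cr, n_rd, n_sets, seed) {
  genes <- if (is.character(subpool)) sort(unique(subpool)) else
    sort(unique(subpool$gene_id))
  if (length(genes) < size) {
    abort(sprintf("Subpool has %d genes; need at least %d.",
                  length(genes), size))
  }
  missing <- setdiff(genes, gene_ids(ds))
  if (length(missing) > 0) {
    abort(paste0("Subpool gene(s) absent from the dataset: ",
                 cat_label(head(missing, 5))))
  }
  rps <- sample_rps_list(ds, n_cr = n_cr, n_rd = n_rd, n_sets = n_sets,
                         seed = derive_seed(seed, 1))
  idx <- rps_index_matrices(rps, sample_ids(ds))
  list(genes = genes, expr = expr_values(ds)[genes, , drop = FALSE],
       rps = rps, idx = idx)
}

#' Full-search signature discovery for one subpool
#'
#' Samples `n_rgs` random gene sets from the subpool, scores each against a
#' fixed list of random patient sets, keeps the `n_gilded` highest-scoring
#' ("gilded") sets, and returns the `signature_size` most frequent genes
#' across them (ties broken by the summed enrichment score of the gilded
#' sets containing the gene, then by gene id).
#'
#' @inheritParams score_rgs
#' @param ds A normalized [expression_dataset()].
#' @param subpool Character vector of gene ids or a one-category slice of a
#'   [partition_by_go()] table.
#' @param n_rgs Number of random gene sets to score (the reference
#'   configuration uses 1,000,000; 20,000 suffices at desk scale).
#' @param n_gilded Number of top-scoring sets kept (1,000-3,000 behave
#'   equivalently in the reference configuration).
#' @param signature_size Genes per signature.
#' @param n_cr,n_rd,n_sets Random patient-set configuration.
#' @param category Category label stored in the result.
#' @param seed Master seed; the patient-set draw and every gene-set stream
#'   are derived from it, so results are reproducible bit-for-bit and
#'   independent of execution order.
#' @return An `mss_signature` tibble (`category`, `list_id`, `gene_id`,
#'   `frequency`, `rank`) with the run configuration in `attr(, "config")`.
#' @export
run_mss_full <- function(ds, subpool, n_rgs = 1e6, n_gilded = 3000,
                         signature_size = 30, n_cr = 25, n_rd = 55,
                         n_sets = 40, seed = 1, nrestart = 2, maxit = 25,
                         fuzzy = FALSE, category = NULL) {
  if (n_gilded > n_rgs) {
    abort(sprintf("n_gilded (%d) exceeds n_rgs (%d).", n_gilded, n_rgs))
  }
  if (is.null(category)) category <- infer_category(subpool)
  inp <- engine_inputs(ds, subpool, signature_size, n_cr, n_rd, n_sets, seed)
  res <- cpp_run_full(inp$expr, as.integer(signature_size),
                      as.integer(n_rgs), inp$idx$cr, inp$idx$rd,
                      as.double(derive_seed(seed, 2)), as.integer(nrestart),
                      as.integer(maxit), isTRUE(fuzzy))
  gilded <- order(-res$scores, seq_along(res$scores))[seq_len(n_gilded)]
  sig <- signature_from_gilded(inp$genes,
                               res$gene_idx[, gilded, drop = FALSE],
                               res$scores[gilded], signature_size, category)
  attr(sig, "config") <- list(mode = "full", seed = seed, n_scored = n_rgs,
                              n_gilded = n_gilded, n_cr = n_cr, n_rd = n_rd,
                              n_sets = n_sets, signature_size = signature_size,
                              category = category)
  attr(sig, "gilded_scores") <- res$scores[gilded]
  sig
}

infer_category <- function(subpool) {
  if (!is.character(subpool) && "category" %in% names(subpool)) {
    u <- unique(subpool$category)
    if (length(u) == 1) return(u)
  }
  "subpool"
}

#' Early-stopping signature discovery for one subpool
#'
#' Identical scoring loop to [run_mss_full()], but a running gilded set of
#' size `max(gilded_min, round(gilded_frac * i))` is maintained as the
#' iterations proceed, and the run terminates once the running list of the
#' `signature_size` most frequent gilded genes is unchanged for `T`
#' consecutive iterations (checked after a warm-up). T in 100-500 trades
#' little robustness for a large reduction in scored gene sets.
#'
#' @inheritParams run_mss_full
#' @param T Stopping criterion: consecutive iterations without a change in
#'   the running top-gene list.
#' @param warmup Iterations before stability tracking starts.
#' @param cap Hard iteration cap; if the list never stabilises the
#'   best-so-far signature is returned with `attr(, "config")$converged =
#'   FALSE` and a warning.
#' @param gilded_min,gilded_frac Running gilded-set size rule.
#' @return An `mss_signature`; `attr(, "config")$n_scored` records the
#'   iteration count at stop.
#' @export
run_mss_early_stop <- function(ds, subpool, T = 300, warmup = 500,
                               cap = 1e6, gilded_min = 50,
                               gilded_frac = 0.003, signature_size = 30,
                               n_cr = 25, n_rd = 55, n_sets = 40, seed = 1,
                               nrestart = 2, maxit = 25, fuzzy = FALSE,
                               category = NULL) {
  stopifnot(T >= 1)
  if (is.null(category)) category <- infer_category(subpool)
  inp <- engine_inputs(ds, subpool, signature_size, n_cr, n_rd, n_sets, seed)
  res <- cpp_run_early_stop(inp$expr, as.integer(signature_size),
                            as.integer(signature_size), as.integer(T),
                            as.integer(warmup), as.integer(cap),
                            as.integer(gilded_min), as.double(gilded_frac),
                            inp$idx$cr, inp$idx$rd,
                            as.double(derive_seed(seed, 2)),
                            as.integer(nrestart), as.integer(maxit),
                            isTRUE(fuzzy))
  if (!res$converged) {
    warn(sprintf(
      "Early stopping did not converge within %d iterations (T = %d).",
      as.integer(cap), T))
  }
  sig <- signature_from_gilded(inp$genes, res$gilded_idx, res$gilded_scores,
                               signature_size, category)
  attr(sig, "config") <- list(mode = "earlystop", seed = seed,
                              n_scored = res$stopped_at, T = T,
                              warmup = warmup, cap = cap,
                              converged = res$converged,
                              n_gilded = ncol(res$gilded_idx), n_cr = n_cr,
                              n_rd = n_rd, n_sets = n_sets,
                              signature_size = signature_size,
                              category = category)
  sig
}

#' Ensemble signature discovery for one subpool
#'
#' Runs `n_lists` independent early-stopping discoveries with a low
#' stopping threshold (T around 30) and distinct child seeds. Each
#' resulting gene list is one independent voter for the downstream
#' predictor.
#'
#' @inheritParams run_mss_early_stop
#' @param n_lists Number of independent lists.
#' @return An `mss_signature` tibble with one `list_id` per ensemble member.
#' @export
run_mss_ensemble <- function(ds, subpool, T = 30, n_lists = 5, warmup = 500,
                             cap = 1e6, gilded_min = 50, gilded_frac = 0.003,
                             signature_size = 30, n_cr = 25, n_rd = 55,
                             n_sets = 40, seed = 1, nrestart = 2, maxit = 25,
                             fuzzy = FALSE, category = NULL) {
  if (is.null(category)) category <- infer_category(subpool)
  sigs <- lapply(seq_len(n_lists), function(k) {
    s <- run_mss_early_stop(ds, subpool, T = T, warmup = warmup, cap = cap,
                            gilded_min = gilded_min,
                            gilded_frac = gilded_frac,
                            signature_size = signature_size, n_cr = n_cr,
                            n_rd = n_rd, n_sets = n_sets,
                            seed = derive_seed(seed, 100 + k),
                            nrestart = nrestart, maxit = maxit,
                            fuzzy = fuzzy, category = category)
    s$list_id <- as.integer(k)
    s
  })
  out <- new_signature_tibble(bind_rows(lapply(sigs, as_tibble)))
  attr(out, "config") <- list(mode = "ensemble", seed = seed, T = T,
                              n_lists = n_lists,
                              n_scored = sum(vapply(sigs, function(s)
                                attr(s, "config")$n_scored, 0)),
                              signature_size = signature_size,
                              category = category)
  out
}

#' Discover signatures for every category of a dataset
#'
#' End-to-end discovery: build the differential-expression pool, partition
#' it into category subpools, and run the chosen discovery mode on each.
#'
#' @inheritParams run_mss_full
#' @param annotation Gene-to-category table (columns `gene_id`, `category`).
#' @param categories Categories to discover (default: all annotated).
#' @param pool_mode `"topk"` (one t-test per gene, smallest `k` p-values;
#'   the optimized rule) or `"subsample"` (the subsampled t-test rule).
#' @param k Pool size for `pool_mode = "topk"`.
#' @param mode Discovery mode: `"full"`, `"earlystop"` or `"ensemble"`.
#' @param T Stopping threshold for the early-stop / ensemble modes.
#' @param n_lists Ensemble size for `mode = "ensemble"`.
#' @param ... Further arguments passed to the per-subpool engine.
#' @return An `mss_signature` tibble covering all categories.
#' @export
discover_signatures <- function(ds, annotation, categories = NULL,
                                pool_mode = c("topk", "subsample"), k = 500,
                                mode = c("full", "earlystop", "ensemble"),
                                n_rgs = 20000, n_gilded = 3000, T = 300,
                                n_lists = 5, signature_size = 30, seed = 1,
                                ...) {
  pool_mode <- arg_match(pool_mode)
  mode <- arg_match(mode)
  pool <- switch(pool_mode,
                 topk = top_k_de_pool(ds, k = k),
                 subsample = subsample_de_pool(ds,
                                               seed = derive_seed(seed, 9)))
  subpools <- partition_by_go(pool, annotation, categories = categories,
                              signature_size = signature_size)
  cats <- sort(unique(subpools$category))
  sigs <- lapply(cats, function(ct) {
    genes <- subpool_genes(subpools, ct)
    cat_seed <- derive_seed(seed, 1000 + match(ct, cats))
    switch(mode,
           full = run_mss_full(ds, genes, n_rgs = n_rgs,
                               n_gilded = n_gilded,
                               signature_size = signature_size,
                               seed = cat_seed, category = ct, ...),
           earlystop = run_mss_early_stop(ds, genes, T = T,
                                          signature_size = signature_size,
                                          seed = cat_seed, category = ct,
                                          ...),
           ensemble = run_mss_ensemble(ds, genes, T = min(T, 30),
                                       n_lists = n_lists,
                                       signature_size = signature_size,
                                       seed = cat_seed, category = ct, ...))
  })
  out <- new_signature_tibble(bind_rows(lapply(sigs, as_tibble)))
  attr(out, "config") <- list(mode = mode, pool_mode = pool_mode, k = k,
                              seed = seed, n_rgs = n_rgs, T = T,
                              n_lists = n_lists,
                              signature_size = signature_size,
                              n_scored = sum(vapply(sigs, function(s)
                                attr(s, "config")$n_scored, 0)),
                              categories = cats)
  attr(out, "per_category") <- setNames(lapply(sigs, attr, "config"), cats)
  out
}

#' Compare two signature sets
#'
#' @param a,b `mss_signature` tibbles sharing categories.
#' @return Tibble with per-category `overlap` (shared genes) and `n_altered`
#'   (genes of `a` absent from `b`).
#' @export
compare_signatures <- function(a, b) {
  cats <- sort(union(unique(a$category), unique(b$category)))
  bind_rows(lapply(cats, function(ct) {
    ga <- unique(a$gene_id[a$category == ct])
    gb <- unique(b$gene_id[b$category == ct])
    tibble(category = ct, size = length(ga),
           overlap = length(intersect(ga, gb)),
           n_altered = length(setdiff(ga, gb)))
  }))
}

#' Relative contribution scores by randomization test
#'
#' Repeats a reduced randomization (default 50,000 gene sets per iteration,
#' 200 iterations, each against a freshly drawn patient-set list) scoring
#' gene sets with fuzzy c-means clustering (fuzzifier 2, hard assignment)
#' plus Fisher's exact test. Every gene set whose mean Fisher p beats
#' `p_thresh` joins the candidate pool; a gene's relative contribution
#' score is its prevalence among candidate sets divided by the maximum
#' prevalence.
#'
#' @inheritParams run_mss_full
#' @param signature The discovered signature for the subpool (its genes are
#'   flagged in the output).
#' @param n_iter Randomization iterations.
#' @param rgs_per_iter Gene sets scored per iteration.
#' @param p_thresh Mean-p threshold for a candidate gene set.
#' @return An `mss_rcs` tibble: `gene_id`, `prevalence`, `rcs` in `[0, 1]`,
#'   `in_signature`.
#' @export
compute_rcs <- function(ds, subpool, signature = NULL, n_iter = 200,
                        rgs_per_iter = 50000, p_thresh = 0.001,
                        signature_size = 30, n_cr = 25, n_rd = 55,
                        n_sets = 40, seed = 1, nrestart = 2, maxit = 25) {
  genes <- if (is.character(subpool)) sort(unique(subpool)) else
    sort(unique(subpool$gene_id))
  if (!is.null(signature)) {
    extra <- setdiff(unique(signature$gene_id), genes)
    if (length(extra) > 0) {
      abort(paste0("Signature gene(s) outside the subpool: ",
                   cat_label(head(extra, 5))))
    }
  }
  S <- length(genes)
  prevalence <- rep(0L, S)
  n_candidates <- 0L
  for (it in seq_len(n_iter)) {
    it_seed <- derive_seed(seed, 5000 + it)
    rps <- sample_rps_list(ds, n_cr = n_cr, n_rd = n_rd, n_sets = n_sets,
                           seed = derive_seed(it_seed, 1))
    idx <- rps_index_matrices(rps, sample_ids(ds))
    res <- cpp_run_full(expr_values(ds)[genes, , drop = FALSE],
                        as.integer(signature_size),
                        as.integer(rgs_per_iter), idx$cr, idx$rd,
                        as.double(derive_seed(it_seed, 2)),
                        as.integer(nrestart), as.integer(maxit), TRUE)
    hits <- which(res$mean_p < p_thresh)
    if (length(hits) > 0) {
      flat <- as.vector(res$gene_idx[, hits, drop = FALSE]) + 1L
      prevalence <- prevalence + tabulate(flat, nbins = S)
      n_candidates <- n_candidates + length(hits)
    }
  }
  if (n_candidates == 0) {
    abort(paste0("No candidate gene set reached p < ", p_thresh,
                 "; consider a larger p_thresh."))
  }
  out <- tibble(gene_id = genes, prevalence = as.integer(prevalence),
                rcs = prevalence / max(prevalence),
                in_signature = genes %in% unique(signature$gene_id %||%
                                                   character()))
  structure(out, class = c("mss_rcs", class(tibble())),
            n_candidates = n_candidates,
            config = list(n_iter = n_iter, rgs_per_iter = rgs_per_iter,
                          p_thresh = p_thresh, seed = seed))
}
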