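#' Precision and recall with RD as the positive class
#'
#' A true positive is a nonresponding (RD) patient predicted RD; a false
#' positive is a responding (CR) patient predicted RD. Precision =
#' tp / (tp + fp), recall = tp / (tp + fn). An undefined metric (zero
#' denominator) is reported as `NA` together with the reason, never as NaN.
#'
#' @param predicted,actual Character vectors of `RD`/`CR` labels (same
#'   length), or `predicted` may be an `mss_prediction` tibble, in which
#'   case its `label` column is used.
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#'   `precision_reason`, `recall_reason`.
#' @examples
#' precision_recall(c("RD", "RD", "CR"), c("RD", "CR", "CR"))
#' @export
precision_recall <- function(predicted, actual) {
  if (inherits(predicted, "mss_prediction") || is.data.frame(predicted)) {
    predicted <- predicted$label
  }
  predicted <- normalize_response(predicted)
  actual <- normalize_response(actual)
  stopifnot(length(predicted) == length(actual))
  tp <- sum(predicted == "RD" & actual == "RD")
  fp <- sum(predicted == "RD" & actual == "CR")
  fn <- sum(predicted == "CR" & actual == "RD")
  tn <- sum(predicted == "CR" & actual == "CR")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         precision = precision, recall = recall,
         precision_reason = if (is.na(precision))
           "no RD predictions" else NA_character_,
         recall_reason = if (is.na(recall))
           "no RD samples" else NA_character_)
}

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(response, k_folds, seed = NULL) {
  assign_folds <- function() {
    fold <- integer(length(response))
    for (cls in unique(response)) {
      idx <- which(response == cls)
      if (length(idx) < 2) {
        abort(paste0("Class '", cls, "' has fewer than 2 samples; ",
                     "cannot stratify."))
      }
      fold[sample(idx)] <- rep_len(seq_len(k_folds), length(idx))
    }
    fold
  }
  if (is.null(seed)) assign_folds() else with_seed(seed, assign_folds())
}

#' Stratified k-fold cross-validation of a signature predictor
#'
#' Folds are stratified by response (the RD:CR imbalance reaches 10:1 in
#' the ER+ regime). Per fold, a centroid predictor is built on the training
#' part and evaluated on the test part; metrics are reported per fold, as
#' the mean of per-fold values (the headline), and pooled over all test
#' predictions.
#'
#' @param ds A normalized [expression_dataset()].
#' @param signatures Signatures (see [build_predictor()]).
#' @param k_folds Number of folds.
#' @param fuzzy Use fuzzy voting.
#' @param seed Seed for the fold assignment.
#' @return An `mss_cv` tibble with one row per fold (`fold`, `n_test`,
#'   `tp`, `fp`, `fn`, `tn`, `precision`, `recall`). Attributes carry the
#'   mean and pooled metrics; see `glance()`.
#' @export
cross_validate <- function(ds, signatures, k_folds = 10, fuzzy = FALSE,
                           seed = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  info <- sample_info(ds)
  fold <- stratified_folds(info$response, k_folds, seed = seed)
  rows <- list()
  pooled_pred <- character(0)
  pooled_act <- character(0)
  for (f in seq_len(k_folds)) {
    test_ids <- info$sample_id[fold == f]
    train_ids <- info$sample_id[fold != f]
    if (length(test_ids) == 0) next
    train <- subset_samples(ds, train_ids)
    if (length(unique(sample_info(train)$response)) < 2) {
      abort("A training fold lost one of the classes; use fewer folds.")
    }
    pred <- predict(build_predictor(train, signatures),
                    subset_samples(ds, test_ids), fuzzy = fuzzy)
    act <- info$response[fold == f]
    pr <- precision_recall(pred, act)
    rows[[f]] <- bind_cols(tibble(fold = f, n_test = length(test_ids)),
                           pr[, c("tp", "fp", "fn", "tn", "precision",
                                  "recall")])
    pooled_pred <- c(pooled_pred, pred$label)
    pooled_act <- c(pooled_act, act)
  }
  out <- bind_rows(rows)
  pooled <- precision_recall(pooled_pred, pooled_act)
  structure(out, class = c("mss_cv", class(tibble())),
            mean_precision = mean(out$precision, na.rm = TRUE),
            mean_recall = mean(out$recall, na.rm = TRUE),
            pooled = pooled,
            config = list(k_folds = k_folds, fuzzy = fuzzy, seed = seed))
}

#' @export
glance.mss_cv <- function(x, ...) {
  pooled <- attr(x, "pooled")
  tibble(k_folds = attr(x, "config")$k_folds,
         mean_precision = attr(x, "mean_precision"),
         mean_recall = attr(x, "mean_recall"),
         pooled_precision = pooled$precision,
         pooled_recall = pooled$recall)
}

#' @export
tidy.mss_cv <- function(x, ...) as_tibble(x)

#' Exhaustive signature-combination search
#'
#' Evaluates every subset of the voters with size in `k_range` by
#' stratified cross-validation (all subsets share the same fold
#' assignment) and ranks combinations by the "best balanced" rule: maximal
#' minimum of mean precision and mean recall, ties broken by mean recall
#' (recall is the priority metric: the point of the predictor is to let
#' nonresponders skip an ineffective treatment), then lexicographically.
#'
#' @inheritParams cross_validate
#' @param k_range Subset sizes to evaluate (2:5 over six signatures gives
#'   the canonical 56 combinations).
#' @return An `mss_combination_report` tibble: `combination`, `k`,
#'   `mean_precision`, `mean_recall`, `balance`, sorted best first; the
#'   best combination is in `attr(, "best")`.
#' @export
combination_search <- function(ds, signatures, k_range = 2:5, k_folds = 10,
                               fuzzy = FALSE, seed = NULL) {
  voters <- as_voter_list(signatures)
  if (length(voters) < 2) abort("Need at least two signatures.")
  k_range <- k_range[k_range >= 1 & k_range <= length(voters)]
  info <- sample_info(ds)
  fold <- stratified_folds(info$response, k_folds, seed = seed)
  # one prediction per (fold, sample, voter); subsets aggregate votes
  fold_votes <- lapply(seq_len(k_folds), function(f) {
    test_ids <- info$sample_id[fold == f]
    if (length(test_ids) == 0) return(NULL)
    train <- subset_samples(ds, info$sample_id[fold != f])
    pred <- predict(build_predictor(train, voters),
                    subset_samples(ds, test_ids))
    votes <- bind_rows(lapply(seq_len(nrow(pred)), function(i) {
      mutate(pred$votes[[i]], sample_id = pred$sample_id[i])
    }))
    votes$actual <- info$response[match(votes$sample_id, info$sample_id)]
    votes$fold <- f
    votes
  })
  all_votes <- bind_rows(fold_votes)
  names_sorted <- sort(names(voters))
  combos <- unlist(lapply(sort(unique(k_range)), function(k) {
    combn(names_sorted, k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- lapply(combos, function(members) {
    sub <- filter(all_votes, .data$voter %in% members)
    per <- sub %>%
      group_by(.data$fold, .data$sample_id, .data$actual) %>%
      summarise(rd = sum(.data$vote == "RD"), cr = sum(.data$vote == "CR"),
                msum = sum(.data$margin), .groups = "drop")
    label <- if (isTRUE(fuzzy)) {
      ifelse(per$msum > 0, "RD", "CR")
    } else {
      ifelse(per$rd > per$cr, "RD",
             ifelse(per$cr > per$rd, "CR", ifelse(per$msum > 0, "RD", "CR")))
    }
    fold_metrics <- bind_rows(lapply(unique(per$fold), function(f) {
      sel <- per$fold == f
      precision_recall(label[sel], per$actual[sel])
    }))
    tibble(combination = paste(members, collapse = "+"),
           k = length(members),
           mean_precision = mean(fold_metrics$precision, na.rm = TRUE),
           mean_recall = mean(fold_metrics$recall, na.rm = TRUE))
  })
  report <- bind_rows(rows) %>%
    mutate(balance = pmin(.data$mean_precision, .data$mean_recall)) %>%
    arrange(dplyr::desc(.data$balance), dplyr::desc(.data$mean_recall),
            .data$combination)
  structure(report,
            class = c("mss_combination_report", class(tibble())),
            best = report$combination[1],
            config = list(k_range = sort(unique(k_range)),
                          k_folds = k_folds, fuzzy = fuzzy, seed = seed))
}

#' @export
glance.mss_combination_report <- function(x, ...) {
  bind_cols(tibble(n_combinations = nrow(x), best = attr(x, "best")),
            as_tibble(x)[1, c("mean_precision", "mean_recall")])
}

#' Signature-discovery stability experiment
#'
#' Splits the discovery samples into two subsets (disjoint cohort groups or
#' stratified random halves), reruns the full discovery pipeline on each
#' with identical configuration and seed, and reports how many signature
#' genes differ per category. Swapping half of the discovery data should
#' alter at most a couple of gene selections per category when signatures
#' are robust.
#'
#' @inheritParams discover_signatures
#' @param split `"cohort"` (cohorts alternately assigned to two groups, or
#'   as given by `cohort_groups`) or `"random"` (stratified random halves).
#' @param cohort_groups Optional list of two character vectors of cohort
#'   ids.
#' @param seed Seed; the same discovery seed is used on both subsets so
#'   that differences reflect the data swap, not the RNG.
#' @param ... Passed to [discover_signatures()].
#' @return An `mss_stability` tibble: `category`, `size`, `overlap`,
#'   `n_altered`; the two signature sets are in `attr(, "signatures")`.
#' @export
stability_experiment <- function(ds, annotation,
                                 split = c("cohort", "random"),
                                 cohort_groups = NULL, seed = 1, ...) {
  split <- arg_match(split)
  info <- sample_info(ds)
  if (split == "cohort") {
    if (is.null(cohort_groups)) {
      cohorts <- unique(info$cohort)
      if (length(cohorts) < 2) {
        abort("Need at least two cohorts for a cohort split.")
      }
      cohort_groups <- list(cohorts[seq_along(cohorts) %% 2 == 1],
                            cohorts[seq_along(cohorts) %% 2 == 0])
    }
    ids1 <- info$sample_id[info$cohort %in% cohort_groups[[1]]]
    ids2 <- info$sample_id[info$cohort %in% cohort_groups[[2]]]
  } else {
    half <- stratified_folds(info$response, 2,
                             seed = derive_seed(seed, 77))
    ids1 <- info$sample_id[half == 1]
    ids2 <- info$sample_id[half == 2]
  }
  sig1 <- discover_signatures(subset_samples(ds, ids1), annotation,
                              seed = seed, ...)
  sig2 <- discover_signatures(subset_samples(ds, ids2), annotation,
                              seed = seed, ...)
  cmp <- compare_signatures(sig1, sig2)
  structure(cmp, class = c("mss_stability", class(tibble())),
            signatures = list(sig1, sig2),
            total_altered = sum(cmp$n_altered),
            config = list(split = split, seed = seed))
}
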