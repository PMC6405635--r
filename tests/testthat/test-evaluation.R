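test_that("precision/recall equals hand counts on every 2-sample pattern", {
  labs <- c("RD", "CR")
  for (p1 in labs) for (p2 in labs) for (a1 in labs) for (a2 in labs) {
    pred <- c(p1, p2)
    act <- c(a1, a2)
    pr <- precision_recall(pred, act)
    tp <- sum(pred == "RD" & act == "RD")
    fp <- sum(pred == "RD" & act == "CR")
    fn <- sum(pred == "CR" & act == "RD")
    tn <- sum(pred == "CR" & act == "CR")
    expect_identical(c(pr$tp, pr$fp, pr$fn, pr$tn), c(tp, fp, fn, tn))
    expect_identical(pr$tp + pr$fp + pr$fn + pr$tn, 2L)
    if (tp + fp > 0) expect_equal(pr$precision, tp / (tp + fp))
    else expect_true(is.na(pr$precision) && !is.na(pr$precision_reason))
    if (tp + fn > 0) expect_equal(pr$recall, tp / (tp + fn))
    else expect_true(is.na(pr$recall))
  }
  pr <- precision_recall(c("RD", "RD", "RD", "RD", "RD", "RD", "RD", "RD",
                           "RD", "RD", "CR"),
                         c(rep("RD", 9), "CR", "RD"))
  expect_equal(pr$precision, 0.9)
  expect_equal(pr$recall, 0.9)
  # all-CR predictions: precision undefined with a reason, recall zero
  d <- precision_recall(c("CR", "CR"), c("RD", "CR"))
  expect_true(is.na(d$precision))
  expect_identical(d$precision_reason, "no RD predictions")
  expect_identical(d$recall, 0)
  expect_error(precision_recall(c("RD", "XX"), c("RD", "RD")), "Invalid")
})

test_that("cross-validation stratifies folds and is seed-reproducible", {
  ds <- tiny_dataset(n_genes = 24, n_cr = 10, n_rd = 10, n_cohorts = 1,
                     n_signal = 8, effect = 3, seed = 43)
  dsn <- batch_normalize(ds)
  sigs <- list(s1 = gene_ids(ds)[1:8], s2 = gene_ids(ds)[c(1:4, 9:12)])
  cv <- cross_validate(dsn, sigs, k_folds = 2, seed = 9)
  expect_identical(nrow(cv), 2L)
  # 10 + 10 samples in two folds: 5 of each class per fold
  expect_identical(cv$n_test, c(10L, 10L))
  expect_identical(cv$tp + cv$fp + cv$fn + cv$tn, c(10L, 10L))
  fold_assign <- msscreen:::stratified_folds(sample_info(ds)$response, 2,
                                             seed = 9)
  expect_identical(unname(table(fold_assign,
                                sample_info(ds)$response)["1", ]),
                   c(5L, 5L))
  cv2 <- cross_validate(dsn, sigs, k_folds = 2, seed = 9)
  expect_identical(as.data.frame(cv), as.data.frame(cv2))
  # headline metric is the arithmetic mean of the per-fold values
  expect_equal(attr(cv, "mean_recall"), mean(cv$recall, na.rm = TRUE))
  expect_equal(attr(cv, "mean_precision"), mean(cv$precision, na.rm = TRUE))
  info <- sample_info(ds)
  one_rd <- subset_samples(ds, c(info$sample_id[info$response == "CR"],
                                 info$sample_id[info$response == "RD"][1]))
  expect_error(cross_validate(one_rd, sigs, k_folds = 2, seed = 1),
               "fewer than 2")
})

test_that("leave-one-out recall is high on separable synthetic data", {
  ds <- tiny_dataset(n_genes = 30, n_cr = 8, n_rd = 12, n_cohorts = 1,
                     n_signal = 10, effect = 3, seed = 47)
  dsn <- batch_normalize(ds)
  cv <- cross_validate(dsn, list(sig = gene_ids(ds)[1:10]), k_folds = 20,
                       seed = 3)
  pooled <- attr(cv, "pooled")
  expect_gte(pooled$recall, 0.9)
  expect_gte(pooled$precision, 0.9)
})

test_that("combination search enumerates the binomial-sum subsets", {
  ds <- tiny_dataset(n_genes = 60, n_cr = 12, n_rd = 20, n_cohorts = 1,
                     n_signal = 10, effect = 3, seed = 53)
  dsn <- batch_normalize(ds)
  voters <- setNames(lapply(0:5, function(i) gene_ids(ds)[(1 + i):(10 + i)]),
                     paste0("v", 1:6))
  rep <- combination_search(dsn, voters, k_range = 2:5, k_folds = 3,
                            seed = 5)
  expect_identical(nrow(rep), as.integer(choose(6, 2) + choose(6, 3) +
                                           choose(6, 4) + choose(6, 5)))
  expect_identical(nrow(rep), 56L)
  rep2 <- combination_search(dsn, voters[1:2], k_range = 2, k_folds = 3,
                             seed = 5)
  expect_identical(nrow(rep2), 1L)
  cv_ref <- cross_validate(dsn, voters[1:2], k_folds = 3, seed = 5)
  expect_equal(rep2$mean_recall, attr(cv_ref, "mean_recall"))
  expect_equal(rep2$mean_precision, attr(cv_ref, "mean_precision"))
})

test_that("the informative signature dominates noise combinations", {
  ds <- tiny_dataset(n_genes = 80, n_cr = 14, n_rd = 26, n_cohorts = 1,
                     n_signal = 10, effect = 3, seed = 59)
  dsn <- batch_normalize(ds)
  voters <- c(list(informative = gene_ids(ds)[1:10]),
              setNames(lapply(1:5, function(i) {
                gene_ids(ds)[(11 + 10 * (i - 1)):(20 + 10 * (i - 1))]
              }), paste0("noise", 1:5)))
  rep <- combination_search(dsn, voters, k_range = 2:5, k_folds = 4,
                            seed = 7)
  top <- as_tibble(rep)[as_tibble(rep)$balance == max(rep$balance), ]
  expect_true(all(grepl("informative", top$combination)))
  expect_true(grepl("informative", attr(rep, "best")))
})

test_that("stability on identical subsets with one seed is exact", {
  bench <- generate_benchmark(
    benchmark_spec(cohort_sizes = c(60, 60), validation_sizes = 30,
                   n_genes = 400,
                   categories = c(catA = 40, catB = 36),
                   planted_per_category = 12),
    seed = 3)
  ds <- batch_normalize(split_benchmark(bench)$discovery)
  ann <- bench$annotation
  sig1 <- discover_signatures(ds, ann, mode = "full", n_rgs = 300,
                              n_gilded = 50, k = 60, signature_size = 12,
                              n_cr = 10, n_rd = 25, n_sets = 5, seed = 21)
  sig2 <- discover_signatures(ds, ann, mode = "full", n_rgs = 300,
                              n_gilded = 50, k = 60, signature_size = 12,
                              n_cr = 10, n_rd = 25, n_sets = 5, seed = 21)
  cmp <- compare_signatures(sig1, sig2)
  expect_true(all(cmp$overlap == 12L))
  expect_true(all(cmp$n_altered == 0L))
  # the experiment driver reports per-category alteration counts
  st <- stability_experiment(ds, ann, split = "random", seed = 21,
                             mode = "full", n_rgs = 300, n_gilded = 50,
                             k = 60, signature_size = 12, n_cr = 8,
                             n_rd = 18, n_sets = 5)
  expect_identical(nrow(st), 2L)
  expect_true(all(st$n_altered >= 0 & st$n_altered <= 12))
})
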