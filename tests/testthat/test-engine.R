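test_that("two-sided Fisher p matches enumeration and stats::fisher.test", {
  withr::local_seed(42)
  tabs <- cbind(a = sample(0:20, 200, TRUE), b = sample(0:20, 200, TRUE),
                c = sample(0:20, 200, TRUE), d = sample(0:20, 200, TRUE))
  p_cpp <- msscreen:::cpp_fisher_p(tabs[, 1], tabs[, 2], tabs[, 3],
                                   tabs[, 4])
  p_orc <- apply(tabs, 1, function(t) fisher_oracle(t[1], t[2], t[3], t[4]))
  expect_equal(p_cpp, p_orc, tolerance = 1e-12)
  p_std <- apply(tabs, 1, function(t) {
    stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value
  })
  expect_equal(p_cpp, p_std, tolerance = 1e-7)
})

test_that("gene-set draws are uniform without replacement and reproducible", {
  pool <- sprintf("g%02d", 1:56)
  rgs <- sample_rgs(pool, size = 30, seed = 4)
  expect_length(rgs, 30)
  expect_identical(anyDuplicated(rgs), 0L)
  expect_true(all(rgs %in% pool))
  expect_identical(rgs, sample_rgs(pool, size = 30, seed = 4))
  # forced draw: subpool of exactly the signature size
  expect_setequal(sample_rgs(pool[1:30], size = 30, seed = 1), pool[1:30])
  expect_error(sample_rgs(pool[1:29], size = 30), "cannot draw")
})

test_that("patient-set draws respect class counts and the scaling rule", {
  ds <- tiny_dataset(n_cr = 25, n_rd = 55, n_cohorts = 1)
  rps <- sample_rps_list(ds, n_sets = 40, seed = 2)
  expect_length(rps, 40)
  expect_true(all(vapply(rps, function(s) length(s$cr), 0L) == 25))
  expect_true(all(vapply(rps, function(s) length(s$rd), 0L) == 55))
  # with exactly the requested counts every set holds all samples
  expect_setequal(c(rps[[1]]$cr, rps[[1]]$rd), sample_ids(ds))
  expect_identical(anyDuplicated(c(rps[[2]]$cr, rps[[2]]$rd)), 0L)

  small <- tiny_dataset(n_cr = 5, n_rd = 11, n_cohorts = 1)
  expect_message(rps_s <- sample_rps_list(small, seed = 2), "scaled down")
  expect_identical(attr(rps_s, "n_cr"), 5)
  expect_identical(attr(rps_s, "n_rd"), 11)
  tiny <- tiny_dataset(n_cr = 2, n_rd = 3, n_cohorts = 1)
  expect_error(suppressMessages(sample_rps_list(tiny)), "Too few samples")
})

test_that("a perfectly separating gene set scores 1 / fisher p", {
  # +1 on every gene for CR, -1 for RD: k-means must split by class
  n_cr <- 25; n_rd <- 55
  response <- c(rep("CR", n_cr), rep("RD", n_rd))
  withr::local_seed(5)
  x <- matrix(rnorm(30 * 80, sd = 0.05), 30, 80,
              dimnames = list(sprintf("g%02d", 1:30),
                              sprintf("s%02d", 1:80)))
  x <- x + outer(rep(1, 30), ifelse(response == "CR", 1, -1))
  ds <- expression_dataset(x, tibble::tibble(
    sample_id = colnames(x), cohort = "c1", response = response))
  rps <- sample_rps_list(ds, n_sets = 1, seed = 1)
  scored <- score_rgs(rownames(x), rps, ds, seed = 3)
  p_perfect <- fisher_oracle(25, 0, 0, 55)
  expect_equal(scored$fisher_ps, p_perfect, tolerance = 1e-9)
  expect_equal(scored$enrichment_score, 1 / p_perfect, tolerance = 1e-6)
  expect_true(all(scored$fisher_ps > 0 & scored$fisher_ps <= 1))
  expect_error(score_rgs(c(rownames(x)[1:29], "nope"), rps, ds), "nope")
})

test_that("null gene sets score near 1 and below separating sets", {
  ds <- tiny_dataset(n_genes = 70, n_cr = 25, n_rd = 55, n_cohorts = 1,
                     n_signal = 30, effect = 2, seed = 13)
  rps <- sample_rps_list(ds, n_sets = 10, seed = 1)
  planted <- gene_ids(ds)[1:30]
  nulls <- gene_ids(ds)[31:60]
  s_planted <- score_rgs(planted, rps, ds, seed = 2)$enrichment_score
  s_null <- score_rgs(nulls, rps, ds, seed = 2)$enrichment_score
  expect_gt(s_planted, s_null)
  expect_lt(s_null, 100)
  expect_gte(s_null, 1)
})

test_that("k-means clustering agrees with stats::kmeans on separated data", {
  withr::local_seed(8)
  X <- cbind(matrix(rnorm(10 * 30, -2), 10, 30),
             matrix(rnorm(10 * 50, 2), 10, 50))
  ours <- msscreen:::cpp_cluster2(X, seed = 1, nrestart = 2, maxit = 25,
                                  fuzzy = FALSE)
  ref <- stats::kmeans(t(X), 2, nstart = 5)$cluster
  expect_identical(length(unique(paste(ours, ref))), 2L)
})

test_that("fuzzy c-means hard assignment matches e1071::cmeans", {
  skip_if_not_installed("e1071")
  withr::local_seed(9)
  X <- cbind(matrix(rnorm(8 * 20, -1.5), 8, 20),
             matrix(rnorm(8 * 25, 1.5), 8, 25))
  ours <- msscreen:::cpp_cluster2(X, seed = 2, nrestart = 2, maxit = 50,
                                  fuzzy = TRUE)
  ref <- e1071::cmeans(t(X), 2, m = 2)$cluster
  expect_identical(length(unique(paste(ours, ref))), 2L)
})

test_that("gilded frequency counting matches a brute-force recount", {
  ds <- tiny_dataset(n_genes = 45, n_cr = 10, n_rd = 20, n_cohorts = 1,
                     n_signal = 10, effect = 2, seed = 17)
  genes <- sort(gene_ids(ds))
  rps <- sample_rps_list(ds, n_cr = 8, n_rd = 16, n_sets = 5, seed = 1)
  idx <- msscreen:::rps_index_matrices(rps, sample_ids(ds))
  res <- msscreen:::cpp_run_full(expr_values(ds)[genes, ], 12L, 150L,
                                 idx$cr, idx$rd, 99, 2L, 25L, FALSE)
  gilded <- order(-res$scores, seq_along(res$scores))[1:60]
  sig <- msscreen:::signature_from_gilded(genes,
                                          res$gene_idx[, gilded],
                                          res$scores[gilded], 12L, "t")
  # brute-force recount over the gilded sets
  sets <- apply(res$gene_idx[, gilded] + 1, 2, function(i) genes[i],
                simplify = FALSE)
  counts <- table(unlist(sets))
  for (i in seq_len(nrow(sig))) {
    expect_identical(sig$frequency[i],
                     as.integer(counts[[sig$gene_id[i]]]))
  }
  expect_true(all(sig$frequency >= max(0, sort(as.integer(counts),
                                               decreasing = TRUE)[13])))
})

test_that("full run on a 30-gene subpool returns the subpool", {
  ds <- tiny_dataset(n_genes = 30, n_cr = 8, n_rd = 16, n_cohorts = 1,
                     n_signal = 5, seed = 19)
  sig <- run_mss_full(ds, gene_ids(ds), n_rgs = 50, n_gilded = 10,
                      n_cr = 6, n_rd = 12, n_sets = 4, seed = 1)
  expect_setequal(sig$gene_id, gene_ids(ds))
  expect_true(all(sig$frequency == 10L))
  expect_error(run_mss_full(ds, gene_ids(ds), n_rgs = 10, n_gilded = 20),
               "exceeds")
})

test_that("discovery is deterministic under the master seed in every mode", {
  ds <- tiny_dataset(n_genes = 50, n_cr = 12, n_rd = 24, n_cohorts = 1,
                     n_signal = 12, effect = 2, seed = 21)
  sub <- gene_ids(ds)[1:40]
  args <- list(ds, sub, n_cr = 10, n_rd = 20, n_sets = 5, seed = 77,
               signature_size = 10)
  f1 <- do.call(run_mss_full, c(args, n_rgs = 400, n_gilded = 60))
  f2 <- do.call(run_mss_full, c(args, n_rgs = 400, n_gilded = 60))
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  e1 <- do.call(run_mss_early_stop, c(args, T = 20, warmup = 50, cap = 2000))
  e2 <- do.call(run_mss_early_stop, c(args, T = 20, warmup = 50, cap = 2000))
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_identical(attr(e1, "config")$n_scored, attr(e2, "config")$n_scored)
  n1 <- do.call(run_mss_ensemble, c(args, T = 10, n_lists = 2, warmup = 30,
                                    cap = 1500))
  n2 <- do.call(run_mss_ensemble, c(args, T = 10, n_lists = 2, warmup = 30,
                                    cap = 1500))
  expect_identical(as.data.frame(n1), as.data.frame(n2))
})

test_that("early stopping on a forced subpool stops at warmup + T", {
  ds <- tiny_dataset(n_genes = 30, n_cr = 8, n_rd = 16, n_cohorts = 1,
                     seed = 23)
  sig <- run_mss_early_stop(ds, gene_ids(ds), T = 25, warmup = 40,
                            cap = 5000, n_cr = 6, n_rd = 12, n_sets = 3,
                            seed = 5)
  expect_identical(attr(sig, "config")$n_scored, 65L)
  expect_true(attr(sig, "config")$converged)
  expect_setequal(sig$gene_id, gene_ids(ds))
  # non-convergence within the cap is flagged
  ds2 <- tiny_dataset(n_genes = 60, n_cr = 10, n_rd = 20, n_cohorts = 1,
                      n_signal = 0, seed = 29)
  expect_warning(
    sig2 <- run_mss_early_stop(ds2, gene_ids(ds2), T = 3000, warmup = 10,
                               cap = 60, n_cr = 8, n_rd = 16, n_sets = 3,
                               seed = 5),
    "did not converge")
  expect_false(attr(sig2, "config")$converged)
})

test_that("a one-list ensemble equals its child early-stop run", {
  ds <- tiny_dataset(n_genes = 45, n_cr = 10, n_rd = 20, n_cohorts = 1,
                     n_signal = 10, effect = 2, seed = 31)
  ens <- run_mss_ensemble(ds, gene_ids(ds), T = 15, n_lists = 1,
                          warmup = 40, cap = 2000, n_cr = 8, n_rd = 16,
                          n_sets = 4, seed = 55, signature_size = 12)
  single <- run_mss_early_stop(ds, gene_ids(ds), T = 15, warmup = 40,
                               cap = 2000, n_cr = 8, n_rd = 16, n_sets = 4,
                               seed = derive_seed(55, 101),
                               signature_size = 12)
  expect_identical(ens$gene_id, single$gene_id)
  expect_identical(ens$frequency, single$frequency)
  # five lists means five voters
  ens5 <- run_mss_ensemble(ds, gene_ids(ds), T = 5, n_lists = 5,
                           warmup = 20, cap = 1000, n_cr = 8, n_rd = 16,
                           n_sets = 3, seed = 55, signature_size = 12)
  expect_identical(sort(unique(ens5$list_id)), 1:5)
})

test_that("relative contribution scores normalize prevalence to [0, 1]", {
  ds <- tiny_dataset(n_genes = 40, n_cr = 12, n_rd = 24, n_cohorts = 1,
                     n_signal = 14, effect = 2.5, seed = 37)
  sub <- gene_ids(ds)[1:24]
  rcs <- compute_rcs(ds, sub, signature = NULL, n_iter = 3,
                     rgs_per_iter = 300, p_thresh = 0.05,
                     signature_size = 14, n_cr = 10, n_rd = 20, n_sets = 4,
                     seed = 3)
  expect_identical(max(rcs$rcs), 1)
  expect_true(all(rcs$rcs >= 0 & rcs$rcs <= 1))
  expect_equal(rcs$rcs, rcs$prevalence / max(rcs$prevalence))
  expect_error(
    compute_rcs(ds, sub, n_iter = 1, rgs_per_iter = 50, p_thresh = 1e-300,
                signature_size = 14, n_cr = 10, n_rd = 20, n_sets = 4,
                seed = 3),
    "larger p_thresh")
})
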