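mk_train <- function() {
  # 6 samples, 4 genes: RD high on g1/g2, CR high on g3/g4
  x <- cbind(rd1 = c(3, 3, 0, 0), rd2 = c(1, 1, 0, 0),
             cr1 = c(0, 0, 3, 3), cr2 = c(0, 0, 1, 1),
             rd3 = c(2, 2, 0.5, 0.5), cr3 = c(0.5, 0.5, 2, 2))
  rownames(x) <- paste0("g", 1:4)
  expression_dataset(x, tibble::tibble(
    sample_id = colnames(x), cohort = "c1",
    response = c("RD", "RD", "CR", "CR", "RD", "CR")))
}

test_that("centroids are class means over the signature genes", {
  ds <- mk_train()
  p <- build_predictor(ds, list(sig = paste0("g", 1:4)))
  expect_equal(unname(p$voters$sig$rd_centroid), c(2, 2, 1/6, 1/6))
  expect_equal(unname(p$voters$sig$cr_centroid), c(1/6, 1/6, 2, 2))
  # a single-sample class centroid is that sample's vector
  one <- subset_samples(ds, c("rd1", "cr1", "cr2"))
  p1 <- build_predictor(one, list(sig = paste0("g", 1:4)))
  expect_equal(unname(p1$voters$sig$rd_centroid), c(3, 3, 0, 0))
  expect_error(build_predictor(ds, list(sig = c("g1", "nope"))), "nope")
  rd_only <- subset_samples(ds, c("rd1", "rd2"))
  expect_error(build_predictor(rd_only, list(sig = paste0("g", 1:4))),
               "both RD and CR")
})

test_that("swapping training labels swaps the centroids exactly", {
  ds <- mk_train()
  swapped <- ds
  swapped$samples$response <- ifelse(ds$samples$response == "RD", "CR", "RD")
  swapped <- expression_dataset(swapped$values, swapped$samples)
  p <- build_predictor(ds, list(sig = paste0("g", 1:4)))
  q <- build_predictor(swapped, list(sig = paste0("g", 1:4)))
  expect_equal(p$voters$sig$rd_centroid, q$voters$sig$cr_centroid)
  expect_equal(p$voters$sig$cr_centroid, q$voters$sig$rd_centroid)
  # and flips every prediction
  new <- matrix(rnorm(4 * 10), 4, 10,
                dimnames = list(paste0("g", 1:4), paste0("n", 1:10)))
  expect_identical(predict(p, new)$label,
                   ifelse(predict(q, new)$label == "RD", "CR", "RD"))
})

test_that("cosine votes follow distance, scale and the tie rule", {
  rd <- c(1, 0)
  cr <- c(0, 1)
  v <- vote(rd, rd, cr)
  expect_identical(v$vote, "RD")
  expect_gt(v$margin, 0)
  # cosine is scale invariant
  expect_identical(vote(2 * rd, rd, cr)$vote, "RD")
  expect_equal(vote(2 * rd, rd, cr)$margin, v$margin)
  # equidistant sample votes CR by the "otherwise" rule with margin 0
  eq <- vote(c(1, 1), rd, cr)
  expect_identical(eq$vote, "CR")
  expect_equal(eq$margin, 0)
  # zero-norm sample falls back to Euclidean comparison
  z <- vote(c(0, 0), c(0.1, 0), c(5, 5))
  expect_identical(z$vote, "RD")
})

test_that("majority voting, tie-breaking and fuzzy mode work as documented", {
  ds <- mk_train()
  voters <- list(a = paste0("g", 1:4), b = paste0("g", 1:4),
                 c = paste0("g", 1:4))
  p <- build_predictor(ds, voters)
  new <- cbind(x1 = c(3, 3, 0.1, 0.1), x2 = c(0.1, 0.1, 3, 3))
  rownames(new) <- paste0("g", 1:4)
  pred <- predict(p, new)
  expect_identical(pred$label, c("RD", "CR"))
  expect_identical(pred$rd_votes, c(3L, 0L))
  expect_false(any(pred$tie_broken))

  # engineered tie: two voters that disagree; summed margin decides
  x2 <- cbind(rd1 = c(1, 0, 0, 1), rd2 = c(1, 0.2, 0.2, 1),
              cr1 = c(0, 1, 1, 0), cr2 = c(0.2, 1, 1, 0.2))
  rownames(x2) <- paste0("g", 1:4)
  ds2 <- expression_dataset(x2, tibble::tibble(
    sample_id = colnames(x2), cohort = "c1",
    response = c("RD", "RD", "CR", "CR")))
  p2 <- build_predictor(ds2, list(a = c("g1", "g2"), b = c("g3", "g4")))
  # sample leans strongly RD on voter a, weakly CR on voter b
  mixed <- matrix(c(1, 0.05, 0.8, 0.7), 4, 1,
                  dimnames = list(paste0("g", 1:4), "m"))
  pr2 <- predict(p2, mixed)
  expect_identical(pr2$rd_votes, 1L)
  expect_true(pr2$tie_broken)
  expect_identical(pr2$label, ifelse(pr2$margin_sum > 0, "RD", "CR"))
  # fuzzy mode follows the sign of the summed margin directly
  fz <- predict(p2, mixed, fuzzy = TRUE)
  expect_identical(fz$label, ifelse(fz$margin_sum > 0, "RD", "CR"))
  expect_false(any(fz$tie_broken))
})

test_that("positive rescaling of a sample never changes its votes", {
  ds <- tiny_dataset(n_genes = 20, n_cr = 8, n_rd = 16, n_signal = 6,
                     effect = 2, seed = 41)
  p <- build_predictor(batch_normalize(ds),
                       list(s1 = gene_ids(ds)[1:10],
                            s2 = gene_ids(ds)[5:14]))
  new <- matrix(rnorm(20 * 8), 20, 8,
                dimnames = list(gene_ids(ds), paste0("n", 1:8)))
  a <- predict(p, new)
  b <- predict(p, new * 7.3)
  expect_identical(a$label, b$label)
  expect_identical(a$rd_votes, b$rd_votes)
})

test_that("predictor JSON serialization round-trips predictions", {
  ds <- mk_train()
  p <- build_predictor(ds, list(sig = paste0("g", 1:4),
                                other = c("g1", "g3")))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_predictor(p, tmp)
  q <- read_predictor(tmp)
  new <- matrix(rnorm(4 * 6), 4, 6,
                dimnames = list(paste0("g", 1:4), paste0("n", 1:6)))
  expect_identical(predict(p, new)$label, predict(q, new)$label)
  expect_equal(predict(p, new)$margin_sum, predict(q, new)$margin_sum,
               tolerance = 1e-12)
})

test_that("tidy and glance summarise fitted predictors", {
  p <- build_predictor(mk_train(), list(sig = paste0("g", 1:4)))
  td <- tidy(p)
  expect_identical(nrow(td), 4L)
  expect_named(td, c("voter", "gene_id", "rd_centroid", "cr_centroid"))
  gl <- glance(p)
  expect_identical(gl$n_voters, 1L)
  expect_identical(gl$n_rd, 3L)
})
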