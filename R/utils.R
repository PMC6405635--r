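#' Derive a reproducible child seed
#'
#' Hashes a master seed together with an integer tag into a new seed in
#' `[1, 2^31 - 1]`. Used internally so that every stage of a run (patient-set
#' draws, gene-set streams, ensemble members) has its own independent,
#' reproducible stream.
#'
#' @param seed Master seed (a single number).
#' @param tag Integer tag distinguishing the derived stream.
#' @return A single integer-valued double in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(tag),
            length(tag) == 1)
  cpp_hash_seed(as.double(seed), as.double(tag))
}

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

# population (ddof 0) standard deviation by row
row_sd_pop <- function(x) {
  m <- rowMeans(x)
  sqrt(rowMeans((x - m)^2))
}

# vectorised two-sample Welch t-test across rows; returns p-values.
# Zero-variance conventions: se == 0 & diff == 0 -> p = 1 (no signal);
# se == 0 & diff != 0 -> p = 0 (perfect separation).
row_welch_p <- function(x, idx_a, idx_b) {
  xa <- x[, idx_a, drop = FALSE]
  xb <- x[, idx_b, drop = FALSE]
  na <- length(idx_a)
  nb <- length(idx_b)
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  diff <- ma - mb
  p <- rep(1, nrow(x))
  ok <- se2 > 0
  tt <- diff[ok] / sqrt(se2[ok])
  df <- se2[ok]^2 / ((va[ok] / na)^2 / (na - 1) + (vb[ok] / nb)^2 / (nb - 1))
  p[ok] <- 2 * pt(-abs(tt), df)
  p[!ok & diff != 0] <- 0
  p
}

cat_label <- function(x) paste(x, collapse = ", ")
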