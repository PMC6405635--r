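# Shared fixtures, all generated in code.

# small two-cohort dataset with `n_signal` separating genes
tiny_dataset <- function(n_genes = 40, n_cr = 8, n_rd = 16, n_cohorts = 2,
                         n_signal = 5, effect = 3, seed = 101) {
  withr::with_seed(seed, {
    n <- n_cr + n_rd
    gene_id <- sprintf("g%03d", seq_len(n_genes))
    response <- sample(c(rep("CR", n_cr), rep("RD", n_rd)))
    cohort <- rep_len(sprintf("c%d", seq_len(n_cohorts)), n)
    x <- matrix(rnorm(n_genes * n), n_genes, n,
                dimnames = list(gene_id, sprintf("s%03d", seq_len(n))))
    if (n_signal > 0) {
      shift <- outer(rep(effect / 2, n_signal),
                     ifelse(response == "RD", 1, -1))
      x[seq_len(n_signal), ] <- x[seq_len(n_signal), ] + shift
    }
    expression_dataset(x, tibble::tibble(
      sample_id = colnames(x), cohort = cohort, response = response))
  })
}

# brute-force two-sided Fisher p via hypergeometric enumeration (oracle)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  lo <- max(0, k - n2)
  hi <- min(k, m)
  if (lo >= hi) return(1)
  pmf <- stats::dhyper(lo:hi, m, n2, k)
  sum(pmf[pmf <= pmf[a - lo + 1] * (1 + 1e-7)])
}

# ---------------------------------------------------------------------------
# lazily computed, shared heavy runs for the acceptance suite

.acc <- new.env(parent = emptyenv())

acc_get <- function(name, compute) {
  if (is.null(.acc[[name]])) .acc[[name]] <- compute()
  .acc[[name]]
}

acc_bench <- function() acc_get("bench", function() {
  generate_benchmark(benchmark_spec(), seed = 1)
})

acc_parts <- function() acc_get("parts", function() {
  parts <- split_benchmark(acc_bench())
  list(discovery = batch_normalize(parts$discovery),
       validation = batch_normalize(parts$validation))
})

# reference full-search discovery on the standard benchmark
acc_full <- function() acc_get("full", function() {
  discover_signatures(acc_parts()$discovery, acc_bench()$annotation,
                      mode = "full", n_rgs = 20000, seed = 1)
})
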