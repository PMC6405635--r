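Package: msscreen
Type: Package
Title: Multiple Survival Screening for Treatment-Response Gene Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Discovery of functional-category-partitioned gene-expression
    signatures of treatment nonresponse from multi-cohort expression
    matrices by Multiple Survival Screening: random gene sets drawn from
    differential-expression subpools are scored by 2-means patient
    clustering combined with Fisher's exact test, and consensus genes of
    the top-scoring ("gilded") sets form per-category signatures.
    Includes the full-search, early-stopping and ensemble discovery modes,
    a relative-contribution-score randomization test, a nearest-centroid
    cosine-voting predictor, evaluation tools (precision/recall with the
    nonresponder class as positive, stratified cross-validation,
    exhaustive signature-combination search, stability experiments) and a
    synthetic multi-cohort benchmark generator with planted ground truth.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
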