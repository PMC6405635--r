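---
title: "Multiple Survival Screening: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple Survival Screening: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Given pre-treatment gene-expression profiles of tumours from several
cohorts, each labelled as responding (CR, complete response — `pCR` is
treated as a synonym) or nonresponding (RD, residual disease) to a
chemotherapy, we want small gene signatures whose expression patterns
predict the nonresponders. The positive class throughout is RD: the
intended clinical use is to spare patients an ineffective treatment, so
recall on RD is the metric that matters most.

`msscreen` implements Multiple Survival Screening (MSS), a random-search
scheme: instead of ranking individual genes, it scores many random *gene
sets* by how well they partition patients into response-enriched groups,
and extracts consensus genes from the top-scoring sets. The search is run
separately inside functional categories (apoptosis, cell cycle, DNA damage
& repair, immune response, cell adhesion, phosphorylation are the
canonical six), yielding one 30-gene signature per category; signatures
then act as independent voters in a nearest-centroid classifier.

## The pipeline

1. **Preprocessing** (`collapse_probes()`, `batch_normalize()`,
   `merge_cohorts()`). Probe-level rows are collapsed to one row per gene
   by averaging; unmapped probes are dropped (they could never take part in
   category-driven discovery). Within each cohort independently, every
   gene row is median-centered and divided by its within-cohort population
   standard deviation (a gene constant within a cohort becomes zero rather
   than NaN). Cohorts are merged over their common genes. Per-cohort
   centering/scaling is the reading of "median-centered and z-scored
   across cohorts" that actually addresses batch effects; scaling the
   pooled matrix instead would leave additive cohort offsets in place.
2. **Gene pool** (`top_k_de_pool()`, `subsample_de_pool()`). Either the
   optimized rule — one two-sample Welch t-test per gene, keep the `k =
   500` smallest p-values — or the original subsampled rule: a gene
   qualifies if p < 0.05 in at least 80 of 100 random draws of 30 CR and
   70 RD samples. Welch rather than pooled-variance is used because the
   class imbalance is strong (RD:CR reaches 10:1); zero-variance genes get
   p = 1 so they can never qualify. Ordering ties break by p-value, then
   gene id, so pools are reproducible.
3. **Category subpools** (`partition_by_go()`). Pool genes are assigned to
   every category they are annotated to (many-to-many "with replacement").
   A requested category with fewer genes than the signature size is an
   error, since no random gene set could be drawn from it.
4. **Random search** (`run_mss_full()`). For one subpool: draw a random
   gene set (RGS) of 30 genes without replacement; score it against a
   fixed list of 40 random patient sets (RPS), each of 25 CR and 55 RD
   samples drawn without replacement; repeat for `n_rgs` iterations. The
   score of an RGS is `1 / mean(p)`, where each p comes from clustering
   the RPS samples into two groups by K-means (k = 2, Euclidean, on the
   RGS expression vectors) and testing the 2×2 cluster-by-response table
   with a two-sided Fisher exact test. An empty cluster contributes p = 1;
   every p is floored at 1e-300 before averaging. The `n_gilded = 3000`
   top-scoring sets are the "gilded" RGSs; the 30 genes most frequent
   across them form the signature (ties at the boundary break by the
   summed enrichment score of the gilded sets containing the gene, then by
   gene id).
5. **Prediction** (`build_predictor()`, `predict()`). Per signature, the
   mean expression vector of each class is the class centroid; a sample
   votes RD when its cosine distance to the RD centroid is strictly
   smaller than to the CR centroid (exact ties vote CR, recorded with
   margin 0). The final label is the majority vote; a tied vote falls back
   to the sign of the summed margins and is flagged. `fuzzy = TRUE` uses
   the summed margins directly. Cosine distance is undefined for zero-norm
   vectors, so those votes fall back to Euclidean comparison.
6. **Evaluation** (`precision_recall()`, `cross_validate()`,
   `combination_search()`, `stability_experiment()`). Folds are stratified
   by response. "Best balanced" combination = maximal min(mean precision,
   mean recall), ties resolved toward recall. The headline
   cross-validation metric is the mean of per-fold values; pooled metrics
   are also attached.

## Early stopping and the ensemble mode

A full run is wasteful: the top-30 frequency list settles long before the
last iteration. `run_mss_early_stop()` maintains a running gilded set —
the top `max(50, round(0.003 · i))` scores after `i` iterations — and
stops once the running top-30 list is unchanged for `T` consecutive
iterations; `T` in 100–500 trades little robustness for a large saving,
and `T = 30` with five independent repeats (`run_mss_ensemble()`), each
list voting separately, cuts the work further. Stability tracking starts
after a warm-up of 500 iterations: the warm-up only needs to cover the
running gilded set's floor (50 sets) with some margin, and a longer one
merely postpones the earliest possible stop (`warmup + T`) without making
the decision better informed.

## The synthetic benchmark

`generate_benchmark()` builds a five-cohort study (four discovery, one
validation) with ~4,000 genes on a log2-like scale: per-gene Gaussian
baselines (mean 8, SD 2), within-class noise SD 1, additive per-cohort,
per-gene batch offsets (SD 1), RD:CR ratio 4 in the ER+ regime (range
3–10; the ER− regime uses ~1, range 0.7–1.4), cohort sizes 120/90/60/150
plus a 120-sample validation cohort — roughly the scale of a multi-cohort
microarray compilation. Six categories with the canonical sizes (186, 56,
84, 56, 104, 77) each contain 30 *planted* signature genes shifted between
classes by 1.5 within-class SDs (random direction), and decoy members
shifted by a quarter of that. Decoys model the mild, non-signature-grade
differential expression that makes carcinogenesis-related categories
enriched in the DE pool at all — with strictly null decoys the
category/pool intersections collapse to the planted genes and the search
becomes vacuous. Unannotated background genes are class-independent, so a
zero-effect specification is a genuine null benchmark. Everything is
deterministic given the master seed, and `mss simulate` writes
byte-identical files for identical seeds.

What the benchmark does *not* emulate: probe-level artefacts,
intensity-dependent noise, correlated gene modules, label noise, and
cohort-specific effect heterogeneity. Passing tests on it demonstrates
algorithmic correctness and the engine's statistical behaviour under a
clean planted-truth model, not clinical performance.

## Numerical choices

- Fisher's exact test is two-sided: the sum of hypergeometric point
  masses not exceeding the observed mass times (1 + 1e-7), the standard
  convention; it is verified against full enumeration for every table
  with total ≤ 80.
- K-means uses k-means++ initialisation with 2 restarts and at most 25
  Lloyd iterations. For k = 2 on strongly structured data, k-means++
  makes additional restarts redundant; restarts are exposed as a
  parameter. Fuzzy c-means (fuzzifier 2, hard assignment by maximum
  membership, used by `compute_rcs()`) follows the same convention.
- All engine randomness is counter-based: the stream of iteration `i` is
  derived from the master seed and `i`, so results are bit-for-bit
  reproducible and independent of execution order or worker count.
  Patient-set draws and fold assignments use R's RNG under derived seeds.
- Degenerate inputs: a cohort with one sample is an error (its SD is
  undefined); a within-cohort constant gene normalizes to zero; a subpool
  smaller than the signature size is an error; undefined precision or
  recall is reported as `NA` with a reason, never NaN.

## Problem sizes used in the checks

The packaged tests and `scripts/acceptance.R` run the discovery at 20,000
RGSs per category with 3,000 gilded sets and 40 patient sets — the
desk-scale configuration; the reference configuration of 10^6 iterations
per category is exposed (`n_rgs`) but not exercised. The relative
contribution score defaults (200 iterations × 50,000 gene sets) likewise
far exceed what the tests run; `compute_rcs()` is exercised at reduced
counts.

## Known limitations

- **Enrichment-score saturation.** When a gene set separates the classes
  very strongly — for the benchmark's defaults, any set holding a dozen or
  more planted genes at 1.5 SD — every random patient set yields the same
  perfect 2×2 table and therefore the same Fisher p, and large fractions
  of RGSs tie at the maximal score. Within such a tie class, gilded
  membership carries little information about individual genes, and the
  consensus ranking degrades precisely in the *small* categories (56
  genes), where every RGS is dominated by planted genes. Measured on the
  default benchmark, per-category planted-gene recovery ranges from about
  two thirds (small categories) to 100% (large ones), early-stop/full
  overlap from 23/30 to 30/30, and re-seeded full runs agree on ~94% of
  selections. This is a property of the score under strongly separable
  data, not of the implementation: real cohorts, with weak and noisy
  effects, sit in the graded regime the method was designed for. The
  held-out predictor is essentially unaffected because the substituted
  genes are themselves mildly informative category members.
- The enrichment score is scale-dependent through K-means; data must be
  normalized (the pipeline's `batch_normalize()`) before discovery.
- `subsample_de_pool()` at its defaults needs at least 30 CR and 70 RD
  samples; small studies should use `top_k_de_pool()`.
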