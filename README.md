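# paireval

Paired evaluation of machine-learning models for small-sample biological
and clinical studies: AUC from rankable pairs, leave-pair-out
cross-validation, exact model-comparison tests, per-sample outlier
detection, and confounder-matched evaluation — with a synthetic-data
generator so everything is testable without external data.

## The problem and the estimator

With tens of samples and thousands of molecular features, a single
cross-validation AUC hides which test samples drive it and whether the
model simply learned a lurking variable (tumour subtype, patient age,
collection site). Paired evaluation decomposes performance into pairs of
test samples. Samples *i*, *j* form a **rankable pair** when their labels
are separated by at least a threshold:

    f(y_i, y_j) >= delta_ij

— an indicator on label identity for classification; |y_i − y_j| against a
constant or against max(sigma_i, sigma_j) of technical-replicate SDs for
regression. Over the set *R* of rankable pairs,

    AUC = (# pairs ranked correctly) / |R|,

which for binary labels equals the Wilcoxon–Mann–Whitney AUC (ties get
half credit). On top of this estimator the package provides:

* **`rankable_pairs()` / `delta_spec()`** — build the oriented pair set.
* **`auc_bruteforce()` / `auc_fast()`** — exhaustive scoring, and an
  O(n log n) inversion-counting merge sort (C++) that provably matches it;
  `auc_from_counts()` for tallied counts.
* **`run_lpocv()` / `run_cv()`** — leave-pair-out CV (one model per
  rankable pair) and k-fold / LOO / Monte Carlo schemes over a pluggable
  `model_adapter()` (built-ins: closed-form ridge, logistic, ranger random
  forest).
* **`compare_models()`** — Fisher's exact test and an exact binomial
  McNemar test on two models' verdicts.
* **`outlier_scan()` / `remove_and_reevaluate()`** — sample-specific AUC
  over the pairs containing each sample, one-sided Fisher tests with BH
  adjustment, and before/after re-evaluation.
* **`split_pairs_discrete()` / `select_pairs_continuous()` /
  `confounder_effect()` / `anova_f()`** — confounder-matched vs mismatched
  evaluation for discrete and continuous (censored) confounders.
* **`simulate_dataset()`** — confounded, replicate-noised, outlier-injected
  expression-like data.

Results are tibbles or small S3 objects with `tidy()` / `glance()` /
`autoplot()` methods; a thin CLI lives in `inst/cli/paireval.R`.

## Worked example

Simulate a 40-sample dataset with one injected outlier (its features keep
their group's profile, its label is drawn from the opposite tail), evaluate
a ridge predictor by LPOCV with replicate-based rankability, and scan for
outliers:

```r
library(paireval)

d    <- simulate_dataset(n_samples = 40, n_features = 20,
                         n_signal_features = 10, beta_signal = 1.5,
                         noise_sd = 0.1, n_outliers = 1, seed = 42)
spec <- delta_spec("absolute_difference", use_replicate_sd = TRUE)
prs  <- rankable_pairs(d, spec)     # 548 rankable pairs
fit  <- run_lpocv(d, prs, adapter_ridge(), seed = 42)
fit
#> <LPOCV run> ridge (lambda = 1), seed 42
#> <paired-evaluation AUC> 0.8412 (461 of 548 rankable pairs correct)

scan <- outlier_scan(fit$verdicts)
head(tibble::as_tibble(scan), 2)
#> # A tibble: 2 × 6
#>   sample_id n_pairs_k credit_k  auc_k  p_value p_adjusted
#>   <chr>         <int>    <dbl>  <dbl>    <dbl>      <dbl>
#> 1 s019             31        1 0.0323 2.22e-25   8.88e-24
#> 2 s005             23        6 0.261  2.83e-10   5.66e- 9
```

`s019` — the sample the generator actually flipped — is misranked in 30 of
its 31 pairs (sample-specific AUC 0.03, adjusted p ≈ 9 × 10⁻²⁴). Removing
it and retraining:

```r
res <- remove_and_reevaluate(d, "s019", spec, adapter_ridge(), seed = 42)
res$after
#> <paired-evaluation AUC> 0.9884 (511 of 517 rankable pairs correct)
res$n_pairs_removed
#> [1] 31
```

The pair count drops by exactly the outlier's 31 pairs (548 → 517) and the
AUC climbs from 0.84 to 0.99: one mislabeled sample accounted for most of
the apparent error. `confounder_effect()` works the same way on
subtype-like confounders, reporting AUC over all / matched / mismatched
pairs with one-sided Fisher tests.

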