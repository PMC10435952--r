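---
title: "Paired evaluation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired evaluation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paireval)
```

## The model

Small-sample biological studies (tens of samples, thousands of molecular
features) cannot afford a held-out test set, and the usual cross-validation
summaries hide *which* test samples a predictor gets wrong. Paired evaluation
decomposes performance into the smallest meaningful unit: an ordered pair of
test samples. Two samples $i, j$ with labels $y_i, y_j$ form a **rankable
pair** when

$$f(y_i, y_j) \ge \delta_{ij},$$

where $f$ is a label distance and $\delta_{ij}$ the minimum separation at
which ordering the pair is meaningful. In classification $f$ is an indicator
on label identity (any two distinct classes are rankable); in regression $f$
is $|y_i - y_j|$ and $\delta_{ij}$ is either a constant or, when technical
replicates are available, $\max(\sigma_i, \sigma_j)$ — the larger of the two
samples' replicate standard deviations, i.e. the measurement error for that
pair. Over the set $R$ of rankable pairs, the AUC is estimated as the
fraction ranked correctly,

$$\widehat{\mathrm{AUC}} = \frac{\sum_{(i,j) \in R} p_{ij}}{|R|},$$

with $p_{ij} = 1$ when the model scores the larger-label sample above the
smaller-label one. For binary labels this is exactly the Wilcoxon–Mann–Whitney
probability that a positive outranks a negative; the package's tests verify
the identity to machine precision on random instances.

Pairs are stored **oriented**: `hi` always names the larger-label sample, so
a pair is correct iff `score(hi) > score(lo)`, in classification and
regression alike.

### Choices the estimator definition leaves open

* **Tied scores.** We award half credit for a tied pair (the Mann–Whitney
  convention), so a constant predictor scores exactly 0.5 rather than 0.
* **Tied labels.** Identical labels are never rankable in any mode — there is
  no order to recover — so `constant_delta = 0` means "any strict label
  difference is rankable".
* **No delta supplied.** With ten or fewer distinct label values we default
  to indicator rankability; otherwise to `constant_delta = 0`. Both defaults
  are announced loudly, because the right delta is a scientific choice
  (replicate variance, assay resolution), not a software default.

## Fast estimation by inversion counting

Sorting samples by model score turns misranked rankable pairs into
*inversions* — positions $i < j$ in score order whose labels satisfy
$z_i > z_j$. A merge sort that adds $m - i + 1$ to the tally whenever an
element crosses from the right half counts all inversions in $O(n \log n)$;
the package implements it bottom-up in C++ (`count_inversions()`), and

$$\widehat{\mathrm{AUC}} = \frac{|R| - \text{inversions} - \tfrac12\,t}{|R|},$$

where $t$ counts rankable pairs with tied scores. Ties are broken by
ascending label before counting, so tied-score pairs contribute no
inversions and are credited exactly 0.5 afterwards; `auc_fast()` therefore
equals `auc_bruteforce()` — the authoritative exhaustive definition — on
every instance, which the test suite asserts on 200+ random datasets. The
equivalence between inversions and misranked pairs holds only when
rankability depends on label inequality alone; with per-pair deltas
(replicate-based $\delta_{ij}$) the package routes through the exhaustive
path instead. A million-sample inversion count runs in well under a second,
and the merge-comparison count roughly doubles when $n$ doubles, the
expected $n \log n$ growth.

## Cross-validation and the adapter contract

Any model that can be fitted on a feature matrix and score held-out rows
plugs in through `model_adapter(fit, score, importances)`. Scores are always
oriented "higher = larger predicted label". Built-ins: a closed-form ridge
regression (fast enough for the tens of thousands of fits a scan performs),
logistic regression via `glm`, and a `ranger` random forest.

**Leave-pair-out cross-validation (LPOCV)** trains one model per rankable
pair on all samples except the pair's two members and scores exactly those
two — the scheme pairs naturally with paired evaluation and avoids the
stratification bias small folds suffer from. One model per *rankable* pair
(not per unordered sample pair) keeps cost proportional to $|R|$.
`run_cv()` provides k-fold, leave-one-out, and Monte Carlo splits; when a
sample is scored in several repeats its out-of-fold scores are averaged
(`pool_cv_scores()`). Per-fold model seeds derive deterministically from
(plan seed, fold index), so identical runs are bit-identical; fold
assignment is a seeded shuffle followed by a contiguous split, unstratified
by default.

## Comparing two models

Two verdict tables over the same pairs feed two 2×2 tallies: a *marginal*
table (model × correct/incorrect) tested with Fisher's exact test, and a
*paired* table (both correct / A only / B only / both incorrect) tested
with an **exact binomial McNemar test** on the discordant cells — the χ²
approximation is avoided because the package targets small samples. The
two-sided Fisher p-value uses the "probability mass ≤ observed" convention.
Exact tests need integer counts, so a half-credit pair counts as incorrect
for the model that tied (conservative); `ties = "exclude"` drops tied pairs
instead. McNemar can separate models whose AUCs coincide but who err on
different pairs — a hint that an ensemble would help.

## Outlier detection

The sample-specific AUC restricts the estimate to $R_k$, the rankable pairs
containing sample $k$:

$$\mathrm{AUC}_k = \frac{\sum_{(i,j) \in R_k} p_{ij}}{|R_k|}.$$

Every pair contains two samples, so $\sum_k |R_k| = 2|R|$ and the overall
AUC is the $|R_k|$-weighted mean of $\mathrm{AUC}_k$ halved — identities the
suite asserts on every instance. `outlier_scan()` tests each sample with a
one-sided Fisher test (alternative: pairs containing $k$ are more likely
misranked) on the (in-$R_k$ / not) × (correct / not) table. Because the scan
tests *every* sample, we add Benjamini–Hochberg adjustment across samples —
a single-candidate test needs none, a scan does; raw p-values are reported
alongside. Removal is advisory: `remove_and_reevaluate()` reports AUC before
and after (retraining by default, or just dropping the sample's pairs with
`retrain = FALSE`), plus full-fit feature importances when the adapter
exposes them, since removing an outlier can visibly reorder them.

## Known confounders

A predictor may score well by recognising a confounder (molecular subtype,
age) rather than the signal of interest. Confounder-matched rankable pairs —
pairs whose members share the confounder value — remove that shortcut:

* **Discrete confounders**: pairs are matched when the values are equal;
  matched and mismatched sets partition $R$.
* **Continuous confounders**: for each index sample one matched pair
  (rankable partner minimising the confounder gap) and one mismatched pair
  (strategy: maximal gap, a random partner from the censored category, or
  all remaining pairs) are selected, so each data point carries its minimal
  and maximal separation along the confounder. Values at or above a
  censoring bound (e.g. age of death recorded as 90+) form one category
  with internal gap 0; a matched partner inside it is drawn at random
  (seeded). Ties are otherwise broken by smallest partner id, making
  selection deterministic given the seed. Random censored-category draws
  are effectively without replacement while distinct partners remain, since
  duplicate selected pairs are kept once.

`confounder_effect()` reports AUC over all, matched, and mismatched pairs,
$\Delta \mathrm{AUC} = \mathrm{AUC}_{all} - \mathrm{AUC}_{matched}$, and two
one-sided Fisher tests with the alternative that matched pairs are more
likely misranked. The *primary* test uses disjoint matched vs mismatched
rows — a valid exact test needs disjoint categories. A second,
presentation-style p-value contrasts the overlapping "all pairs" and
"matched pairs" columns side by side, the tabulation conventionally used
when the two AUC columns are printed next to each other; we verified that
only this overlapping layout reproduces such published side-by-side
p-values, and report both so either convention can be matched. A
significantly lower matched AUC indicates the model has learned the
confounder. `anova_f()` (classical one-way ANOVA) quantifies how strongly a
discrete confounder is associated with the labels; a large F anticipates a
large ΔAUC. If a pair qualifies as matched for one index sample and
mismatched for another, the matched assignment wins, keeping the test's
rows disjoint.

## The synthetic generator

`simulate_dataset()` produces the structure the method is designed to
probe, not realistic RNA-seq counts: standard-normal features; a signal
block whose mean drives the label with coefficient `beta_signal`; a
disjoint feature block shifted by the (standardised) confounder, so the
confounder leaves a molecular footprint a model can exploit; Gaussian label
noise; technical replicates whose empirical SD populates `replicate_sd`;
and optional outliers. Defaults — 60 samples, 100 features (10 signal, 10
confounder-shifted, shift 1 SD), label noise 0.3, triplicates with SD 0.2 —
emulate a small-sample drug-response study with subtype-aligned expression
variance. The continuous confounder mode draws ages uniformly on [65, 95],
censored at 90 downstream.

**Outlier mechanism.** An injected outlier keeps its features and has its
label replaced by a draw from the opposite tail of the label distribution —
the archetype being a sample whose molecular profile clearly clusters with
one group while its measured response resembles the other. Flip candidates
are drawn from samples away from the label median: a sample *at* the median
has no "opposite" tail, and flipping it produces a half-misranked,
undetectable pseudo-outlier rather than the phenomenon of interest.

**What passing tests do and do not show.** The generator's Gaussian,
homoscedastic, block-structured features make the recovery scenarios clean:
they demonstrate that the machinery (pair selection, tests, bookkeeping)
behaves as designed, not that any particular real dataset contains
detectable outliers or confounding. Heavy-tailed noise, correlated feature
blocks, and multi-way batch structure are outside what these simulations
exercise.

### Study conditions used in the recovery tests

The stochastic recovery checks (also recomputed by `scripts/acceptance.R`)
fix the following conditions, chosen once as representative of the target
setting:

* **Confounder recovery**: 60 samples, generator defaults, ridge adapter,
  replicate-SD rankability, 50 seeds. Confounded scenario:
  `beta_signal = 0`, `beta_confounder = 2` (the label is pure confounder) —
  the median ΔAUC should exceed 0.15 with the disjoint Fisher p below 0.01
  in most seeds. Clean scenario: `beta_signal = 1`, `beta_confounder = 0` —
  the median |ΔAUC| stays below 0.05 even though the confounder still
  shifts a feature block.
* **Outlier recovery**: 40 samples, a 20-feature panel with 10 signal
  features (drug-response predictors in this setting are trained on small
  pre-selected gene panels), `beta_signal = 1.5`, label noise 0.1, one
  injected outlier, 50 seeds; the injected sample should top the adjusted-p
  ranking in at least 90% of seeds. Detection presupposes a predictor that
  mostly ranks ordinary pairs correctly (LPOCV AUC ≈ 0.85 here); with a
  weak predictor the scan degenerates, by design, to "everything looks
  noisy".

Problem sizes throughout (hundreds to ~1,800 pairs per run; 50 seeds per
scenario) were chosen so the whole suite exercises full LPOCV scans while
remaining comfortably runnable on a laptop.

## Numerical and degenerate-input conventions

* AUC is kept at full precision; only comparisons against 2-decimal printed
  values round half up to 2 decimals.
* Empty rankable-pair sets warn at construction and error at AUC time (an
  undefined estimate is never silently 0 or 0.5).
* `mcnemar_exact()` returns p = 1 with no discordant pairs; Fisher tables
  must be non-negative integers.
* The inversion tally is kept in 64-bit integers (returned as doubles):
  $n(n-1)/2$ overflows 32-bit counts near $n = 10^5$.
* All randomised operations (fold assignment, censored-category draws, the
  generator) take explicit seeds and restore the caller's RNG state.

## Limitations

* Rankability for partially ordered labels is not supported beyond the
  censored-category handling of continuous confounders.
* The confounder analysis requires the confounder to be measured; latent
  batch effects must be discovered by other means first.
* The package quantifies confounding but does not correct for it — data
  modification (ComBat-style batch removal) is deliberately out of scope.
* Feature-importance attribution cannot separate "importance due to signal"
  from "importance due to confounder"; the reported importances are the
  adapter's, unadjusted.
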