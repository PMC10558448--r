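---
title: "Measuring imputation quality with sliced-Wasserstein discrepancies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring imputation quality with sliced-Wasserstein discrepancies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missbench)
```

## The measurement problem

When missingness is induced artificially into a complete dataset, an
imputation can be scored against the ground truth. The common
sample-wise statistics (RMSE, MAE, R²) implicitly define a *prediction*
task: recover each missing value. But the goal of imputation in a
statistical workflow is to recover the *distribution* of the data, and
the two objectives disagree. Imputing every missing value of a feature
by its observed mean is close to optimal in mean-squared error for any
roughly symmetric feature, yet it replaces part of a continuous
distribution with a point mass. Feature-wise two-sample scores detect
that collapse, but only marginal by marginal: a joint structure can be
destroyed — e.g. a diagonal point cloud reflected onto the
anti-diagonal — while every marginal stays exactly intact.

`missbench` therefore scores imputations at three levels. Classes A
(sample-wise) and B (feature-wise) are the community-standard measures,
implemented exactly; class C is a sliced-Wasserstein discrepancy that
sees the joint distribution.

## The sliced-Wasserstein discrepancy

Let the complete data be $x_1, \dots, x_N \in \mathbb{R}^d$ and the
imputed data $\hat x_1, \dots, \hat x_N$ (equal to $x_i$ at observed
cells). The procedure:

1. Draw $M \ge d$ directions $n_r$ uniformly on the unit sphere and
   $P$ random partitions of $\{1,\dots,N\}$ into halves $(I_p, J_p)$ of
   sizes $\lceil N/2 \rceil$ and $\lfloor N/2 \rfloor$.
2. For each $(r, p)$, project all points onto $n_r$ and normalise by
   $s$, the standard deviation of $\{x_i \cdot n_r : i \in I_p\}$.
3. Compute the baseline distance
   $w(r,p) = W_2(\{x_i \cdot n_r / s\}_{i \in I_p}, \{x_j \cdot n_r / s\}_{j \in J_p})$
   and the imputed distance $\hat w(r,p)$ in which the $J_p$ half is
   taken from the imputed data. The $I_p$ half always comes from the
   original data.

The baseline $w$ is the transport distance *inherent to the data*: even
a perfect imputation faces finite-sample spread between two halves of
the same sample. Three derived summaries are reported
(`class_c_report()`):

* the KL / KS / $W_2$ discrepancy between the flattened distributions
  $\{w(r,p)\}$ and $\{\hat w(r,p)\}$ — zero exactly when imputation is
  perfect;
* quantiles and mean of the ratios $\hat w / w$ — the relative
  distortion attributable to imputation;
* the proportion of pairs with $\hat w$ above an outlier threshold.

When the two flattened samples are compared we use the full $M \times P$
collections on both sides (rather than pairing each $\hat w(r,p)$ with
its own baseline); the pairing information is consumed separately by
the ratio summary.

### Parameters

* **M** (directions): default `default_n_directions(d)` = $2d$.
  Direction count controls the Monte-Carlo resolution of the slicing;
  a small multiple of the dimension is dense enough for the summaries
  used here. Presets of 50 (for $d \approx 14$–$25$) and 90 (for wider
  one-hot encoded data) are conventional for this benchmark design and
  can be passed explicitly.
* **P** (partitions): default 10. Partition resampling averages out
  the arbitrariness of any single reference half.
* **s floor**: a pair is skipped (recorded in `skipped`, never scored)
  when $s < 10^{-12}$, i.e. the projected reference half is numerically
  constant. If *all* pairs degenerate the table errors.
* **outlier threshold**: deliberately has **no default**. Distances
  are in units of the projected reference spread, so any absolute
  threshold is dataset- and scale-specific; the caller must choose it.
* Coded (categorical/ordinal, incl. one-hot) columns enter projections
  as the real values of their codes — the slicing operates on the
  encoded matrix as a whole.

## Reference imputers

*Mean/mode imputation* (`impute_mean()`): observed column mean for
continuous features, observed mode for coded features with ties broken
to the smallest level code. Deterministic, $m = 1$.

*Chained equations* (`impute_chained_equations()`): missing cells are
initialised by column mean/mode; then for `n_iter` sweeps each
incomplete column is visited **left-to-right by column index** (a fixed
order chosen for reproducibility) and regressed on all other columns
using the rows where it is observed. Continuous columns redraw missing
entries as the linear prediction plus a Gaussian residual draw (the
noise draw is what preserves marginal spread — a conditional-mean
plug-in would shrink it); binary coded columns use a logistic fit and a
Bernoulli draw; multi-level coded columns use the linear draw projected
to the nearest valid level. Defaults $m = 5$ completions and
`n_iter = 10` sweeps follow common chained-equations practice. A
rank-deficient design (constant predictors) falls back to a mean/mode
draw with a warning rather than failing; rank deficiency short of that
is handled by zeroing unidentifiable coefficients.

Imputed coded values are post-processed to valid levels
(nearest-level projection). How coded variables *should* be imputed is
an unresolved community question; nearest-level is this package's
documented choice, and externally post-processed completions can be
registered instead via `register_external_imputation()`, which enforces
bit-exact preservation of observed cells for every imputer.

For downstream classification with multiple imputations, the
classifier is fitted per completion and the *outputs* are pooled
(`pool_predictions()`): probability averaging by default, majority vote
(ties to the positive class) as the alternative. Pooling outputs rather
than pooling completed datasets keeps imputation uncertainty visible to
the evaluation.

## Missingness, partitioning and the harness

`induce_mcar()` defaults to an **exact-count** policy — exactly
`round(rate·N·d)` cells drawn uniformly without replacement — so a
stated rate of 25% is exactly realised and checkable; a Bernoulli
per-cell policy is available where modelling realism matters. The
outcome column is never masked: labels are not features. No row or
column protection is applied (pure MCAR can, with small probability,
empty a row); scoring functions treat unscorable columns explicitly
(fully missing columns error by name, class B lists skipped features).

`make_split_plan()` builds the two-level design: 3 independent
development/holdout splits (default holdout fraction 0.25 — the
fraction is a configurable choice, not a canonical constant) and 5
cross-validation folds within each development set, fold sizes within
one of each other. `run_scenario()` masks development and holdout parts
at independent rates, selects hyperparameters by mean validation AUC
over folds × completions (ties to the first declared grid point),
refits per completion, pools, and records AUC, accuracy, Brier score,
precision, sensitivity and specificity. The grids are deliberately
small and config-driven; exhaustive grids belong on a cluster, not in a
reference implementation.

## Numerical choices

* **1-D 2-Wasserstein**: inverse-CDF integration on the union grid of
  both quantile functions' breakpoints, evaluated at interval midpoints
  (exactly the discrete-transport optimum; verified in the tests
  against a transport linear program on small instances). Equal sizes
  reduce to the root-mean-square of sorted-order differences.
* **KS**: ECDFs evaluated right-continuously at the union of sample
  points; exact under ties.
* **KL**: the divergence between two samples is estimated on a shared
  equal-width histogram spanning the pooled range (default 30 bins)
  with additive smoothing $\varepsilon = 10^{-10}$ per bin followed by
  renormalisation. A histogram estimator is deterministic and admits an
  exact small-case oracle, at the cost of bin-count sensitivity —
  density-based estimators exist but trade reproducibility for
  smoothness. A zero-width pooled range means both samples are the same
  constant, and returns 0.
* **Class A**: scores are computed on masked cells only, with
  per-feature standardisation (divide by the observed-value standard
  deviation) ON by default so heterogeneous units cannot dominate the
  pooled error; the flag is exposed because either convention is
  defensible. $R^2$ is reported `NA` with a warning when the true
  masked values are constant.
* **Class B** defaults to `missing_only` mode (distribution of the
  true vs imputed *missing* values); `full_feature` mode compares whole
  reconstructed marginals and is the mode in which the
  marginal-blindness demonstration is run.
* **AUC**: Mann–Whitney rank form, ties counting one half.
* **Skewness**: the biased moment form $g_1 = m_3 / m_2^{3/2}$.

All stochastic operations take an explicit integer seed and restore the
caller's RNG state; equal arguments give bit-identical results. CSVs
write doubles with 17 significant digits, so write/read round trips are
bit-identical; missing cells are empty fields.

## The synthetic generator

`generate_numeric(n, d, class_sep, seed)` draws a balanced two-class
sample with each class an isotropic unit-variance Gaussian centred at a
vertex of the hypercube $\{\pm \text{class\_sep}\}^d$; the two vertices
are chosen uniformly at random (distinct when `class_sep > 0`), so the
number of signal-carrying coordinates varies with the draw, and
`class_sep` is half the distance between adjacent vertices. This is a
transparent re-statement of the hypercube-cluster construction commonly
used for simulation studies (the widely used library generator adds
random covariance mixing and multi-cluster classes; we implement the
stated structure, not that code). The benchmark configuration is
`generate_numeric(1000, 25, 1.0, seed)`.

`generate_mixed()` adds integer-coded categorical/ordinal columns by
quantile-binning *additional* latent informative Gaussian draws —
binning preserves class signal and is exactly reproducible — plus
standard-normal uninformative columns independent of the outcome.
Level counts default to 3 (categorical) and 4 (ordinal) and are
configurable; the mixed design's exact composition is a free parameter
of this package, not a canonical constant.

What the generator does *not* emulate: covariate correlation within a
class (features are conditionally independent), heavy tails, natural
(non-MCAR) missingness, label noise, and class imbalance beyond ±1.
Passing tests on these data therefore certify the *machinery* — exact
masking, preservation invariants, metric correctness, qualitative
orderings — not performance on any particular clinical dataset, where
missingness is usually informative and distributions are not Gaussian.

## Test and script problem sizes

The test suite and the acceptance script run the full pipeline at
1000 × 25 with $M = 50$, $P = 10$, 20 seeds for the imputer-dominance
comparison, 10 seeds for the ratio-monotonicity and AUC-ordering
checks, and small LP-verified instances (≤ 6 points per sample, 1000
instances) for the transport oracle. These sizes were chosen to make
every qualitative claim statistically stable while keeping a complete
run in the low minutes on one core.

## Known limitations

* The sliced discrepancy uses one completion per table; multiple
  completions produce one table each, summarised by
  `stability_analysis()` (between-table variance of mean $\hat w$
  separates imputation stochasticity from projection noise).
* MAR/MNAR mechanisms are out of scope: induced missingness is MCAR
  only, and naturally missing data arrives pre-baked in user CSVs.
* KL on small samples is bin-limited; prefer KS/W₂ when $N$ is tiny.
* The chained-equations engine is a linear/logistic reference
  implementation — adequate for benchmarking the *measures*; it is not
  a replacement for a full-featured multiple-imputation package with
  predictive mean matching and diagnostics.
* Feature-importance analysis is limited to summarising externally
  supplied importance vectors (via `skewness()`); no Shapley values are
  computed here.
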