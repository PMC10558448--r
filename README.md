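# missbench

Benchmarking imputation quality for incomplete tabular data — and its
downstream effect on binary classification.

## The problem

Clinical and epidemiological tables are rarely complete. The standard
two-stage recipe — impute the missing cells, then fit a classifier — is
usually judged by sample-wise error statistics (RMSE, MAE, R²) that
reward recovering each missing *value*. But imputation is not
prediction: a method can minimise RMSE while producing a completed
dataset whose *distribution* is badly wrong (mean imputation is the
canonical offender — it collapses every missing value in a feature onto
a single point). Feature-wise two-sample statistics catch some of this,
but they only see the marginals: a joint distribution can be distorted
while every single-feature marginal remains exactly intact.

`missbench` implements three classes of imputation discrepancy measure
and the machinery to benchmark them:

* **Class A (sample-wise)** — RMSE, MAE and R² over the masked cells.
* **Class B (feature-wise)** — Kullback–Leibler divergence, two-sample
  Kolmogorov–Smirnov statistic and 1-D 2-Wasserstein distance between
  true and imputed values, feature by feature, with min/median/max
  summaries.
* **Class C (whole-distribution)** — a sliced-Wasserstein discrepancy:
  choose `M ≥ d` random unit directions **n**ᵣ and `P` random
  half-partitions (I_p, J_p) of the sample index set; for each pair
  (r, p) project the data onto **n**ᵣ, normalise by the standard
  deviation *s* of the projected original data over I_p, and compute
  two 1-D 2-Wasserstein distances:

  - the baseline `w(r, p) = W₂({xᵢ·nᵣ/s : i ∈ I_p}, {xⱼ·nᵣ/s : j ∈ J_p})`,
    the distance inherent to the data;
  - the imputed `ŵ(r, p)`, with the J_p half replaced by imputed data.

  The two collections {w} and {ŵ} are then compared as distributions
  (KL/KS/W₂), the ratios ŵ/w summarise the relative distortion due to
  imputation, and the fraction of pairs with ŵ above a threshold flags
  outlier imputations.

Around these sit MCAR missingness induction (exact-count or Bernoulli),
development/holdout + k-fold partitioning, reference imputers (column
mean/mode and multiple imputation by chained equations), prediction
pooling across multiple imputations, classifier benchmarking (logistic
regression, random forest, or anything honouring the fit/predict
contract), and a synthetic labelled-data generator so everything is
testable without external downloads. Externally produced completions
(from any third-party imputer) can be registered and scored through the
same interface.

## Worked example

Generate the simulated study dataset (1000 samples, 25 informative
Gaussian-cluster features, binary outcome), knock out 25% of cells
completely at random, impute with mean imputation and with chained
equations, and compare:

```r
library(missbench)
truth <- generate_numeric(1000, 25, 1.0, seed = 1)
mask  <- induce_mcar(truth, 0.25, seed = 2)
incomplete <- apply_mask(truth, mask)

imp_mean <- impute_mean(incomplete)
imp_mice <- impute_chained_equations(incomplete, m = 5, n_iter = 10, seed = 3)

unlist(class_a_scores(truth, imp_mean$completions[[1]], mask)[c("rmse", "mae", "r_squared")])
#>      rmse       mae r_squared
#> 1.0019805 0.8123875 0.3640528

dirs  <- sample_directions(d = 25, M = 50, seed = 4)
parts <- make_half_partitions(N = 1000, P = 10, seed = 5)
class_c_report(sw_distance_table(truth, imp_mean$completions[[1]], dirs, parts),
               outlier_threshold = 10)
#> <mb_class_c> over 500 (r, p) pairs
#>   distance-distribution discrepancy: KL 0.9209, KS 0.506, W2 0.05187
#>   ratio what/w: median 1.493, mean 1.591
#>   outlier proportion (what > 10): 0
class_c_report(sw_distance_table(truth, imp_mice$completions[[1]], dirs, parts),
               outlier_threshold = 10)
#> <mb_class_c> over 500 (r, p) pairs
#>   distance-distribution discrepancy: KL 0.08195, KS 0.036, W2 0.002843
#>   ratio what/w: median 0.9964, mean 1.02
#>   outlier proportion (what > 10): 0
```

Reading the numbers: mean imputation looks acceptable sample-wise
(RMSE ≈ 1 on standardised features), but its sliced distances sit far
from the data's baseline distribution (KS ≈ 0.51 between {w} and {ŵ};
projected distances typically 1.5× the baseline). Chained equations
leaves the distance distribution nearly untouched (KS ≈ 0.04, median
ratio ≈ 1) — the distributional fidelity that the sample-wise scores
cannot see.

## Command line

A thin CLI over the same functions lives at `inst/cli/missbench`
(subcommands `simulate`, `mask`, `split`, `impute`, `score`, `sw`,
`benchmark`); `benchmark` runs a YAML-configured pipeline via
`run_pipeline()`, writing a long-format metrics CSV and a JSON manifest
carrying the seeds and config hash.

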