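Package: missbench
Title: Benchmarking Imputation Quality for Incomplete Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring how faithfully an imputation method
    reconstructs an incomplete dataset, and for quantifying the downstream
    effect of imputation quality on binary classification. Provides
    sample-wise error statistics (RMSE, MAE, R^2), feature-wise two-sample
    distributional discrepancies (Kullback-Leibler divergence,
    Kolmogorov-Smirnov statistic, 1-D 2-Wasserstein distance), and a
    sliced-Wasserstein discrepancy class that projects the full data
    distribution onto random directions and compares baseline against
    imputed transport distances over random half-partitions of the sample.
    Includes MCAR missingness induction, development/holdout plus
    cross-validation partitioning, reference imputers (column mean,
    multiple imputation by chained equations), prediction pooling across
    multiple imputations, a classifier benchmarking harness, a synthetic
    labelled-data generator (Gaussian clusters at hypercube vertices, with
    optional categorical/ordinal/uninformative columns), and a
    configuration-driven pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang,
    ranger
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
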