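test_that("directions are unit vectors, deterministic and isotropic", {
  ds <- sample_directions(5, 20, seed = 1)
  expect_equal(dim(ds$directions), c(20L, 5L))
  expect_true(all(abs(sqrt(rowSums(ds$directions^2)) - 1) < 1e-12))
  expect_identical(ds, sample_directions(5, 20, seed = 1))
  expect_error(sample_directions(5, 4, seed = 1), "M >= d")

  # d = 1: directions live on {-1, +1}
  one <- sample_directions(1, 10, seed = 2)
  expect_true(all(one$directions %in% c(-1, 1)))

  # Monte-Carlo isotropy: the empirical mean direction is near zero
  big <- sample_directions(5, 10000, seed = 3)
  expect_lt(sqrt(sum(colMeans(big$directions)^2)), 0.05)
})

test_that("half-partitions split indices into near-equal disjoint halves", {
  odd <- make_half_partitions(7, 5, seed = 4)
  for (pr in odd$pairs) {
    expect_length(pr$I, 4)  # (N + 1) / 2
    expect_length(pr$J, 3)  # (N - 1) / 2
    expect_length(intersect(pr$I, pr$J), 0)
    expect_setequal(c(pr$I, pr$J), 1:7)
  }
  even <- make_half_partitions(10, 3, seed = 5)
  for (pr in even$pairs) {
    expect_length(pr$I, 5)
    expect_length(pr$J, 5)
  }
  expect_identical(make_half_partitions(10, 3, seed = 5), even)
  expect_error(make_half_partitions(3, 2, seed = 1), "N >= 4")
})

test_that("perfect imputation gives w_hat identical to w and zero discrepancies", {
  ds <- generate_numeric(100, 4, 1.0, seed = 6)
  dirs <- sample_directions(4, 8, seed = 7)
  parts <- make_half_partitions(100, 5, seed = 8)
  tab <- sw_distance_table(ds, ds$values, dirs, parts)
  expect_identical(tab$w, tab$w_hat)
  cc <- class_c_report(tab, outlier_threshold = max(tab$w, na.rm = TRUE) + 1)
  expect_equal(cc$dist_discrepancy$ks, 0)
  expect_equal(cc$dist_discrepancy$w2, 0)
  expect_equal(cc$dist_discrepancy$kl, 0, tolerance = 1e-12)
  expect_true(all(abs(cc$ratio_summary - 1) < 1e-12))
  expect_equal(cc$outlier_proportion, 0)
})

test_that("the distance table is invariant to joint rescaling of the data", {
  ds <- generate_numeric(60, 3, 1.0, seed = 9)
  imp <- impute_mean(apply_mask(ds, induce_mcar(ds, 0.25, seed = 10)))$completions[[1]]
  dirs <- sample_directions(3, 6, seed = 11)
  parts <- make_half_partitions(60, 4, seed = 12)
  base <- sw_distance_table(ds, imp, dirs, parts)
  for (c_scale in c(1e-3, 7, 1e4)) {
    scaled <- sw_distance_table(mb_dataset(ds$values * c_scale), imp * c_scale,
                                dirs, parts)
    expect_equal(scaled$w, base$w, tolerance = 1e-10)
    expect_equal(scaled$w_hat, base$w_hat, tolerance = 1e-10)
  }
})

test_that("in one dimension the table reduces to the standardised 1-D distance", {
  set.seed(13)
  x <- matrix(rnorm(30), ncol = 1)
  xhat <- x
  xhat[25:30] <- 0
  dirs <- sample_directions(1, 1, seed = 14)
  parts <- make_half_partitions(30, 1, seed = 15)
  tab <- sw_distance_table(mb_dataset(x), xhat, dirs, parts)
  I <- parts$pairs[[1]]$I
  J <- parts$pairs[[1]]$J
  dir1 <- dirs$directions[1, 1]
  s <- sd(x[I] * dir1)
  expect_equal(tab$w[1, 1],
               wasserstein2_1d(x[I] * dir1 / s, x[J] * dir1 / s))
  expect_equal(tab$w_hat[1, 1],
               wasserstein2_1d(x[I] * dir1 / s, xhat[J] * dir1 / s))
})

test_that("degenerate projections are skipped, fully-degenerate data errors", {
  # constant data: every projected half has zero spread
  const <- mb_dataset(matrix(1, 10, 2))
  dirs <- sample_directions(2, 3, seed = 16)
  parts <- make_half_partitions(10, 2, seed = 17)
  expect_error(sw_distance_table(const, const$values, dirs, parts), "degenerate")
})

test_that("class C ratios and outliers behave at the boundaries", {
  ds <- generate_numeric(80, 3, 1.0, seed = 18)
  msk <- induce_mcar(ds, 0.3, seed = 19)
  far <- ds$values
  far[msk$mask] <- 1e3  # constant far outside the data range
  dirs <- sample_directions(3, 6, seed = 20)
  parts <- make_half_partitions(80, 5, seed = 21)
  tab_far <- sw_distance_table(ds, far, dirs, parts)
  tab_perfect <- sw_distance_table(ds, ds$values, dirs, parts)
  cc_far <- class_c_report(tab_far, outlier_threshold = 1)
  cc_perfect <- class_c_report(tab_perfect, outlier_threshold = 1)
  expect_gt(cc_far$ratio_summary[["mean"]], 10)
  expect_gt(cc_far$ratio_summary[["mean"]], cc_perfect$ratio_summary[["mean"]])

  # threshold below every positive w_hat -> proportion 1
  tiny <- class_c_report(tab_far, outlier_threshold = 1e-300)
  expect_equal(tiny$outlier_proportion, 1)
  expect_error(class_c_report(tab_far, outlier_threshold = -1), "positive")
  expect_error(class_c_report(tab_far), "outlier_threshold")
})

test_that("stability analysis separates projection from imputation variance", {
  ds <- generate_numeric(80, 3, 1.0, seed = 22)
  msk <- induce_mcar(ds, 0.3, seed = 23)
  inc <- apply_mask(ds, msk)
  dirs <- sample_directions(3, 6, seed = 24)
  parts <- make_half_partitions(80, 5, seed = 25)

  # deterministic imputer: identical tables, zero between-table variance
  mean_tabs <- lapply(1:3, function(i) {
    sw_distance_table(ds, impute_mean(inc)$completions[[1]], dirs, parts)
  })
  st <- stability_analysis(mean_tabs, threshold = 1)
  expect_equal(st$between_table_variance, 0)
  expect_identical(mean_tabs[[1]]$w_hat, mean_tabs[[2]]$w_hat)

  # stochastic imputer with different seeds: strictly positive
  mice_tabs <- lapply(1:3, function(i) {
    ck <- impute_chained_equations(inc, m = 1, n_iter = 3, seed = 600 + i)
    sw_distance_table(ds, ck$completions[[1]], dirs, parts)
  })
  expect_gt(stability_analysis(mice_tabs, threshold = 1)$between_table_variance, 0)

  # mismatched direction seeds are rejected
  other <- sw_distance_table(ds, impute_mean(inc)$completions[[1]],
                             sample_directions(3, 6, seed = 99), parts)
  expect_error(stability_analysis(list(mean_tabs[[1]], other), threshold = 1),
               "share")
  expect_error(stability_analysis(mean_tabs[1], threshold = 1), ">= 2")
})

test_that("rotating truth and imputation together preserves the entry distribution", {
  ds <- correlated_gaussian(200, 0.7, seed = 26)
  noise <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("n1", "n2", "n3")))
  d2 <- mb_dataset(cbind(ds$values, noise))
  msk <- induce_mcar(d2, 0.25, seed = 27)
  imp <- impute_mean(apply_mask(d2, msk))$completions[[1]]
  Q <- random_orthogonal(5, seed = 28)
  parts <- make_half_partitions(200, 2, seed = 29)
  tab_a <- sw_distance_table(d2, imp, sample_directions(5, 500, seed = 30), parts)
  tab_b <- sw_distance_table(mb_dataset(d2$values %*% Q), imp %*% Q,
                             sample_directions(5, 500, seed = 31), parts)
  p <- suppressWarnings(stats::ks.test(as.vector(tab_a$w_hat),
                                       as.vector(tab_b$w_hat))$p.value)
  expect_gt(p, 0.001)
})

test_that("distance tables serialise to CSV with a manifest", {
  ds <- generate_numeric(40, 3, 1.0, seed = 32)
  imp <- impute_mean(apply_mask(ds, induce_mcar(ds, 0.25, seed = 33)))$completions[[1]]
  tab <- sw_distance_table(ds, imp, sample_directions(3, 6, seed = 34),
                           make_half_partitions(40, 4, seed = 35))
  f <- withr::local_tempfile(fileext = ".csv")
  manifest <- write_sw_table(tab, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 24)
  expect_named(df, c("r", "p", "s", "w", "w_hat"))
  raw <- jsonlite::read_json(manifest)
  expect_equal(raw$M, 6)
  expect_equal(raw$P, 4)
})
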