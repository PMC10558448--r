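test_that("mean imputation fills observed means and modes", {
  vals <- cbind(a = c(1, NA, 3), b = c(0, 0, 1))
  ds <- mb_dataset(vals, list(feature_schema("a", "continuous"),
                              feature_schema("b", "categorical", 0:1)))
  out <- impute_mean(ds)
  expect_equal(unname(out$completions[[1]][2, "a"]), 2)

  # binary coded column {0, 0, 1, NA} -> mode 0
  ds2 <- mb_dataset(cbind(b = c(0, 0, 1, NA), c = 1:4),
                    list(feature_schema("b", "categorical", 0:1),
                         feature_schema("c", "continuous")))
  expect_equal(unname(impute_mean(ds2)$completions[[1]][4, "b"]), 0)

  # mode ties break to the smallest level
  ds3 <- mb_dataset(cbind(b = c(0, 0, 1, 1, NA), c = 1:5),
                    list(feature_schema("b", "ordinal", 0:1),
                         feature_schema("c", "continuous")))
  expect_equal(unname(impute_mean(ds3)$completions[[1]][5, "b"]), 0)

  # no missing cells -> identity
  full <- mb_dataset(matrix(rnorm(12), 4, 3))
  expect_identical(impute_mean(full)$completions[[1]], full$values)

  # fully-missing column errors naming the column
  ds4 <- mb_dataset(cbind(x = c(NA, NA), y = c(1, 2)))
  expect_error(impute_mean(ds4), "'x'")
})

test_that("chained equations recovers an exact linear relation", {
  set.seed(1)
  x <- rnorm(200)
  y <- 2 * x
  vals <- cbind(x = x, y = y)
  vals[sample(200, 60), "y"] <- NA
  ds <- mb_dataset(vals)
  out <- impute_chained_equations(ds, m = 1, n_iter = 5, seed = 2)
  mis <- is.na(vals[, "y"])
  expect_lt(mean(abs(out$completions[[1]][mis, "y"] - 2 * x[mis])), 0.1)
})

test_that("chained equations is deterministic, multi-chain and preserves observed cells", {
  ds <- generate_numeric(80, 4, 1.0, seed = 3)
  msk <- induce_mcar(ds, 0.3, seed = 4)
  inc <- apply_mask(ds, msk)
  a <- impute_chained_equations(inc, m = 3, n_iter = 3, seed = 5)
  b <- impute_chained_equations(inc, m = 3, n_iter = 3, seed = 5)
  expect_identical(a$completions, b$completions)
  expect_equal(a$m, 3L)
  expect_false(identical(a$completions[[1]], a$completions[[2]]))
  for (ck in a$completions) {
    expect_false(anyNA(ck))
    expect_identical(ck[!msk$mask], ds$values[!msk$mask])
  }

  # no missing cells -> all completions equal the input
  none <- impute_chained_equations(ds, m = 2, n_iter = 2, seed = 6)
  expect_identical(none$completions[[1]], ds$values)
  expect_identical(none$completions[[2]], ds$values)
})

test_that("coded columns are imputed onto valid levels", {
  ds <- generate_mixed(120, 3, 1, 1, 0, 1.0, seed = 7)
  msk <- induce_mcar(ds, 0.25, seed = 8)
  inc <- apply_mask(ds, msk)
  out <- impute_chained_equations(inc, m = 2, n_iter = 3, seed = 9)
  kinds <- vapply(ds$schema, `[[`, character(1), "kind")
  for (ck in out$completions) {
    for (j in which(kinds %in% c("categorical", "ordinal"))) {
      expect_true(all(ck[, j] %in% ds$schema[[j]]$levels))
    }
  }
})

test_that("degenerate designs fall back to a mean draw with a warning", {
  vals <- cbind(x = rep(1, 10), y = c(rnorm(7), NA, NA, NA))
  ds <- mb_dataset(vals)
  expect_warning(out <- impute_chained_equations(ds, m = 1, n_iter = 1, seed = 1),
                 "degenerate")
  expect_false(anyNA(out$completions[[1]]))
})

test_that("pooling averages probabilities or takes majority labels", {
  expect_equal(pool_predictions(list(0.2, 0.4), "average"), 0.3)
  expect_equal(pool_predictions(list(c(0.9, 0.1), c(0.8, 0.2)), "average"),
               c(0.85, 0.15))
  # majority over thresholded labels {1, 1, 0} -> 1
  expect_equal(pool_predictions(list(0.9, 0.8, 0.1), "majority"), 1)
  # ties go to the positive class
  expect_equal(pool_predictions(list(0.9, 0.1), "majority"), 1)
  # m = 1 is the identity
  expect_equal(pool_predictions(list(c(0.3, 0.7)), "average"), c(0.3, 0.7))
  expect_error(pool_predictions(list()), "non-empty")
  expect_error(pool_predictions(list(0.5, c(0.5, 0.6))), "equal length")
  expect_error(pool_predictions(list(1.5)), "\\[0, 1\\]")
})

test_that("external completions are validated against observed cells", {
  ds <- generate_numeric(20, 3, 1.0, seed = 10)
  msk <- induce_mcar(ds, 0.25, seed = 11)
  inc <- apply_mask(ds, msk)

  ok <- register_external_imputation(list(ds$values, ds$values, ds$values),
                                     msk, "oracle", original = inc$values)
  expect_equal(ok$m, 3L)

  tampered <- ds$values
  obs_cell <- which(!msk$mask)[1]
  tampered[obs_cell] <- tampered[obs_cell] + 1
  expect_error(register_external_imputation(list(tampered), msk, "bad",
                                            original = inc$values),
               "altered observed cell")

  leftover <- ds$values
  leftover[which(msk$mask)[1]] <- NA
  expect_error(register_external_imputation(list(leftover), msk, "bad"),
               "missing cells")
})

test_that("chained equations beats mean imputation on correlated data (sliced discrepancy)", {
  wins <- 0L
  for (s in 1:20) {
    ds <- correlated_gaussian(500, 0.9, seed = 100 + s)
    msk <- induce_mcar(ds, 0.25, seed = 200 + s)
    inc <- apply_mask(ds, msk)
    dirs <- sample_directions(2, 4, seed = 300 + s)
    parts <- make_half_partitions(500, 10, seed = 400 + s)
    disc <- function(mimp) {
      tab <- sw_distance_table(ds, mimp$completions[[1]], dirs, parts)
      class_c_report(tab, outlier_threshold = 10)$dist_discrepancy$w2
    }
    d_mean <- disc(impute_mean(inc))
    d_mice <- disc(impute_chained_equations(inc, m = 1, n_iter = 5, seed = 500 + s))
    if (d_mice < d_mean) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})
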