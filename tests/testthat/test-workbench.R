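test_that("dataset CSV + schema sidecar round-trips bit-identically", {
  ds <- generate_mixed(40, 3, 1, 1, 1, 1.0, seed = 1)
  msk <- induce_mcar(ds, 0.2, seed = 2)
  inc <- apply_mask(ds, msk)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(inc, f)
  back <- read_dataset_csv(f)
  expect_identical(back$values, inc$values)
  expect_identical(back$labels, inc$labels)
  expect_identical(lapply(back$schema, unclass), lapply(inc$schema, unclass))
  # empty CSV fields became missing cells
  expect_equal(sum(is.na(back$values)), sum(msk$mask))
})

test_that("level codes outside the declared set are rejected with location", {
  ds <- mb_dataset(cbind(o = c(0, 1, 2, 1)),
                   list(feature_schema("o", "ordinal", 0:2)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, f)
  txt <- readLines(f)
  txt[3] <- "5"  # row 2 of the data
  writeLines(txt, f)
  expect_error(read_dataset_csv(f), "row 2, column 'o'")
})

test_that("schema invariants are enforced", {
  expect_error(feature_schema("x", "categorical", levels = 1), ">= 2 levels")
  expect_error(feature_schema("x", "continuous", levels = 1:2), "must not declare")
  expect_error(mb_dataset(cbind(a = 1:3, a = 4:6),
                          list(feature_schema("a", "continuous"),
                               feature_schema("a", "continuous"))),
               "unique")
  expect_error(mb_dataset(cbind(k = c(0, 3)),
                          list(feature_schema("k", "categorical", 0:1))),
               "outside its declared levels")
})

pipeline_config <- function(outdir, seed = 5) {
  list(seed = seed, output_dir = outdir,
       dataset = list(type = "synthetic_numeric", n = 60, d_informative = 4,
                      class_sep = 1.0),
       mask = list(rates = c(0.25), policy = "exact_count"),
       imputers = list(list(name = "mean"), list(name = "mice", m = 2, n_iter = 2)),
       metrics = c("class_a", "class_b", "class_c"),
       sw = list(P = 5, outlier_threshold = 2.0))
}

test_that("run_pipeline writes metrics for every imputer and reruns byte-identically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_pipeline(pipeline_config(d1))
  r2 <- run_pipeline(pipeline_config(d2))
  expect_setequal(unique(r1$metrics$method), c("mean", "mice"))
  expect_true(all(c("rmse", "ks_median", "sw_w2") %in% r1$metrics$metric))
  # mice has m = 2 completions feeding a stability row
  expect_true("sw_between_table_variance" %in%
                r1$metrics$metric[r1$metrics$method == "mice"])
  expect_identical(readLines(r1$metrics_file), readLines(r2$metrics_file))
  manifest <- jsonlite::read_json(r1$manifest_file)
  expect_equal(manifest$seed, 5)
  expect_true(nzchar(manifest$config_hash))
})

test_that("a zero-rate run reports perfect class C baselines", {
  d <- withr::local_tempdir()
  cfg <- pipeline_config(d)
  cfg$mask$rates <- 0
  cfg$imputers <- list(list(name = "mean"))
  res <- run_pipeline(cfg)
  m <- res$metrics
  expect_equal(m$value[m$metric == "sw_ks"], 0)
  expect_equal(m$value[m$metric == "sw_w2"], 0)
  expect_equal(m$value[m$metric == "sw_ratio_median"], 1)
  # class A/B have nothing to score without masked cells
  expect_false(any(m$metric == "rmse"))
})

test_that("config validation catches broken configs", {
  expect_error(validate_run_config(list(output_dir = "x",
                                        dataset = list(type = "synthetic_numeric"))),
               "seed")
  expect_error(validate_run_config(list(seed = 1,
                                        dataset = list(type = "synthetic_numeric"))),
               "output_dir")
  expect_error(run_pipeline(list(seed = 1, output_dir = tempdir(),
                                 dataset = list(type = "nope"))),
               "unknown dataset type")
  cfg <- list(seed = 1, output_dir = "x",
              dataset = list(type = "csv", path = "/nonexistent.csv",
                             schema_path = "/nonexistent.json"))
  expect_error(validate_run_config(cfg), "missing")
})

test_that("the CLI simulate/mask/score path runs end to end", {
  dir <- withr::local_tempdir()
  data_csv <- file.path(dir, "data.csv")
  mask_csv <- file.path(dir, "mask.csv")
  expect_output(missbench_cli(c("simulate", "--n", "40", "--d", "3",
                                "--seed", "1", "--out", data_csv)), "wrote")
  expect_output(missbench_cli(c("mask", "--data", data_csv, "--rate", "0.25",
                                "--seed", "2", "--out", mask_csv)), "masked cells")
  imp_dir <- file.path(dir, "imp")
  expect_output(missbench_cli(c("impute", "--data", data_csv, "--mask", mask_csv,
                                "--method", "mean", "--seed", "3",
                                "--out", imp_dir)), "wrote")
  report <- file.path(dir, "report.json")
  expect_output(missbench_cli(c("score", "--data", data_csv, "--mask", mask_csv,
                                "--imputed", file.path(imp_dir, "mean_completion01.csv"),
                                "--threshold", "2", "--seed", "4",
                                "--out", report)), "wrote")
  out <- jsonlite::read_json(report)
  expect_true(out$class_a$rmse >= 0)
  expect_error(missbench_cli(c("unknown")), "subcommand")
})
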