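#' Validate a run configuration
#'
#' A run configuration is a named list (typically read from YAML via
#' [read_run_config()]) describing one reproducible benchmark run:
#'
#' ```yaml
#' seed: 17
#' output_dir: out
#' dataset:
#'   type: synthetic_numeric        # or synthetic_mixed | csv
#'   n: 200
#'   d_informative: 10
#'   class_sep: 1.0
#' mask: {rates: [0.25, 0.5], policy: exact_count}
#' imputers:
#'   - {name: mean}
#'   - {name: mice, m: 5, n_iter: 10}
#' metrics: [class_a, class_b, class_c]
#' sw: {P: 10, outlier_threshold: 2.0}   # M defaults to 2d
#' downstream:
#'   enabled: false
#' ```
#'
#' All randomness is routed through the declared `seed`; no wall-clock
#' seeding occurs anywhere.
#'
#' @param config Named list.
#' @return The validated (default-filled) config, invisibly usable by
#'   [run_pipeline()].
#' @export
validate_run_config <- function(config) {
  defaults <- list(
    mask = list(rates = c(0.25, 0.5), policy = "exact_count"),
    imputers = list(list(name = "mean"), list(name = "mice")),
    metrics = c("class_a", "class_b", "class_c"),
    sw = list(P = 10L, outlier_threshold = 2.0),
    downstream = list(enabled = FALSE)
  )
  # top-level defaults fill missing keys; named sub-lists merge key-wise
  # (unnamed lists like `imputers` are replaced wholesale when supplied)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
               is.list(config[[nm]])) {
      config[[nm]] <- modifyList(defaults[[nm]], config[[nm]])
    }
  }
  if (is.null(config$seed)) stop_invalid("config must declare an explicit integer `seed`")
  if (is.null(config$output_dir)) stop_invalid("config must declare `output_dir`")
  if (is.null(config$dataset$type)) stop_invalid("config must declare dataset$type")
  if (config$dataset$type == "csv") {
    for (p in c(config$dataset$path, config$dataset$schema_path)) {
      if (is.null(p) || !file.exists(p)) stop_invalid("dataset csv/schema path missing: %s",
                                                      p %||% "(unset)")
    }
  }
  for (r in config$mask$rates) {
    if (r < 0 || r > 1) stop_invalid("mask rates must lie in [0, 1]")
  }
  config
}

#' @rdname validate_run_config
#' @param path YAML config path.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

config_dataset <- function(config) {
  ds <- config$dataset
  switch(ds$type,
    synthetic_numeric = generate_numeric(ds$n %||% 1000L, ds$d_informative %||% 25L,
                                         ds$class_sep %||% 1.0, seed = config$seed),
    synthetic_mixed = generate_mixed(ds$n %||% 1000L, ds$d_informative %||% 25L,
                                     ds$d_categorical %||% 2L, ds$d_ordinal %||% 2L,
                                     ds$d_uninformative %||% 3L, ds$class_sep %||% 1.0,
                                     seed = config$seed),
    csv = read_dataset_csv(ds$path, ds$schema_path),
    stop_invalid("unknown dataset type '%s'", ds$type))
}

config_imputer <- function(spec) {
  switch(spec$name,
    mean = imputer_mean(),
    mice = imputer_mice(m = spec$m %||% 5L, n_iter = spec$n_iter %||% 10L),
    stop_invalid("unknown imputer '%s'", spec$name))
}

long_row <- function(dataset, method, rate, completion, metric, value) {
  data.frame(dataset = dataset, method = method, rate_train = rate,
             rate_test = rate, completion_index = completion,
             metric = metric, value = value)
}

#' Execute a configured mask / impute / score run
#'
#' For every (rate, imputer) combination: induce MCAR missingness,
#' impute, and score the completions with the selected metric classes.
#' Metric rows accumulate in a long-format CSV
#' (`dataset, method, rate_train, rate_test, completion_index, metric,
#' value`); a JSON manifest records the seed, the full config and its
#' hash. A failing scenario is reported (stage and scenario tuple) and
#' the remaining scenarios continue.
#'
#' @param config Named list as for [validate_run_config()], or a YAML
#'   path.
#' @return Invisibly, a list with `metrics` (the long data.frame),
#'   `metrics_file`, `manifest_file`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- config_dataset(config)
  ds_name <- config$dataset$type
  d <- n_features(truth)
  M <- config$sw$M %||% default_n_directions(d)
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  for (rate in config$mask$rates) {
    mask <- induce_mcar(truth, rate, seed = config$seed + round(1000 * rate),
                        policy = config$mask$policy)
    incomplete <- apply_mask(truth, mask)
    for (imp_spec in config$imputers) {
      imputer <- config_imputer(imp_spec)
      scen <- sprintf("rate=%g imputer=%s", rate, imputer$name)
      res <- tryCatch({
        mimp <- imputer$impute(incomplete, seed = config$seed + 7L)
        any_masked <- any(mask$mask)
        if (!any_masked && length(intersect(config$metrics, c("class_a", "class_b")))) {
          note("[%s] no masked cells; class A/B have nothing to score", scen)
        }
        if (any_masked && "class_a" %in% config$metrics) {
          for (k in seq_len(mimp$m)) {
            a <- class_a_scores(truth, mimp$completions[[k]], mask)
            for (mt in c("rmse", "mae", "r_squared")) {
              add(long_row(ds_name, imputer$name, rate, k, mt, a[[mt]]))
            }
          }
        }
        if (any_masked && "class_b" %in% config$metrics) {
          for (k in seq_len(mimp$m)) {
            b <- class_b_report(truth, mimp$completions[[k]], mask)
            for (i in seq_len(nrow(b$summaries))) {
              s <- b$summaries[i, ]
              for (q in c("min", "median", "max")) {
                add(long_row(ds_name, imputer$name, rate, k,
                             sprintf("%s_%s", s$statistic, q), s[[q]]))
              }
            }
            if (length(b$skipped)) {
              note("[%s] class_b skipped features: %s", scen,
                   paste(b$skipped, collapse = ", "))
            }
          }
        }
        if ("class_c" %in% config$metrics) {
          dirs <- sample_directions(d, M, seed = config$seed + 11L)
          parts <- make_half_partitions(n_samples(truth), config$sw$P,
                                        seed = config$seed + 13L)
          tables <- lapply(mimp$completions, function(ck) {
            sw_distance_table(truth, ck, dirs, parts)
          })
          for (k in seq_along(tables)) {
            if (nrow(tables[[k]]$skipped)) {
              note("[%s] completion %d: %d degenerate (r,p) pairs skipped",
                   scen, k, nrow(tables[[k]]$skipped))
            }
            cc <- class_c_report(tables[[k]],
                                 outlier_threshold = config$sw$outlier_threshold)
            for (mt in c("kl", "ks", "w2")) {
              add(long_row(ds_name, imputer$name, rate, k,
                           sprintf("sw_%s", mt), cc$dist_discrepancy[[mt]]))
            }
            add(long_row(ds_name, imputer$name, rate, k, "sw_ratio_median",
                         cc$ratio_summary[["median"]]))
            add(long_row(ds_name, imputer$name, rate, k, "sw_outlier_proportion",
                         cc$outlier_proportion))
          }
          if (length(tables) >= 2L) {
            st <- stability_analysis(tables, threshold = config$sw$outlier_threshold)
            add(long_row(ds_name, imputer$name, rate, NA_integer_,
                         "sw_between_table_variance", st$between_table_variance))
          }
        }
        TRUE
      }, error = function(e) {
        note("[%s] scoring failed: %s", scen, conditionMessage(e))
        FALSE
      })
      invisible(res)
    }
  }

  if (isTRUE(config$downstream$enabled)) {
    plan <- make_split_plan(n_samples(truth),
                            config$downstream$n_repeats %||% 3L,
                            config$downstream$n_folds %||% 5L,
                            config$downstream$holdout_fraction %||% 0.25,
                            seed = config$seed + 23L)
    cls <- switch(config$downstream$classifier %||% "logistic",
                  logistic = classifier_logistic(),
                  random_forest = classifier_random_forest(),
                  stop_invalid("unknown classifier '%s'", config$downstream$classifier))
    for (pair in config$downstream$rates %||% list(c(0.25, 0.25), c(0.25, 0.5))) {
      pair <- unlist(pair)
      for (imp_spec in config$imputers) {
        imputer <- config_imputer(imp_spec)
        scen <- sprintf("downstream train=%g test=%g imputer=%s",
                        pair[1], pair[2], imputer$name)
        tryCatch({
          rec <- run_scenario(truth, plan, pair[1], pair[2], imputer, cls,
                              pooling = config$downstream$pooling %||% "average",
                              seed = config$seed + 29L)
          for (i in seq_len(nrow(rec))) {
            for (mt in c("auc", "accuracy", "brier", "precision",
                         "sensitivity", "specificity")) {
              add(data.frame(dataset = ds_name, method = imputer$name,
                             rate_train = pair[1], rate_test = pair[2],
                             completion_index = rec$repeat_id[i],
                             metric = paste0("downstream_", mt),
                             value = rec[[mt]][i]))
            }
          }
        }, error = function(e) note("[%s] failed: %s", scen, conditionMessage(e)))
      }
    }
  }

  metrics <- do.call(rbind, rows)
  metrics_file <- file.path(config$output_dir, "metrics.csv")
  out <- metrics
  out$value <- fmt_num(out$value)
  write.table(out, metrics_file, sep = ",", quote = FALSE, row.names = FALSE)
  manifest_file <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(list(seed = config$seed, config = config,
                            config_hash = rlang::hash(config),
                            log = log_lines),
                       manifest_file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(metrics = metrics, metrics_file = metrics_file,
                 manifest_file = manifest_file))
}
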