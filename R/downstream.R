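#' Area under the ROC curve
#'
#' Mann--Whitney formulation: the probability that a random positive
#' scores above a random negative, with tied scores contributing one
#' half.
#'
#' @param labels 0/1 vector containing both classes.
#' @param scores Numeric score vector (higher = more positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(labels, scores) {
  labels <- as.numeric(labels)
  if (length(labels) != length(scores)) stop_invalid("labels and scores lengths differ")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_invalid("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold-based classification performance metrics
#'
#' Confusion-matrix metrics at a probability threshold plus the Brier
#' score (mean squared difference between predicted probability and
#' outcome) and AUC. Predictions are positive when
#' `score >= threshold`. Precision is `NA` when nothing is predicted
#' positive.
#'
#' @param labels 0/1 vector containing both classes.
#' @param scores Probability vector in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return Named list: `auc`, `accuracy`, `brier`, `precision`,
#'   `sensitivity`, `specificity`.
#' @export
performance_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.numeric(labels)
  if (any(scores < 0 | scores > 1)) stop_invalid("scores must lie in [0, 1]")
  auc <- auc_roc(labels, scores)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  list(auc = auc,
       accuracy = (tp + tn) / length(labels),
       brier = mean((scores - labels)^2),
       precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp))
}

#' Sample skewness (moment definition)
#'
#' `g1 = m3 / m2^(3/2)` with central moments computed with divisor
#' `n` (the biased moment form). Zero for symmetric samples; used to
#' flag asymmetry in feature-importance value distributions, which for
#' symmetric-by-design simulated data indicates a distorted model.
#'
#' @param values Numeric vector, `n >= 3`, non-constant.
#' @return Skewness `g1`.
#' @export
skewness <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop_invalid("need at least 3 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop_invalid("skewness undefined for constant values")
  mean((values - m)^3) / m2^1.5
}

#' Correlate imputation discrepancy with downstream performance
#'
#' Pearson correlation plus the least-squares trend slope of
#' performance on discrepancy. The caller groups inputs (e.g. by test
#' missingness rate) before calling, since the relationship differs by
#' scenario.
#'
#' @param discrepancy,performance Equal-length numeric vectors
#'   (`n >= 3`), each with positive variance.
#' @return List with `correlation`, `slope`, `n`.
#' @export
correlate_quality_vs_performance <- function(discrepancy, performance) {
  if (length(discrepancy) != length(performance) || length(discrepancy) < 3L) {
    stop_invalid("need equal-length vectors with at least 3 points")
  }
  if (var(discrepancy) == 0 || var(performance) == 0) {
    stop_invalid("correlation undefined: zero variance")
  }
  list(correlation = cor(discrepancy, performance),
       slope = cov(discrepancy, performance) / var(discrepancy),
       n = length(discrepancy))
}

#' Imputer specifications for the harness
#'
#' An imputer spec is a name plus a function
#' `impute(incomplete_dataset, seed)` returning an `mb_mimp`.
#' `imputer_mean()` wraps deterministic column mean/mode imputation
#' (`m = 1`); `imputer_mice()` wraps chained-equations multiple
#' imputation.
#'
#' @param name Label used in reports.
#' @param impute Function `(incomplete, seed) -> mb_mimp`.
#' @return An object of class `mb_imputer`.
#' @export
imputer_spec <- function(name, impute) {
  structure(list(name = name, impute = impute), class = "mb_imputer")
}

#' @rdname imputer_spec
#' @export
imputer_mean <- function() {
  imputer_spec("mean", function(incomplete, seed) impute_mean(incomplete))
}

#' @rdname imputer_spec
#' @param m,n_iter Passed to [impute_chained_equations()].
#' @export
imputer_mice <- function(m = 5L, n_iter = 10L) {
  imputer_spec("mice", function(incomplete, seed) {
    impute_chained_equations(incomplete, m = m, n_iter = n_iter, seed = seed)
  })
}

#' Run one train/test missingness scenario end to end
#'
#' For each development/holdout repeat of the split plan: mask the
#' development rows at `train_rate` and the holdout rows at
#' `test_rate` (MCAR, exact count), impute each part (`m` completions),
#' select the classifier hyperparameters by cross-validated AUC
#' (averaged over folds and completions), refit the selected
#' configuration on the full development set per completion, score the
#' holdout per completion, pool the scores, and record performance.
#' Rates of zero reproduce training/testing on the complete data.
#'
#' Validation folds whose labels are single-class are skipped with a
#' warning; hyperparameter ties resolve to the first grid point in
#' declaration order.
#'
#' @param truth Complete labelled [mb_dataset()].
#' @param split An `mb_split_plan` for `nrow(truth$values)` samples.
#' @param train_rate,test_rate MCAR rates in `[0, 1]` for the
#'   development and holdout parts.
#' @param imputer An `mb_imputer`.
#' @param classifier An `mb_classifier`.
#' @param pooling `"average"` (default) or `"majority"`.
#' @param seed Integer seed driving masking and imputation.
#' @return data.frame with one row per repeat: scenario tuple plus
#'   `auc`, `accuracy`, `brier`, `precision`, `sensitivity`,
#'   `specificity`.
#' @export
run_scenario <- function(truth, split, train_rate, test_rate, imputer,
                         classifier, pooling = c("average", "majority"), seed) {
  pooling <- match.arg(pooling)
  if (is.null(truth$labels)) stop_invalid("dataset must carry labels")
  if (!inherits(split, "mb_split_plan")) stop_invalid("`split` must be an mb_split_plan")
  if (!inherits(imputer, "mb_imputer")) stop_invalid("`imputer` must be an mb_imputer")
  if (!inherits(classifier, "mb_classifier")) stop_invalid("`classifier` must be an mb_classifier")
  for (rt in c(train_rate, test_rate)) {
    if (rt < 0 || rt > 1) stop_invalid("rates must lie in [0, 1]")
  }
  grid <- grid_points(classifier)
  rows <- list()
  for (rep_i in seq_len(split$n_repeats)) {
    sub_seed <- function(k) (as.integer(seed) * 131L + rep_i * 17L + k) %% .Machine$integer.max
    hold_idx <- split$repeats[[rep_i]]$holdout
    fold <- split$repeats[[rep_i]]$fold
    dev_idx <- dev_indices(split, rep_i)
    dev_ds <- subset_rows(truth, dev_idx)
    hold_ds <- subset_rows(truth, hold_idx)
    imp_dev <- impute_part(dev_ds, train_rate, imputer, sub_seed(1L), sub_seed(2L))
    imp_hold <- impute_part(hold_ds, test_rate, imputer, sub_seed(3L), sub_seed(4L))
    y_dev <- dev_ds$labels
    y_hold <- hold_ds$labels

    best <- select_grid_point(grid, classifier, imp_dev, y_dev, fold, split$n_folds)
    hold_scores <- lapply(seq_along(imp_dev), function(k) {
      model <- classifier$fit(imp_dev[[k]], y_dev, best)
      classifier$predict(model, imp_hold[[min(k, length(imp_hold))]])
    })
    pooled <- pool_predictions(hold_scores, method = pooling)
    perf <- performance_metrics(y_hold, pooled)
    rows[[rep_i]] <- data.frame(
      repeat_id = rep_i, train_rate = train_rate, test_rate = test_rate,
      imputer = imputer$name, classifier = classifier$name, pooling = pooling,
      auc = perf$auc, accuracy = perf$accuracy, brier = perf$brier,
      precision = perf$precision, sensitivity = perf$sensitivity,
      specificity = perf$specificity)
  }
  do.call(rbind, rows)
}

# mask a dataset part at `rate` and return the list of completions
# (rate 0 short-circuits to the complete data)
impute_part <- function(part, rate, imputer, mask_seed, impute_seed) {
  if (rate == 0) return(list(part$values))
  mask <- induce_mcar(part, rate, seed = mask_seed)
  mimp <- imputer$impute(apply_mask(part, mask), seed = impute_seed)
  mimp$completions
}

select_grid_point <- function(grid, classifier, completions, y, fold, n_folds) {
  if (length(grid) == 1L) return(grid[[1L]])
  val_auc <- vapply(grid, function(params) {
    aucs <- c()
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      va <- !tr
      if (length(unique(y[va])) < 2L || length(unique(y[tr])) < 2L) {
        warning(sprintf("fold %d skipped: single-class labels", f), call. = FALSE)
        next
      }
      for (ck in completions) {
        model <- classifier$fit(ck[tr, , drop = FALSE], y[tr], params)
        aucs <- c(aucs, auc_roc(y[va], classifier$predict(model, ck[va, , drop = FALSE])))
      }
    }
    if (!length(aucs)) NA_real_ else mean(aucs)
  }, numeric(1))
  if (all(is.na(val_auc))) stop_invalid("no usable validation fold in grid search")
  grid[[which.max(val_auc)]]  # ties -> first grid point in declaration order
}
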