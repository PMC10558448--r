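#' Classifier specifications for the benchmarking harness
#'
#' A classifier spec bundles a name, a hyperparameter grid and a
#' fit/predict contract: `fit(x, y, params)` consumes a complete
#' training matrix plus 0/1 labels and returns a fitted model;
#' `predict(model, x)` returns `P(class = 1)` per row, in `[0, 1]`.
#' Any external classifier honouring this contract plugs into
#' [run_scenario()].
#'
#' `classifier_logistic()` is a maximum-likelihood logistic fit (no
#' tunable hyperparameters; its grid has a single point).
#' `classifier_random_forest()` is a randomised tree ensemble
#' (\pkg{ranger}) with a small default grid over `num_trees` and
#' `mtry`.
#'
#' @param name Label used in reports.
#' @param grid Named list mapping parameter name to candidate values;
#'   must be non-empty (use a single dummy point for untunable
#'   models).
#' @param fit,predict Functions implementing the contract.
#' @return An object of class `mb_classifier`.
#' @export
classifier_spec <- function(name, grid, fit, predict) {
  if (!is.list(grid) || length(grid) < 1L || any(lengths(grid) < 1L)) {
    stop_invalid("hyperparameter grid must be a non-empty named list")
  }
  structure(list(name = name, grid = grid, fit = fit, predict = predict),
            class = "mb_classifier")
}

#' @rdname classifier_spec
#' @export
classifier_logistic <- function() {
  classifier_spec(
    name = "logistic",
    grid = list(intercept = TRUE),
    fit = function(x, y, params) {
      suppressWarnings(glm.fit(cbind(1, x), y, family = binomial()))
    },
    predict = function(model, x) {
      beta <- ifelse(is.na(model$coefficients), 0, model$coefficients)
      plogis(drop(cbind(1, x) %*% beta))
    }
  )
}

#' @rdname classifier_spec
#' @param num_trees,mtry Candidate values for the random-forest grid.
#' @param seed Seed passed to each forest fit (kept fixed so the grid
#'   search compares hyperparameters, not RNG draws).
#' @export
classifier_random_forest <- function(num_trees = c(100L, 300L),
                                     mtry = NULL, seed = 1L) {
  classifier_spec(
    name = "random_forest",
    grid = list(num_trees = num_trees,
                mtry = if (is.null(mtry)) NA_integer_ else mtry),
    fit = function(x, y, params) {
      df <- as.data.frame(x)
      df$.outcome <- factor(y, levels = c(0, 1))
      mtry_val <- if (is.na(params$mtry)) max(1L, floor(sqrt(ncol(x)))) else params$mtry
      ranger::ranger(.outcome ~ ., data = df, probability = TRUE,
                     num.trees = params$num_trees, mtry = mtry_val,
                     seed = seed, num.threads = 1L)
    },
    predict = function(model, x) {
      pr <- stats::predict(model, data = as.data.frame(x),
                           num.threads = 1L)$predictions
      pr[, "1"]
    }
  )
}

grid_points <- function(spec) {
  g <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}
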