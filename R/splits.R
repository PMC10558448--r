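#' Build a two-level development/holdout + cross-validation split plan
#'
#' The evaluation design partitions a dataset at two levels: first into
#' several independent development/holdout splits (so that conclusions
#' do not rest on one holdout cohort), then each development set into
#' `n_folds` cross-validation folds with fold sizes differing by at most
#' one. Defaults follow the benchmark design of three repeats and five
#' folds.
#'
#' @param n_samples Number of samples (`>= 2 * n_folds`).
#' @param n_repeats Number of independent development/holdout splits.
#' @param n_folds Number of cross-validation folds within each
#'   development set.
#' @param holdout_fraction Fraction of samples held out per repeat, in
#'   `(0, 1)`.
#' @param seed Integer seed; repeats use independent draws from one
#'   stream.
#' @return An object of class `mb_split_plan`: list with `n_repeats`,
#'   `n_folds`, `holdout_fraction`, `seed` and `repeats`, where each
#'   repeat holds `holdout` (index vector) and `fold` (fold label in
#'   `1..n_folds` for every development index, named by index).
#' @export
make_split_plan <- function(n_samples, n_repeats = 3L, n_folds = 5L,
                            holdout_fraction = 0.25, seed) {
  check_counts(n_samples = n_samples, n_repeats = n_repeats, n_folds = n_folds)
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop_invalid("holdout_fraction must be in (0, 1)")
  }
  if (n_samples < 2L * n_folds) stop_invalid("need n_samples >= 2 * n_folds")
  n_hold <- round(holdout_fraction * n_samples)
  if (n_samples - n_hold < n_folds) {
    stop_invalid("development set (%d) smaller than n_folds (%d)",
                 n_samples - n_hold, n_folds)
  }
  reps <- with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      holdout <- sort(sample.int(n_samples, n_hold))
      dev <- setdiff(seq_len(n_samples), holdout)
      fold <- sample(rep(seq_len(n_folds), length.out = length(dev)))
      names(fold) <- dev
      list(holdout = holdout, fold = fold)
    })
  })
  structure(list(n_repeats = as.integer(n_repeats), n_folds = as.integer(n_folds),
                 holdout_fraction = holdout_fraction, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), repeats = reps),
            class = "mb_split_plan")
}

#' @export
print.mb_split_plan <- function(x, ...) {
  cat(sprintf("<mb_split_plan> %d samples, %d repeats, %d folds, holdout fraction %.2f\n",
              x$n_samples, x$n_repeats, x$n_folds, x$holdout_fraction))
  invisible(x)
}

dev_indices <- function(plan, r) as.integer(names(plan$repeats[[r]]$fold))

#' Serialise / load a split plan as JSON
#'
#' Index sets are written 0-based (documented in the file itself via a
#' `"index_base": 0` field) for interoperability with non-R tooling.
#'
#' @param plan An `mb_split_plan`.
#' @param path JSON path.
#' @return `write_split_plan_json()` returns `path` invisibly;
#'   `read_split_plan_json()` returns an `mb_split_plan`.
#' @export
write_split_plan_json <- function(plan, path) {
  reps <- lapply(plan$repeats, function(r) {
    list(holdout = r$holdout - 1L,
         development = as.integer(names(r$fold)) - 1L,
         fold = unname(r$fold))
  })
  jsonlite::write_json(
    list(index_base = 0L, n_samples = plan$n_samples, n_repeats = plan$n_repeats,
         n_folds = plan$n_folds, holdout_fraction = plan$holdout_fraction,
         seed = plan$seed, repeats = reps),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan_json
#' @export
read_split_plan_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  reps <- lapply(seq_len(raw$n_repeats), function(i) {
    r <- if (is.data.frame(raw$repeats)) {
      list(holdout = raw$repeats$holdout[[i]],
           development = raw$repeats$development[[i]],
           fold = raw$repeats$fold[[i]])
    } else raw$repeats[[i]]
    fold <- as.integer(r$fold)
    names(fold) <- as.integer(r$development) + 1L
    list(holdout = as.integer(r$holdout) + 1L, fold = fold)
  })
  structure(list(n_repeats = raw$n_repeats, n_folds = raw$n_folds,
                 holdout_fraction = raw$holdout_fraction,
                 n_samples = raw$n_samples,
                 seed = if (is.null(raw$seed)) NA_integer_ else raw$seed,
                 repeats = reps),
            class = "mb_split_plan")
}
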