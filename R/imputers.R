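#' Multiple-imputation container
#'
#' Holds `m` completed copies of an incomplete value matrix, all sharing
#' one missingness mask. Every completion must agree bit-exactly with
#' the original observed cells and contain no remaining missing cells.
#'
#' @param completions List of `m >= 1` numeric matrices.
#' @param mask The `mb_mask` the completions fill in.
#' @param method_name Imputation method label.
#' @param seed Seed used by the imputer (`NA` for deterministic ones).
#' @param original The incomplete matrix (observed cells + `NA`); used
#'   to validate observed-cell preservation when supplied.
#' @return An object of class `mb_mimp` with elements `completions`,
#'   `mask`, `method_name`, `m`, `seed`.
#' @export
multiple_imputation <- function(completions, mask, method_name, seed = NA_integer_,
                                original = NULL) {
  if (!is.list(completions) || length(completions) < 1L) {
    stop_invalid("need a non-empty list of completions")
  }
  m <- mask_matrix(mask)
  completions <- lapply(completions, function(x) {
    x <- as.matrix(x); storage.mode(x) <- "double"; x
  })
  for (k in seq_along(completions)) {
    ck <- completions[[k]]
    if (!identical(dim(ck), dim(m))) {
      stop_invalid("completion %d shape does not match mask", k)
    }
    if (anyNA(ck)) stop_invalid("completion %d still contains missing cells", k)
    if (!is.null(original)) {
      obs <- !m & !is.na(original)
      bad <- which(obs & (ck != original))
      if (length(bad)) {
        rc <- arrayInd(bad[1], dim(m))
        stop_invalid("completion %d altered observed cell at row %d, column %d",
                     k, rc[1], rc[2])
      }
    }
  }
  structure(list(completions = completions,
                 mask = if (inherits(mask, "mb_mask")) mask else
                   structure(list(mask = m, rate = mean(m), seed = NA_integer_,
                                  policy = "exact_count"), class = "mb_mask"),
                 method_name = method_name, m = length(completions),
                 seed = as.integer(seed)),
            class = "mb_mimp")
}

#' @export
print.mb_mimp <- function(x, ...) {
  cat(sprintf("<mb_mimp> method '%s', m = %d completions of %d x %d (%d imputed cells each)\n",
              x$method_name, x$m, nrow(x$mask$mask), ncol(x$mask$mask),
              sum(x$mask$mask)))
  invisible(x)
}

# column summaries used for initialisation and fallbacks ---------------

col_mode <- function(x, levels) {
  # observed mode; ties broken towards the smallest level code
  tab <- table(factor(x, levels = levels))
  as.numeric(levels[which.max(tab)])
}

fill_value <- function(obs, fs) {
  if (is_coded(fs)) col_mode(obs, fs$levels) else mean(obs)
}

nearest_level <- function(x, levels) {
  levels[max.col(-abs(outer(x, levels, `-`)), ties.method = "first")]
}

incomplete_parts <- function(incomplete) {
  vals <- as_values(incomplete)
  schema <- if (inherits(incomplete, "mb_dataset")) incomplete$schema else
    lapply(colnames(vals) %||% sprintf("f%02d", seq_len(ncol(vals))),
           feature_schema, kind = "continuous")
  mask <- is.na(vals)
  list(vals = vals, schema = schema, mask = mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Column mean / mode imputation
#'
#' Each missing cell receives its column's observed mean (continuous
#' columns) or observed mode (coded columns; ties go to the smallest
#' level code). Deterministic single imputation (`m = 1`).
#'
#' @param incomplete An [mb_dataset()] (or matrix) containing `NA`
#'   cells.
#' @return An `mb_mimp` with one completion.
#' @export
impute_mean <- function(incomplete) {
  p <- incomplete_parts(incomplete)
  vals <- p$vals
  for (j in seq_len(ncol(vals))) {
    mis <- p$mask[, j]
    if (!any(mis)) next
    obs <- vals[!mis, j]
    if (length(obs) < 1L) {
      stop_invalid("column '%s' is fully missing; mean imputation undefined",
                   p$schema[[j]]$name)
    }
    vals[mis, j] <- fill_value(obs, p$schema[[j]])
  }
  multiple_imputation(list(vals),
                      structure(list(mask = p$mask, rate = mean(p$mask),
                                     seed = NA_integer_, policy = "exact_count"),
                                class = "mb_mask"),
                      "mean", original = p$vals)
}

#' Multiple imputation by chained equations
#'
#' Initialises missing cells by column mean/mode, then performs
#' `n_iter` sweeps in which each incomplete column (visited
#' left-to-right) is regressed on all other columns using the rows
#' where it is observed, and its missing entries are redrawn from the
#' fitted conditional: linear regression plus a Gaussian residual draw
#' for continuous columns, logistic regression plus a Bernoulli draw for
#' binary-coded columns, and linear regression projected to the nearest
#' level for coded columns with more than two levels. `m` independent
#' chains give `m` completions. Degenerate regressions (e.g. constant
#' predictors) fall back to a mean/mode draw with a warning rather than
#' failing.
#'
#' @param incomplete An [mb_dataset()] (or matrix) containing `NA`
#'   cells; every column needs at least two observed values.
#' @param m Number of completions (chains).
#' @param n_iter Sweeps per chain.
#' @param seed Integer seed; the full set of chains is deterministic
#'   given the seed.
#' @return An `mb_mimp` with `m` completions.
#' @export
impute_chained_equations <- function(incomplete, m = 5L, n_iter = 10L, seed) {
  check_counts(m = m, n_iter = n_iter)
  p <- incomplete_parts(incomplete)
  n_obs_col <- colSums(!p$mask)
  if (any(n_obs_col < 2L)) {
    stop_invalid("column '%s' has fewer than 2 observed values",
                 p$schema[[which(n_obs_col < 2L)[1]]]$name)
  }
  incomplete_cols <- which(colSums(p$mask) > 0L)
  init <- p$vals
  for (j in incomplete_cols) {
    init[p$mask[, j], j] <- fill_value(p$vals[!p$mask[, j], j], p$schema[[j]])
  }
  completions <- with_seed(seed, {
    lapply(seq_len(m), function(chain) {
      x <- init
      for (it in seq_len(n_iter)) {
        for (j in incomplete_cols) {
          x[p$mask[, j], j] <- draw_column(x, p$vals, p$mask, j, p$schema[[j]])
        }
      }
      x
    })
  })
  multiple_imputation(completions,
                      structure(list(mask = p$mask, rate = mean(p$mask),
                                     seed = NA_integer_, policy = "exact_count"),
                                class = "mb_mask"),
                      "mice", seed = seed, original = p$vals)
}

# one chained-equations update of column j's missing entries
draw_column <- function(x, orig, mask, j, fs) {
  mis <- mask[, j]
  obs <- !mis
  y <- orig[obs, j]
  design <- cbind(1, x[, -j, drop = FALSE])
  fallback <- function() {
    # degenerate design: draw around the observed mean/mode
    if (is_coded(fs)) {
      rep(col_mode(y, fs$levels), sum(mis))
    } else {
      rnorm(sum(mis), mean(y), sd(y))
    }
  }
  degenerate <- function(why) {
    warning(sprintf("chained equations: column '%s' degenerate (%s); using mean/mode draw",
                    fs$name, why), call. = FALSE)
    fallback()
  }
  tryCatch({
    binary <- is_coded(fs) && length(fs$levels) == 2L
    if (binary) {
      yb <- as.numeric(y == fs$levels[2])
      fit <- suppressWarnings(glm.fit(design[obs, , drop = FALSE], yb,
                                      family = binomial()))
      if (fit$rank <= 1L) return(degenerate("constant predictors"))
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      pr <- plogis(drop(design[mis, , drop = FALSE] %*% beta))
      fs$levels[1 + rbinom(sum(mis), 1L, pr)]
    } else {
      fit <- lm.fit(design[obs, , drop = FALSE], y)
      if (fit$rank <= 1L) return(degenerate("constant predictors"))
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      dfree <- max(1L, length(y) - fit$rank)
      sigma <- sqrt(sum(fit$residuals^2) / dfree)
      pred <- drop(design[mis, , drop = FALSE] %*% beta)
      val <- pred + rnorm(sum(mis), 0, sigma)
      if (is_coded(fs)) nearest_level(val, fs$levels) else val
    }
  }, error = function(e) degenerate(conditionMessage(e)))
}

#' Pool classifier outputs across multiple imputations
#'
#' The classification task is run once per completion and the per-
#' completion outputs are pooled: `"average"` returns the element-wise
#' mean probability; `"majority"` thresholds each probability vector at
#' 0.5 and returns the modal 0/1 label (ties go to the positive class).
#'
#' @param per_imputation_scores List of `m >= 1` equal-length
#'   probability vectors in `[0, 1]`.
#' @param method `"average"` or `"majority"`.
#' @return Numeric vector: pooled probabilities (average) or pooled 0/1
#'   labels (majority).
#' @export
pool_predictions <- function(per_imputation_scores, method = c("average", "majority")) {
  method <- match.arg(method)
  if (!is.list(per_imputation_scores) || length(per_imputation_scores) < 1L) {
    stop_invalid("need a non-empty list of score vectors")
  }
  len <- unique(lengths(per_imputation_scores))
  if (length(len) != 1L) stop_invalid("score vectors must have equal length")
  s <- do.call(cbind, per_imputation_scores)
  if (anyNA(s) || any(s < 0 | s > 1)) stop_invalid("scores must lie in [0, 1]")
  if (method == "average") {
    rowMeans(s)
  } else {
    votes <- rowSums(s >= 0.5)
    as.numeric(2 * votes >= ncol(s))
  }
}

#' Wrap externally produced completions as a validated container
#'
#' Adapter for scoring imputations produced outside the package (e.g.
#' random-forest, autoencoder or adversarial imputers): any set of
#' completed matrices can be registered, provided the observed cells
#' are untouched and no missing sentinels remain.
#'
#' @param completions List of completed matrices.
#' @param mask The `mb_mask` that was applied to the original data.
#' @param name Method label for reports.
#' @param original Optional incomplete matrix (observed values + `NA`)
#'   against which observed-cell preservation is enforced.
#' @return An `mb_mimp`.
#' @export
register_external_imputation <- function(completions, mask, name, original = NULL) {
  multiple_imputation(completions, mask, name, original = original)
}

#' Write a multiple-imputation container to disk
#'
#' Each completion becomes a CSV mirroring the input header; a JSON
#' manifest records the method, `m`, seed and mask file.
#'
#' @param mimp An `mb_mimp`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the manifest path.
#' @export
write_imputation <- function(mimp, dir, prefix = mimp$method_name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(mimp$m)
  for (k in seq_len(mimp$m)) {
    files[k] <- file.path(dir, sprintf("%s_completion%02d.csv", prefix, k))
    m <- apply(mimp$completions[[k]], 2, fmt_num)
    colnames(m) <- colnames(mimp$completions[[k]])
    write.table(m, files[k], sep = ",", quote = FALSE, row.names = FALSE)
  }
  mask_file <- file.path(dir, sprintf("%s_mask.csv", prefix))
  write_mask_csv(mimp$mask, mask_file)
  manifest <- file.path(dir, sprintf("%s_manifest.json", prefix))
  jsonlite::write_json(list(method = mimp$method_name, m = mimp$m,
                            seed = mimp$seed, mask_file = basename(mask_file),
                            completion_files = basename(files)),
                       manifest, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
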