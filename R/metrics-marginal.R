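#' Two-sample Kolmogorov--Smirnov statistic
#'
#' Supremum absolute difference between the two empirical CDFs,
#' evaluated (right-continuously) at the union of the sample points.
#' Exact under ties.
#'
#' @param a,b Non-empty numeric samples.
#' @return Statistic in `[0, 1]`.
#' @export
ks_statistic <- function(a, b) {
  check_samples(a, b)
  pts <- sort(unique(c(a, b)))
  fa <- findInterval(pts, sort(a)) / length(a)
  fb <- findInterval(pts, sort(b)) / length(b)
  max(abs(fa - fb))
}

#' One-dimensional 2-Wasserstein distance between empirical samples
#'
#' The 2-Wasserstein (Mallows' L2) distance between the empirical
#' distributions of `a` and `b`, computed by inverse-CDF (quantile
#' function) integration. Sample sizes may differ; equal sizes reduce
#' to the root mean square of sorted-order differences.
#'
#' @param a,b Non-empty numeric samples.
#' @return Non-negative distance.
#' @export
wasserstein2_1d <- function(a, b) {
  check_samples(a, b)
  a <- sort(a)
  b <- sort(b)
  n <- length(a)
  m <- length(b)
  if (n == m) return(sqrt(mean((a - b)^2)))
  # both quantile functions are piecewise constant on intervals whose
  # endpoints are multiples of 1/n or 1/m; evaluate at interval midpoints
  brk <- sort(unique(c(seq_len(n) / n, seq_len(m) / m)))
  dt <- diff(c(0, brk))
  u <- brk - dt / 2
  qa <- a[floor(u * n) + 1L]
  qb <- b[floor(u * m) + 1L]
  sqrt(sum(dt * (qa - qb)^2))
}

#' Kullback--Leibler divergence between two samples
#'
#' `KL(P_a || P_b)` estimated on a shared equal-width histogram
#' spanning the pooled range, with additive `epsilon` smoothing
#' followed by renormalisation (so both histograms are proper
#' distributions and the divergence is non-negative). Reported in nats.
#'
#' @param a,b Non-empty numeric samples.
#' @param bins Number of histogram bins.
#' @param epsilon Additive smoothing mass per bin.
#' @return Non-negative divergence (0 when the pooled range is
#'   degenerate, which can only happen for identical constants).
#' @export
kl_divergence <- function(a, b, bins = 30L, epsilon = 1e-10) {
  check_samples(a, b)
  check_counts(bins = bins)
  if (epsilon <= 0) stop_invalid("epsilon must be positive")
  rng <- range(c(a, b))
  if (diff(rng) == 0) return(0)
  brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  hist_mass <- function(x) {
    cnt <- tabulate(findInterval(x, brk, rightmost.closed = TRUE,
                                 all.inside = TRUE), bins)
    p <- cnt / length(x) + epsilon
    p / sum(p)
  }
  pa <- hist_mass(a)
  pb <- hist_mass(b)
  sum(pa * log(pa / pb))
}

check_samples <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop_invalid("samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop_invalid("samples must not contain NA")
  invisible(NULL)
}

#' All three two-sample discrepancies at once
#'
#' Convenience wrapper returning the Kullback--Leibler divergence,
#' Kolmogorov--Smirnov statistic and 1-D 2-Wasserstein distance between
#' two samples, the triple used for both feature-wise (class B) scoring
#' and the sliced-Wasserstein distance-distribution (class C)
#' comparison.
#'
#' @inheritParams kl_divergence
#' @return List with `kl`, `ks`, `w2`.
#' @export
two_sample_score <- function(a, b, bins = 30L, epsilon = 1e-10) {
  list(kl = kl_divergence(a, b, bins = bins, epsilon = epsilon),
       ks = ks_statistic(a, b),
       w2 = wasserstein2_1d(a, b))
}

#' Feature-wise (class B) distributional discrepancy report
#'
#' For each feature, compares the distribution of true values against
#' imputed values — at the masked positions only (default
#' `missing_only` mode, which targets how well the *missing* values'
#' distribution is recreated) or over the whole column (`full_feature`
#' mode, which compares the complete reconstructed marginal). Because
#' the scores are computed feature by feature, the report also
#' summarises the minimum, median and maximum of each statistic over
#' features.
#'
#' In `missing_only` mode, features with fewer than two masked cells
#' cannot be scored and are listed in `skipped`.
#'
#' @param truth Complete ground-truth [mb_dataset()] (or matrix).
#' @param imputed Completed matrix (one completion).
#' @param mask The `mb_mask` that was applied.
#' @param mode `"missing_only"` or `"full_feature"`.
#' @param bins,epsilon Passed to [kl_divergence()].
#' @return List of class `mb_class_b`: `per_feature` (data.frame with
#'   columns `feature`, `kl`, `ks`, `w2`), `summaries` (data.frame with
#'   `min`, `median`, `max` per statistic), `skipped` (character),
#'   `mode`.
#' @export
class_b_report <- function(truth, imputed, mask,
                           mode = c("missing_only", "full_feature"),
                           bins = 30L, epsilon = 1e-10) {
  mode <- match.arg(mode)
  tv <- as_values(truth)
  iv <- as_values(imputed)
  m <- mask_matrix(mask)
  if (!identical(dim(tv), dim(iv)) || !identical(dim(tv), dim(m))) {
    stop_invalid("truth, imputed and mask shapes must agree")
  }
  nms <- colnames(tv) %||% sprintf("f%02d", seq_len(ncol(tv)))
  rows <- list()
  skipped <- character(0)
  for (j in seq_len(ncol(tv))) {
    if (mode == "missing_only") {
      sel <- m[, j]
      if (sum(sel) < 2L) {
        skipped <- c(skipped, nms[j])
        next
      }
      a <- tv[sel, j]
      b <- iv[sel, j]
    } else {
      a <- tv[, j]
      b <- iv[, j]
    }
    sc <- two_sample_score(a, b, bins = bins, epsilon = epsilon)
    rows[[length(rows) + 1L]] <- data.frame(feature = nms[j], kl = sc$kl,
                                            ks = sc$ks, w2 = sc$w2)
  }
  if (!length(rows)) stop_invalid("no feature has enough masked cells to score")
  per_feature <- do.call(rbind, rows)
  summaries <- do.call(rbind, lapply(c("kl", "ks", "w2"), function(stat) {
    v <- per_feature[[stat]]
    data.frame(statistic = stat, min = min(v), median = median(v), max = max(v))
  }))
  structure(list(per_feature = per_feature, summaries = summaries,
                 skipped = skipped, mode = mode),
            class = "mb_class_b")
}

#' @export
print.mb_class_b <- function(x, ...) {
  cat(sprintf("<mb_class_b> mode '%s', %d features scored%s\n", x$mode,
              nrow(x$per_feature),
              if (length(x$skipped)) sprintf(" (%d skipped)", length(x$skipped)) else ""))
  print(x$summaries, row.names = FALSE)
  invisible(x)
}
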