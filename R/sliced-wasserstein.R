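#' Sample random projection directions on the unit sphere
#'
#' Draws `M` independent directions uniformly on the unit sphere in
#' `d` dimensions (isotropic Gaussian draws, normalised). Projecting
#' onto many random directions probes the joint distribution along axes
#' other than the features themselves, which is what lets the sliced
#' discrepancy detect structure that every marginal misses. At least as
#' many directions as dimensions are required.
#'
#' @param d Data dimension (`>= 1`).
#' @param M Number of directions (`>= d`).
#' @param seed Integer seed.
#' @return Object of class `mb_directions`: list with `directions`
#'   (`M x d` matrix of unit rows), `d`, `M`, `seed`.
#' @export
sample_directions <- function(d, M, seed) {
  check_counts(d = d, M = M)
  if (M < d) stop_invalid("need M >= d directions (got M = %d < d = %d)", M, d)
  dirs <- with_seed(seed, {
    g <- matrix(rnorm(M * d), M, d)
    g / sqrt(rowSums(g^2))
  })
  structure(list(directions = dirs, d = as.integer(d), M = as.integer(M),
                 seed = as.integer(seed)),
            class = "mb_directions")
}

#' Draw random half-partitions of the sample index set
#'
#' Each partition splits `{1, ..., N}` into two disjoint subsets
#' `I_p` and `J_p` of sizes `ceiling(N/2)` and `floor(N/2)` (equal for
#' even `N`; `(N+1)/2` and `(N-1)/2` for odd `N`). `I_p` later serves
#' as the reference half, `J_p` as the half that gets replaced by
#' imputed data.
#'
#' @param N Number of samples (`>= 4`).
#' @param P Number of partitions (default 10, the benchmark design
#'   value).
#' @param seed Integer seed.
#' @return Object of class `mb_partitions`: list with `pairs` (list of
#'   `list(I, J)`), `N`, `P`, `seed`.
#' @export
make_half_partitions <- function(N, P = 10L, seed) {
  check_counts(N = N, P = P)
  if (N < 4L) stop_invalid("need N >= 4 samples to form half-partitions")
  pairs <- with_seed(seed, {
    lapply(seq_len(P), function(p) {
      perm <- sample.int(N)
      list(I = sort(perm[seq_len(ceiling(N / 2))]),
           J = sort(perm[(ceiling(N / 2) + 1L):N]))
    })
  })
  structure(list(pairs = pairs, N = as.integer(N), P = as.integer(P),
                 seed = as.integer(seed)),
            class = "mb_partitions")
}

#' Default number of directions for a given dimension
#'
#' Twice the data dimension (never fewer than the dimension itself): a
#' modest multiple of `d` keeps the direction sample dense enough to
#' probe off-axis structure without inflating runtime. The benchmark
#' presets `M = 50` (for data of dimension around 14–25) and `M = 90`
#' (for wider mixed encodings) remain available by passing `M`
#' explicitly.
#'
#' @param d Data dimension.
#' @return Integer direction count.
#' @export
default_n_directions <- function(d) max(as.integer(d), 2L * as.integer(d))

#' Baseline and imputed sliced-Wasserstein distance table
#'
#' For every direction `r` and half-partition `p`, the data are
#' projected onto the direction and normalised by `s(r, p)`, the
#' standard deviation of the projected *original* data over the
#' reference half `I_p`. The baseline distance `w(r, p)` is the 1-D
#' 2-Wasserstein distance between the projected original halves — the
#' distance inherent to the data. The imputed distance `what(r, p)`
#' replaces the `J_p` half by the imputed data (the `I_p` half always
#' comes from the original data). Pairs with `s(r, p)` below `1e-12`
#' are degenerate and recorded in `skipped` instead of scored.
#'
#' @param truth Complete ground-truth [mb_dataset()] (or numeric
#'   matrix; coded columns participate in projections as real values).
#' @param imputed Completed matrix (one completion; run once per
#'   completion for multiple imputations).
#' @param directions An `mb_directions` from [sample_directions()].
#' @param partitions An `mb_partitions` from [make_half_partitions()].
#' @return Object of class `mb_sw_table`: `M x P` matrices `w`,
#'   `w_hat`, `s` (with `NA` at skipped pairs), `skipped` (data.frame
#'   of degenerate `(r, p)`), plus the direction/partition seeds for
#'   provenance.
#' @export
sw_distance_table <- function(truth, imputed, directions, partitions) {
  tv <- as_values(truth)
  iv <- as_values(imputed)
  if (!identical(dim(tv), dim(iv))) stop_invalid("truth and imputed shapes must agree")
  if (anyNA(tv) || anyNA(iv)) stop_invalid("inputs to the distance table must be complete")
  if (!inherits(directions, "mb_directions")) stop_invalid("`directions` must come from sample_directions()")
  if (!inherits(partitions, "mb_partitions")) stop_invalid("`partitions` must come from make_half_partitions()")
  if (ncol(tv) != directions$d) {
    stop_invalid("directions are %d-dimensional but data has %d columns",
                 directions$d, ncol(tv))
  }
  if (nrow(tv) != partitions$N) {
    stop_invalid("partitions cover %d samples but data has %d rows",
                 partitions$N, nrow(tv))
  }
  M <- directions$M
  P <- partitions$P
  proj <- tv %*% t(directions$directions)      # N x M, original data
  proj_hat <- iv %*% t(directions$directions)  # N x M, imputed data
  w <- w_hat <- s_mat <- matrix(NA_real_, M, P)
  skipped <- list()
  for (p in seq_len(P)) {
    I <- partitions$pairs[[p]]$I
    J <- partitions$pairs[[p]]$J
    for (r in seq_len(M)) {
      ref <- proj[I, r]
      s <- sd(ref)
      if (!is.finite(s) || s < 1e-12) {
        skipped[[length(skipped) + 1L]] <- data.frame(r = r, p = p)
        next
      }
      s_mat[r, p] <- s
      w[r, p] <- wasserstein2_1d(ref / s, proj[J, r] / s)
      w_hat[r, p] <- wasserstein2_1d(ref / s, proj_hat[J, r] / s)
    }
  }
  if (all(is.na(w))) stop_invalid("all (r, p) pairs are degenerate (zero projected spread)")
  structure(list(w = w, w_hat = w_hat, s = s_mat,
                 skipped = if (length(skipped)) do.call(rbind, skipped) else
                   data.frame(r = integer(0), p = integer(0)),
                 M = M, P = P,
                 direction_seed = directions$seed,
                 partition_seed = partitions$seed),
            class = "mb_sw_table")
}

#' @export
print.mb_sw_table <- function(x, ...) {
  sc <- sum(!is.na(x$w))
  cat(sprintf("<mb_sw_table> M = %d directions x P = %d partitions (%d scored, %d skipped)\n",
              x$M, x$P, sc, nrow(x$skipped)))
  cat(sprintf("  median w = %.4g, median w_hat = %.4g\n",
              median(x$w, na.rm = TRUE), median(x$w_hat, na.rm = TRUE)))
  invisible(x)
}

#' Whole-distribution (class C) discrepancy report
#'
#' Treats the flattened baseline distances `{w(r, p)}` and imputed
#' distances `{what(r, p)}` as two probability distributions and scores
#' their discrepancy with the same KL / KS / 2-Wasserstein triple used
#' feature-wise; summarises the relative change `what / w` (over pairs
#' with `w > 0`); and reports the proportion of scored pairs whose
#' imputed distance exceeds an outlier threshold. The threshold is
#' scale-dependent (distances are in units of the projected reference
#' spread), so it must be chosen by the caller — there is no default.
#'
#' @param table An `mb_sw_table`.
#' @param kl_bins Histogram bins for the KL estimate.
#' @param outlier_threshold Positive threshold above which an imputed
#'   distance counts as an outlier.
#' @return Object of class `mb_class_c`: `dist_discrepancy` (list
#'   `kl`, `ks`, `w2`), `ratio_summary` (named vector: min, q25,
#'   median, q75, max, mean), `outlier_proportion`, `outlier_threshold`,
#'   `n_pairs`.
#' @export
class_c_report <- function(table, kl_bins = 30L, outlier_threshold) {
  if (!inherits(table, "mb_sw_table")) stop_invalid("`table` must be an mb_sw_table")
  if (missing(outlier_threshold) || !is.numeric(outlier_threshold) ||
      outlier_threshold <= 0) {
    stop_invalid("outlier_threshold must be a positive number (it is scale-dependent and has no default)")
  }
  ok <- !is.na(table$w)
  if (sum(ok) < 2L) stop_invalid("need at least 2 scored (r, p) pairs")
  w <- table$w[ok]
  w_hat <- table$w_hat[ok]
  disc <- two_sample_score(w, w_hat, bins = kl_bins)
  pos <- w > 0
  if (!any(pos)) stop_invalid("all baseline distances are zero; ratios undefined")
  ratio <- w_hat[pos] / w[pos]
  q <- quantile(ratio, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  structure(list(dist_discrepancy = disc,
                 ratio_summary = c(min = q[1], q25 = q[2], median = q[3],
                                   q75 = q[4], max = q[5], mean = mean(ratio)),
                 outlier_proportion = mean(w_hat > outlier_threshold),
                 outlier_threshold = outlier_threshold,
                 n_pairs = sum(ok)),
            class = "mb_class_c")
}

#' @export
print.mb_class_c <- function(x, ...) {
  cat(sprintf("<mb_class_c> over %d (r, p) pairs\n", x$n_pairs))
  cat(sprintf("  distance-distribution discrepancy: KL %.4g, KS %.4g, W2 %.4g\n",
              x$dist_discrepancy$kl, x$dist_discrepancy$ks, x$dist_discrepancy$w2))
  cat(sprintf("  ratio what/w: median %.4g, mean %.4g\n",
              x$ratio_summary[["median"]], x$ratio_summary[["mean"]]))
  cat(sprintf("  outlier proportion (what > %g): %.4g\n",
              x$outlier_threshold, x$outlier_proportion))
  invisible(x)
}

#' Stability of repeated imputations in sliced-Wasserstein terms
#'
#' Given one distance table per repeated imputation (all computed with
#' the same directions and partitions), separates the spread caused by
#' the random projections (within-table variance of the imputed
#' distances) from the spread caused by imputation stochasticity
#' (between-table variance of per-table mean imputed distance), and
#' reports each repetition's outlier proportion at a threshold. A
#' deterministic imputer yields identical tables and zero
#' between-table variance.
#'
#' @param tables List of `>= 2` `mb_sw_table` objects sharing direction
#'   and partition seeds.
#' @param threshold Positive outlier threshold on the imputed
#'   distances.
#' @return List with `outlier_proportions` (one per table),
#'   `between_table_variance` (variance of per-table means),
#'   `within_table_variance` (mean of per-table variances),
#'   `per_table_mean_w_hat`.
#' @export
stability_analysis <- function(tables, threshold) {
  if (!is.list(tables) || length(tables) < 2L) stop_invalid("need >= 2 tables")
  if (!all(vapply(tables, inherits, logical(1), "mb_sw_table"))) {
    stop_invalid("all elements must be mb_sw_table objects")
  }
  if (!is.numeric(threshold) || threshold <= 0) stop_invalid("threshold must be positive")
  ref <- tables[[1]]
  for (t in tables[-1]) {
    if (!identical(c(t$direction_seed, t$partition_seed, t$M, t$P),
                   c(ref$direction_seed, ref$partition_seed, ref$M, ref$P))) {
      stop_invalid("tables must share direction/partition seeds and sizes")
    }
  }
  flat <- lapply(tables, function(t) t$w_hat[!is.na(t$w_hat)])
  means <- vapply(flat, mean, numeric(1))
  list(outlier_proportions = vapply(flat, function(x) mean(x > threshold), numeric(1)),
       between_table_variance = var(means),
       within_table_variance = mean(vapply(flat, var, numeric(1))),
       per_table_mean_w_hat = means)
}

#' Write a distance table as CSV plus manifest
#'
#' Long format with columns `r`, `p`, `s`, `w`, `w_hat` (skipped pairs
#' omitted); the JSON manifest records seeds, sizes and skipped pairs.
#'
#' @param table An `mb_sw_table`.
#' @param path CSV path; the manifest goes next to it.
#' @return Invisibly, the manifest path.
#' @export
write_sw_table <- function(table, path) {
  ok <- which(!is.na(table$w), arr.ind = TRUE)
  df <- data.frame(r = ok[, 1], p = ok[, 2],
                   s = table$s[ok], w = table$w[ok], w_hat = table$w_hat[ok])
  df <- df[order(df$p, df$r), ]
  out <- cbind(r = df$r, p = df$p, s = fmt_num(df$s), w = fmt_num(df$w),
               w_hat = fmt_num(df$w_hat))
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  manifest <- sub("\\.csv$", "", path)
  manifest <- paste0(manifest, ".manifest.json")
  jsonlite::write_json(list(M = table$M, P = table$P,
                            direction_seed = table$direction_seed,
                            partition_seed = table$partition_seed,
                            skipped = table$skipped),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
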