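#' Generate a labelled Gaussian-cluster dataset
#'
#' Draws a balanced two-class sample in which each class is an isotropic
#' unit-variance Gaussian centred at a vertex of the hypercube
#' `{-class_sep, +class_sep}^d`. The two class vertices are chosen
#' uniformly at random (distinct whenever `class_sep > 0`), so every
#' coordinate on which the vertices differ carries class signal.
#' `class_sep` is half the distance between adjacent hypercube vertices;
#' `class_sep = 0` collapses both centroids to the origin. The default
#' configuration `generate_numeric(1000, 25, 1.0, seed)` emulates a
#' 1000-sample, 25-informative-feature simulation study design.
#'
#' @param n Number of samples (`>= 2`). Classes are balanced to within
#'   one sample.
#' @param d_informative Number of continuous informative features
#'   (`>= 1`).
#' @param class_sep Non-negative half-distance between adjacent
#'   hypercube vertices.
#' @param seed Integer seed; output is bit-identical for equal
#'   arguments.
#' @return An [mb_dataset()] with continuous schema and 0/1 labels.
#' @export
generate_numeric <- function(n, d_informative, class_sep = 1.0, seed) {
  check_counts(n = n, d_informative = d_informative)
  if (n < 2L) stop_invalid("n must be >= 2")
  if (!is.numeric(class_sep) || class_sep < 0) stop_invalid("class_sep must be >= 0")
  with_seed(seed, {
    out <- draw_clusters(n, d_informative, class_sep)
    mb_dataset(out$x, lapply(sprintf("num%02d", seq_len(d_informative)),
                             feature_schema, kind = "continuous"),
               labels = out$y, seed = seed)
  })
}

# shared core: balanced labels, random distinct hypercube vertices,
# unit-variance Gaussian clusters, shuffled row order
draw_clusters <- function(n, d, class_sep) {
  v0 <- sample(c(-1, 1), d, replace = TRUE)
  v1 <- sample(c(-1, 1), d, replace = TRUE)
  if (class_sep > 0) {
    while (all(v1 == v0)) v1 <- sample(c(-1, 1), d, replace = TRUE)
  }
  n0 <- ceiling(n / 2)
  y <- sample(rep(c(0L, 1L), c(n0, n - n0)))
  centres <- unname(rbind(v0, v1)) * class_sep
  x <- matrix(rnorm(n * d), n, d) + centres[y + 1L, , drop = FALSE]
  list(x = x, y = y)
}

#' Generate a mixed-type labelled dataset
#'
#' Extends [generate_numeric()] with integer-coded categorical and
#' ordinal columns and pure-noise columns. Coded columns are obtained by
#' quantile-binning additional informative continuous draws (from the
#' same Gaussian-cluster model) into their declared number of levels, so
#' they retain class signal; uninformative columns are standard normal
#' noise independent of the labels.
#'
#' @inheritParams generate_numeric
#' @param d_categorical,d_ordinal,d_uninformative Column counts
#'   (`>= 0`).
#' @param n_levels_categorical,n_levels_ordinal Number of level codes
#'   (`0 .. k-1`) for each coded column.
#' @return An [mb_dataset()] whose schema records feature kinds.
#' @export
generate_mixed <- function(n, d_informative, d_categorical = 0L, d_ordinal = 0L,
                           d_uninformative = 0L, class_sep = 1.0, seed,
                           n_levels_categorical = 3L, n_levels_ordinal = 4L) {
  check_counts(n = n, d_informative = d_informative)
  for (nmv in c(d_categorical, d_ordinal, d_uninformative)) {
    if (nmv < 0) stop_invalid("feature counts must be >= 0")
  }
  if (n < 2L) stop_invalid("n must be >= 2")
  with_seed(seed, {
    d_latent <- d_informative + d_categorical + d_ordinal
    out <- draw_clusters(n, d_latent, class_sep)
    cols <- list()
    schema <- list()
    add <- function(x, fs) {
      cols[[length(cols) + 1L]] <<- x
      schema[[length(schema) + 1L]] <<- fs
    }
    for (j in seq_len(d_informative)) {
      add(out$x[, j], feature_schema(sprintf("num%02d", j), "continuous"))
    }
    k <- d_informative
    for (j in seq_len(d_categorical)) {
      add(quantile_bin(out$x[, k + j], n_levels_categorical),
          feature_schema(sprintf("cat%02d", j), "categorical",
                         seq_len(n_levels_categorical) - 1))
    }
    k <- k + d_categorical
    for (j in seq_len(d_ordinal)) {
      add(quantile_bin(out$x[, k + j], n_levels_ordinal),
          feature_schema(sprintf("ord%02d", j), "ordinal",
                         seq_len(n_levels_ordinal) - 1))
    }
    for (j in seq_len(d_uninformative)) {
      add(rnorm(n), feature_schema(sprintf("noise%02d", j), "uninformative"))
    }
    mb_dataset(do.call(cbind, cols), schema, labels = out$y, seed = seed)
  })
}

# equal-count discretisation into codes 0..k-1 at empirical quantiles
quantile_bin <- function(x, k) {
  brk <- unique(quantile(x, probs = seq(0, 1, length.out = k + 1), names = FALSE))
  code <- findInterval(x, brk, rightmost.closed = TRUE, all.inside = TRUE) - 1L
  as.numeric(code)
}

check_counts <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1 ||
        v != round(v)) {
      stop_invalid("`%s` must be a positive integer", nm)
    }
  }
}
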