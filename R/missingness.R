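#' Induce missingness completely at random (MCAR)
#'
#' Builds a boolean mask over the value matrix (never over the outcome
#' column; labels are not features). Under the default `exact_count`
#' policy, exactly `round(rate * N * d)` cells are chosen uniformly
#' without replacement, so the realised missingness rate equals the
#' requested one up to rounding. The `bernoulli` policy masks each cell
#' independently with probability `rate`.
#'
#' @param dataset An [mb_dataset()].
#' @param rate Missingness rate in `[0, 1]` (the benchmark design uses
#'   0.25 and 0.50).
#' @param seed Integer seed.
#' @param policy `"exact_count"` (default) or `"bernoulli"`.
#' @return An object of class `mb_mask`: list with `mask` (logical
#'   `N x d`, `TRUE` = missing), `rate`, `seed`, `policy`.
#' @export
induce_mcar <- function(dataset, rate, seed, policy = c("exact_count", "bernoulli")) {
  policy <- match.arg(policy)
  vals <- as_values(dataset)
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0 || rate > 1) {
    stop_invalid("rate must be in [0, 1]")
  }
  nc <- length(vals)
  if (nc == 0L) stop_invalid("dataset is empty")
  mask <- with_seed(seed, {
    if (policy == "exact_count") {
      k <- round(rate * nc)
      m <- rep(FALSE, nc)
      if (k > 0) m[sample.int(nc, k)] <- TRUE
      m
    } else {
      runif(nc) < rate
    }
  })
  mask <- matrix(mask, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  structure(list(mask = mask, rate = rate, seed = as.integer(seed),
                 policy = policy),
            class = "mb_mask")
}

#' @export
print.mb_mask <- function(x, ...) {
  cat(sprintf("<mb_mask> %d x %d, %d masked cells (realised rate %.4f, policy %s)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), mean(x$mask), x$policy))
  invisible(x)
}

mask_matrix <- function(mask) if (inherits(mask, "mb_mask")) mask$mask else mask

#' Apply a missingness mask to a dataset
#'
#' Masked cells become `NA`; observed cells are bit-identical to the
#' input.
#'
#' @param dataset An [mb_dataset()].
#' @param mask An `mb_mask` (or logical matrix) of matching shape.
#' @return An [mb_dataset()] with `NA` at the masked cells.
#' @export
apply_mask <- function(dataset, mask) {
  m <- mask_matrix(mask)
  vals <- dataset$values
  if (!identical(dim(m), dim(vals))) {
    stop_invalid("mask shape (%d x %d) does not match dataset (%d x %d)",
                 nrow(m), ncol(m), nrow(vals), ncol(vals))
  }
  vals[m] <- NA_real_
  out <- dataset
  out$values <- vals
  out
}

#' Write / read a missingness mask as 0/1 CSV
#'
#' The CSV shares the data CSV's header so masks and values stay
#' aligned by column name.
#'
#' @param mask An `mb_mask`.
#' @param path CSV path.
#' @return `write_mask_csv()` returns `path` invisibly;
#'   `read_mask_csv()` returns an `mb_mask` (with the realised rate).
#' @export
write_mask_csv <- function(mask, path) {
  m <- mask_matrix(mask) * 1L
  write.table(m, path, sep = ",", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname write_mask_csv
#' @export
read_mask_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "integer")
  m <- as.matrix(df) == 1L
  structure(list(mask = m, rate = mean(m), seed = NA_integer_,
                 policy = "exact_count"),
            class = "mb_mask")
}
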