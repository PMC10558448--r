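# Independent oracles used to validate the fast implementations.

# Discrete-transport linear program for the 1-D 2-Wasserstein distance
# between two uniform empirical measures (boot::simplex; tiny instances
# only). Completely independent of the quantile-function route.
lp_wasserstein2 <- function(a, b) {
  n <- length(a)
  m <- length(b)
  if (n == 1 && m == 1) return(abs(a - b))
  cost <- outer(a, b, function(x, y) (x - y)^2)
  A3 <- matrix(0, n + m - 1, n * m)
  for (i in seq_len(n)) A3[i, (seq_len(m) - 1) * n + i] <- 1
  for (j in seq_len(m - 1)) A3[n + j, (j - 1) * n + seq_len(n)] <- 1
  s <- boot::simplex(a = as.vector(cost), A3 = A3,
                     b3 = c(rep(1 / n, n), rep(1 / m, m - 1)), maxi = FALSE)
  stopifnot(s$solved == 1)
  sqrt(max(0, s$value))
}

# ECDF sup-difference by direct double loop over evaluation points.
brute_ks <- function(a, b) {
  pts <- c(a, b)
  dmax <- 0
  for (x in pts) {
    dmax <- max(dmax, abs(mean(a <= x) - mean(b <= x)))
  }
  dmax
}

# AUC by enumeration over all positive-negative pairs, ties counting 1/2.
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Correlated bivariate Gaussian dataset (rho), used for imputer
# comparisons where cross-feature signal matters.
correlated_gaussian <- function(n, rho, seed) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rho * x1 + sqrt(1 - rho^2) * rnorm(n)
  mb_dataset(cbind(x1 = x1, x2 = x2))
}

# Random orthogonal matrix via QR of a Gaussian draw.
random_orthogonal <- function(d, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(d * d), d, d)))
}

# The diagonal/anti-diagonal construction: truth lives on y = x with a
# symmetric first coordinate; the "imputation" reflects the second
# coordinate, leaving every marginal untouched.
diagonal_example <- function(n_half = 100) {
  v <- seq(0.1, 3, length.out = n_half)
  u <- c(-v, v)
  truth <- mb_dataset(cbind(f1 = u, f2 = u))
  mask <- matrix(c(rep(FALSE, 2 * n_half), rep(TRUE, 2 * n_half)), ncol = 2)
  imputed <- cbind(f1 = u, f2 = -u)
  list(truth = truth, mask = mask, imputed = imputed)
}
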