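# Independent oracles used across test files.

# Invert the regularized incomplete gamma survival function by bisection
# (never calls qgamma, the path under test). Works on the upper tail so
# quantiles at p near 0 keep full precision.
gamma_quantile_bisect <- function(upper_p, shape, scale = 2, tol = 1e-12) {
  lo <- 0
  hi <- 1
  while (stats::pgamma(hi, shape, scale = scale,
                       lower.tail = FALSE) > upper_p) hi <- hi * 2
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (stats::pgamma(mid, shape, scale = scale,
                      lower.tail = FALSE) > upper_p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Closed-form chi-square(4) upper tail: exp(-x/2) * (1 + x/2).
chisq4_tail <- function(x) exp(-x / 2) * (1 + x / 2)

# Scalar trend (score) test, written independently of the vectorized path.
trend_test_scalar <- function(g, y) {
  if (var(g) == 0) return(1)
  ybar <- mean(y)
  U <- sum((g - mean(g)) * y)
  V <- ybar * (1 - ybar) * sum((g - mean(g))^2)
  2 * stats::pnorm(abs(U / sqrt(V)), lower.tail = FALSE)
}

# Two-loop permutation covariance oracle sharing the estimator's
# permutation stream (same seed, same sample() calls).
perm_cov_oracle <- function(G, y, w, m, seed) {
  set.seed(seed)
  X <- matrix(NA_real_, m, ncol(G))
  for (k in seq_len(m)) {
    y_k <- sample(y)
    for (j in seq_len(ncol(G))) {
      X[k, j] <- gamma_transform(trend_test_scalar(G[, j], y_k), w[j])
    }
  }
  n <- ncol(G)
  rho <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      rho[i, j] <- sum((X[, i] - mean(X[, i])) * (X[, j] - mean(X[, j]))) /
        (m - 1)
    }
  }
  rho
}

# Shared small fixture: a null pathway data set.
make_null_data <- function(n = 120, D = 0.15, seed = 5, ploidy = "diploid") {
  cfg <- ld_config(n_subjects = n, D = D, ploidy = ploidy)
  G <- simulate_genotypes(cfg, seed = seed)
  set.seed(seed + 1)
  y <- as.integer(stats::runif(n) < 0.5)
  list(cfg = cfg, G = G, y = y)
}
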