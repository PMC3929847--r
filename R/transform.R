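#' Gene-size weights for the Lancaster procedure
#'
#' Builds the per-test chi-square degrees of freedom (the Lancaster weights)
#' from gene sizes. Larger genes contribute more tests to a combined set, so
#' down-weighting by size removes the bias toward large genes.
#'
#' @param n_sizes positive integer vector, one gene size per test (for SNP
#'   data, the number of SNPs in the gene the test belongs to; for
#'   expression data, the number of probes).
#' @param scheme weighting scheme: `"inv"` (default) gives `w = 2/n`, so a
#'   gene's tests carry a total weight of 2 regardless of its size, which
#'   removes the size bias completely; `"inv_sqrt"` gives `w = 2/sqrt(n)`
#'   (partial correction); `"flat"` gives `w = 2` for every test (plain
#'   Fisher combination, no correction).
#' @return numeric vector of weights `w > 0`, same length as `n_sizes`.
#'   A size of 1 yields `w = 2` under every scheme, so a singleton test is
#'   always the untouched chi-square(2) transform.
#' @examples
#' weights_from_gene_sizes(c(4, 4, 1), "inv_sqrt")
#' @export
weights_from_gene_sizes <- function(n_sizes,
                                    scheme = c("inv", "inv_sqrt", "flat")) {
  scheme <- match.arg(scheme)
  if (length(n_sizes) < 1L) {
    stop("'n_sizes' must have length >= 1")
  }
  if (any(!is.finite(n_sizes)) || any(n_sizes < 1) ||
      any(n_sizes != floor(n_sizes))) {
    stop("'n_sizes' must be positive integers")
  }
  switch(scheme,
    inv_sqrt = 2 / sqrt(n_sizes),
    inv      = 2 / n_sizes,
    flat     = rep(2, length(n_sizes))
  )
}

# Smallest p-value the gamma transform will accept; keeps the transformed
# value finite (qgamma at p = 1e-15 is large but finite for any w > 0).
.p_floor <- 1e-15

#' Clip p-values into the valid domain
#'
#' @param p numeric vector of p-values.
#' @return p clipped into `[1e-15, 1]`.
#' @keywords internal
clip_pvalues <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  pmax(p, .p_floor)
}

#' Gamma-quantile transform of a p-value
#'
#' Maps `p` to the upper-`p` quantile of a chi-square distribution with `w`
#' degrees of freedom, i.e. the `(1 - p)` quantile of Gamma(shape `w/2`,
#' scale 2). A uniform p-value is thereby converted to a chi-square variable
#' with `w` (possibly non-integer) degrees of freedom; `w = 2` recovers
#' Fisher's `-2 log p`.
#'
#' @param p p-value(s) in `(0, 1]`; values below `1e-15` are clipped.
#' @param w weight(s) `> 0`, recycled against `p`.
#' @return numeric vector of transformed values `>= 0`, strictly decreasing
#'   in `p`; `p = 1` maps to exactly 0.
#' @examples
#' gamma_transform(0.5, 2)   # -2*log(0.5)
#' @export
gamma_transform <- function(p, w) {
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be finite and > 0")
  }
  p <- clip_pvalues(p)
  # upper-tail quantile computed directly for accuracy at small p
  stats::qgamma(p, shape = w / 2, scale = 2, lower.tail = FALSE)
}

#' The Lancaster combination statistic
#'
#' `T = sum_i gamma_transform(p_i, w_i)`. With all `w_i = 2` this is
#' Fisher's `-2 sum log p_i`. Under independent uniform p-values `T` is
#' exactly chi-square with `sum(w)` degrees of freedom.
#'
#' @param p p-values in `(0, 1]`.
#' @param w weights `> 0`, same length as `p`.
#' @return the scalar statistic `T >= 0`.
#' @examples
#' lancaster_statistic(c(0.5, 0.5), c(2, 2))
#' @export
lancaster_statistic <- function(p, w) {
  if (length(p) != length(w)) {
    stop("'p' and 'w' must have the same length")
  }
  sum(gamma_transform(p, w))
}

#' Moments of the Lancaster statistic under dependence
#'
#' `E(T) = sum(w)` holds whatever the dependence (each transformed value is
#' marginally chi-square `w_i`).  The variance picks up the covariances of
#' the transformed values:
#' `Var(T) = 2 sum(w) + 2 sum_{i<j} rho_ij`,
#' where `rho_ij` is the covariance between the gamma-transformed values
#' (NOT between the raw p-values).
#'
#' @param w weight vector.
#' @param rho either `NULL`/`0` for independence, or a symmetric matrix of
#'   transformed-scale covariances with dimension `length(w)`; only the
#'   off-diagonal entries enter the variance.
#' @return list with components `mean` and `variance`.
#' @seealso [estimate_transformed_covariance()] for obtaining `rho` by
#'   phenotype permutation.
#' @export
moments_correlated <- function(w, rho = NULL) {
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be finite and > 0")
  }
  n <- length(w)
  if (inherits(rho, "cov_estimate")) rho <- rho$rho
  off_sum <- 0
  if (!is.null(rho) && !identical(rho, 0)) {
    if (!is.matrix(rho) || nrow(rho) != n || ncol(rho) != n) {
      stop("'rho' must be a ", n, " x ", n, " matrix")
    }
    if (max(abs(rho - t(rho))) > 1e-8 * max(1, max(abs(rho)))) {
      stop("'rho' must be symmetric")
    }
    off_sum <- sum(rho[upper.tri(rho)])
  }
  mean_T <- sum(w)
  var_T <- 2 * mean_T + 2 * off_sum
  if (var_T <= 0) {
    # a covariance estimate that drives Var(T) <= 0 is not usable
    stop("Var(T) = ", format(var_T),
         " <= 0; the supplied covariance matrix is not a valid estimate")
  }
  list(mean = mean_T, variance = var_T)
}
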