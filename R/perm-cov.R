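#' Estimate the transformed-scale covariance by phenotype permutation
#'
#' The variance of the Lancaster statistic under dependence needs the
#' covariances `rho_ij` between the gamma-transformed values
#' `x_i = gamma_transform(p_i, w_i)`. When only raw data are available,
#' these are estimated by permutation: the phenotype labels are shuffled
#' among subjects (genotype rows untouched, so LD is preserved), the
#' per-variant tests are rerun to give a p-value vector per permutation,
#' each vector is gamma-transformed, and `rho` is the sample covariance of
#' the transformed vectors across permutations.
#'
#' Permutations are drawn independently (no distinctness enforced; with
#' `m` far below `n!` collisions are immaterial) and the identity
#' permutation is not excluded.
#'
#' @param genotypes subject x variant numeric matrix, no missing values.
#' @param phenotype 0/1 vector with both classes.
#' @param w weight vector, one per variant.
#' @param m number of permutations (default 1000).
#' @param method per-variant test passed to [per_variant_test()];
#'   `"trend"` runs all `m` permutations in a single matrix product.
#' @param seed integer seed; the same seed gives a bit-identical estimate.
#' @return object of class `"cov_estimate"`: list with `rho` (symmetric
#'   variant x variant covariance matrix of the transformed values), `m`,
#'   `source = "permutation"` and `seed`. Under the null the diagonal is
#'   close to `2 * w` (the chi-square variance), kept for diagnostics; only
#'   the off-diagonals enter `Var(T)`.
#' @export
estimate_transformed_covariance <- function(genotypes, phenotype, w,
                                            m = 1000,
                                            method = c("trend", "logistic"),
                                            seed = NULL) {
  method <- match.arg(method)
  G <- as.matrix(genotypes)
  y <- as.numeric(phenotype)
  if (m < 2) stop("'m' must be >= 2")
  if (length(unique(y)) < 2) stop("phenotype must contain both classes")
  if (length(y) != nrow(G)) stop("phenotype length must match genotype rows")
  if (length(w) != ncol(G)) stop("one weight per variant is required")
  if (anyNA(G)) stop("genotype matrix must be complete (no missing values)")
  if (!is.null(seed)) set.seed(seed)

  if (method == "trend") {
    Y <- vapply(seq_len(m), function(k) sample(y), numeric(length(y)))
    P <- trend_test_matrix(G, Y)                  # variant x m
    X <- matrix(gamma_transform(as.vector(P), rep(w, m)),
                nrow = ncol(G))
  } else {
    X <- vapply(seq_len(m), function(k) {
      p_k <- per_variant_test(G, sample(y), method = "logistic")
      gamma_transform(p_k, w)
    }, numeric(ncol(G)))
  }
  rho <- stats::cov(t(X))                         # m observations per pair
  rho <- (rho + t(rho)) / 2                       # exact symmetry
  dimnames(rho) <- list(colnames(G), colnames(G))
  structure(
    list(rho = rho, m = m, source = "permutation", seed = seed),
    class = "cov_estimate"
  )
}

#' Wrap a user-supplied covariance matrix
#'
#' @param rho symmetric matrix of transformed-scale covariances.
#' @return object of class `"cov_estimate"` with `source = "given"`.
#' @export
given_covariance <- function(rho) {
  rho <- as.matrix(rho)
  if (nrow(rho) != ncol(rho) || max(abs(rho - t(rho))) > 1e-8) {
    stop("'rho' must be a symmetric square matrix")
  }
  structure(list(rho = rho, m = NA_integer_, source = "given", seed = NULL),
            class = "cov_estimate")
}

#' @export
print.cov_estimate <- function(x, ...) {
  cat(sprintf(
    "Transformed-scale covariance (%s%s), %d x %d\n",
    x$source, if (x$source == "permutation") paste0(", m = ", x$m) else "",
    nrow(x$rho), ncol(x$rho)))
  cat(sprintf("  mean off-diagonal: %.4f\n",
              mean(x$rho[upper.tri(x$rho)])))
  invisible(x)
}
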