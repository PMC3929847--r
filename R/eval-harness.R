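#' Build a correlation matrix for the copula benchmark
#'
#' Structures used when assessing the approximations on directly simulated
#' correlated p-values: block compound symmetry with a fixed `rho`
#' (`block_fixed`), with per-block `rho ~ Beta(0.3, 1.5)` (`block_beta`)
#' or `rho ~ U(-0.2, 0.2)` (`block_uniform`), and full random positive
#' definite correlation matrices (`random_pd`, built from random orthogonal
#' eigenvectors with Dirichlet-distributed eigenvalues summing to the
#' dimension, rescaled to unit diagonal).
#'
#' @param kind one of `"block_fixed"`, `"block_beta"`, `"block_uniform"`,
#'   `"random_pd"`.
#' @param rho within-block correlation for `block_fixed`; must satisfy
#'   `-1/(block_size - 1) < rho < 1` for positive definiteness.
#' @param n_blocks,block_size block layout (default 20 blocks of 5, a
#'   100 x 100 matrix).
#' @param seed integer seed (used by the random kinds).
#' @return correlation matrix with unit diagonal, positive definite.
#' @export
build_sigma <- function(kind = c("block_fixed", "block_beta",
                                 "block_uniform", "random_pd"),
                        rho = 0.3, n_blocks = 20, block_size = 5,
                        seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  n <- n_blocks * block_size
  cs_block <- function(r) {
    if (r <= -1 / (block_size - 1) || r >= 1) {
      stop("block rho = ", r, " outside the positive definite range (",
           format(-1 / (block_size - 1)), ", 1)")
    }
    matrix(r, block_size, block_size) + (1 - r) * diag(block_size)
  }
  if (kind == "random_pd") {
    Q <- qr.Q(qr(matrix(stats::rnorm(n * n), n)))
    ev <- stats::rgamma(n, shape = 1)
    ev <- ev / sum(ev) * n
    S <- Q %*% (ev * t(Q))
    return(stats::cov2cor(S))
  }
  rhos <- switch(kind,
    block_fixed   = rep(rho, n_blocks),
    block_beta    = stats::rbeta(n_blocks, 0.3, 1.5),
    block_uniform = stats::runif(n_blocks, -0.2, 0.2)
  )
  blocks <- lapply(rhos, cs_block)
  S <- matrix(0, n, n)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1) * block_size + 1):(b * block_size)
    S[idx, idx] <- blocks[[b]]
  }
  S
}

#' Sample correlated p-values through a Gaussian copula
#'
#' Draws `Z ~ MVN(0, sigma)` and maps `p_i = 1 - Phi(Z_i)` (one-sided),
#' so each marginal is exactly Uniform(0, 1) while the joint dependence is
#' governed by `sigma`.
#'
#' @param sigma positive definite correlation matrix.
#' @param n_draws number of p-value vectors to draw.
#' @param seed integer seed.
#' @return `n_draws` x `ncol(sigma)` matrix of p-values.
#' @export
sample_correlated_pvalues <- function(sigma, n_draws = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- tryCatch(chol(sigma), error = function(e) {
    stop("'sigma' is not positive definite: ", conditionMessage(e))
  })
  n <- ncol(sigma)
  Z <- matrix(stats::rnorm(n_draws * n), n_draws, n) %*% L
  stats::pnorm(Z, lower.tail = FALSE)
}

#' Transformed-scale covariance implied by a Gaussian copula pair
#'
#' For two p-values generated from bivariate standard normals with
#' correlation `r` through `p = 1 - Phi(Z)`, computes
#' `cov(gamma_transform(p_1, w1), gamma_transform(p_2, w2))` by
#' Gauss-Hermite quadrature over the bivariate normal. This is the exact
#' population quantity the permutation estimator targets under this
#' copula, used to feed the moment-matched reference in [qq_comparison()].
#'
#' @param r copula (normal-scale) correlation.
#' @param w1,w2 weights of the two tests.
#' @param n_nodes quadrature nodes per dimension.
#' @return scalar covariance on the transformed scale.
#' @export
cov_transformed_gaussian <- function(r, w1 = 2, w2 = 2, n_nodes = 64) {
  gh <- .gauss_hermite(n_nodes)
  # probabilist nodes/weights: z ~ N(0,1); evaluate the transform through
  # the upper normal tail so extreme nodes stay finite
  z <- gh$nodes
  wq <- gh$weights
  fz <- function(z, w) {
    stats::qgamma(stats::pnorm(z, lower.tail = FALSE), shape = w / 2,
                  scale = 2, lower.tail = FALSE)
  }
  f1 <- fz(z, w1)
  mu1 <- sum(wq * f1)
  mu2 <- sum(wq * fz(z, w2))
  if (abs(r) < .Machine$double.eps) return(0)
  # E[f1(Z1) f2(Z2)] with Z2 | Z1 ~ N(r z1, 1 - r^2)
  s <- sqrt(1 - r^2)
  inner <- vapply(z, function(z1) sum(wq * fz(r * z1 + s * z, w2)),
                  numeric(1))
  sum(wq * f1 * inner) - mu1 * mu2
}

# Gauss-Hermite rule rescaled to the standard normal weight
.gauss_hermite <- function(n) {
  # Golub-Welsch: eigen-decomposition of the Jacobi matrix for Hermite
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- e$vectors[1, ]^2          # physicists' weights / sqrt(pi)
  list(nodes = nodes * sqrt(2), weights = weights)
}

#' Transformed-scale covariance matrix implied by a Gaussian copula
#'
#' Applies [cov_transformed_gaussian()] entrywise. Since the copula
#' correlations within a compound-symmetric block are equal, results are
#' cached per unique `(r, w_i, w_j)`.
#'
#' @param sigma copula correlation matrix.
#' @param w weight vector.
#' @return transformed-scale covariance matrix (off-diagonals only are
#'   meaningful for `Var(T)`; diagonal set to `2 * w`).
#' @export
copula_transformed_covariance <- function(sigma, w) {
  n <- ncol(sigma)
  rho <- matrix(0, n, n)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- sigma[i, j]
      if (abs(r) < 1e-12) next
      key <- paste(signif(r, 12), w[i], w[j])
      if (is.null(cache[[key]])) {
        cache[[key]] <- cov_transformed_gaussian(r, w[i], w[j])
      }
      rho[i, j] <- rho[j, i] <- cache[[key]]
    }
  }
  diag(rho) <- 2 * w
  rho
}

#' Empirical vs approximated quantiles of the Lancaster statistic
#'
#' Draws `n_draws` correlated p-value vectors from the Gaussian copula,
#' forms the Lancaster statistic for each, and tabulates its empirical
#' quantiles against (i) the naive chi-square(`sum(w)`) reference the
#' original procedure assumes and (ii) the moment-matched scaled
#' chi-square using the true copula-implied transformed covariance.
#' The flatter-than-`y = x` naive curve is the visual signature of the
#' Type I inflation under correlation.
#'
#' @param sigma copula correlation matrix.
#' @param w weight vector (recycled to `ncol(sigma)`).
#' @param n_draws Monte Carlo draws (>= 1000).
#' @param probs quantile levels tabulated.
#' @param seed integer seed.
#' @return data.frame with columns `prob`, `empirical`, `naive`
#'   (chi-square `sum(w)` quantile) and `TA` (scaled chi-square quantile),
#'   plus attributes `c` and `v`.
#' @export
qq_comparison <- function(sigma, w = rep(2, ncol(sigma)), n_draws = 10000,
                          probs = seq(0.01, 0.99, by = 0.01), seed = NULL) {
  if (n_draws < 1000) stop("'n_draws' must be >= 1000")
  w <- rep_len(w, ncol(sigma))
  P <- sample_correlated_pvalues(sigma, n_draws, seed = seed)
  X <- matrix(gamma_transform(as.vector(t(P)), rep(w, n_draws)),
              nrow = ncol(sigma))
  T_draws <- colSums(X)
  rho <- copula_transformed_covariance(sigma, w)
  m <- moments_correlated(w, rho)
  par <- satterthwaite_params(m)
  emp <- stats::quantile(T_draws, probs, names = FALSE)
  naive <- stats::qgamma(probs, shape = sum(w) / 2, scale = 2)
  ta <- stats::qgamma(probs, shape = par$v / 2, scale = 2) / par$c
  out <- data.frame(prob = probs, empirical = emp, naive = naive, TA = ta)
  attr(out, "c") <- par$c
  attr(out, "v") <- par$v
  attr(out, "T_draws") <- T_draws
  out
}

#' Scenario description for a rejection-rate experiment
#'
#' One cell of the benchmark: a pathway LD layout, a disease model with a
#' shared effect size, replication and permutation counts, the nominal
#' level, and the weighting scheme.
#'
#' @param ld_config an [ld_config()].
#' @param case disease case `"I"`..`"VI"`.
#' @param beta shared effect size (0 gives the null / Type I error row).
#' @param reps number of simulation replicates.
#' @param m_perm permutations per replicate for the covariance estimate.
#' @param alpha nominal level.
#' @param weighting `"gene_size"` (weights from gene sizes via the scheme
#'   in `weight_scheme`) or `"flat"` (`w = 2` everywhere).
#' @param weight_scheme scheme passed to [weights_from_gene_sizes()] when
#'   `weighting = "gene_size"`.
#' @param test per-variant test, `"trend"` or `"logistic"`.
#' @param seed master seed; per-replicate seeds are derived from it by a
#'   counter so results do not depend on execution order.
#' @return list of class `"scenario_spec"`.
#' @export
scenario_spec <- function(ld_config = corLancaster::ld_config(),
                          case = "I", beta = 0, reps = 1000, m_perm = 1000,
                          alpha = 0.05,
                          weighting = c("gene_size", "flat"),
                          weight_scheme = "inv",
                          test = c("trend", "logistic"), seed = 1L) {
  weighting <- match.arg(weighting)
  test <- match.arg(test)
  if (reps < 1) stop("'reps' must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  structure(
    list(ld_config = ld_config, case = case, beta = beta, reps = reps,
         m_perm = m_perm, alpha = alpha, weighting = weighting,
         weight_scheme = weight_scheme, test = test, seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

# per-replicate seed derived by counter from the master seed; kept inside
# 32-bit integer range
.derive_seed <- function(master, r) {
  as.integer((as.numeric(master) + 7919 * as.numeric(r)) %% 2147483647) + 1L
}

#' Type I error / power experiment for one scenario
#'
#' For each replicate: simulate pathway genotypes and phenotype, run the
#' per-variant tests, estimate the transformed-scale covariance by
#' phenotype permutation on that replicate's data, and compute all six
#' combined p-values ([combine_pvalues()]). Returns the per-method
#' rejection proportion at the nominal level — the Type I error when
#' `beta = 0`, the power otherwise.
#'
#' @param spec a [scenario_spec()].
#' @param methods combination methods to evaluate.
#' @param verbose print progress every 100 replicates.
#' @return list with `rates` (named rejection proportions), `reps_used`,
#'   `failures` (replicates that errored, counted not dropped), and
#'   `pvalues` (reps x method matrix).
#' @export
rejection_rate_experiment <- function(spec,
                                      methods = c("independent", "TA", "TB",
                                                  "TC", "TD", "TE"),
                                      verbose = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  cfg <- spec$ld_config
  model <- disease_model(spec$case, beta = spec$beta)
  w <- if (spec$weighting == "gene_size") {
    pathway_weights(cfg$gene_sizes, spec$weight_scheme)
  } else {
    rep(2, sum(cfg$gene_sizes))
  }
  need_rho <- any(methods != "independent")
  P <- matrix(NA_real_, spec$reps, length(methods),
              dimnames = list(NULL, methods))
  failures <- 0L
  for (r in seq_len(spec$reps)) {
    res <- tryCatch({
      G <- simulate_genotypes(cfg, seed = .derive_seed(spec$seed, 3L * r))
      y <- simulate_phenotype(G, model,
                              seed = .derive_seed(spec$seed, 3L * r + 1L))
      if (length(unique(y)) < 2) stop("degenerate phenotype draw")
      p_obs <- per_variant_test(G, y, method = spec$test)
      rho <- if (need_rho) {
        estimate_transformed_covariance(
          G, y, w, m = spec$m_perm, method = spec$test,
          seed = .derive_seed(spec$seed, 3L * r + 2L))
      } else NULL
      combine_pvalues(p_obs, w, rho = rho, methods = methods)$pvalues
    }, error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
    } else {
      P[r, ] <- res[methods]
    }
    if (verbose && r %% 100 == 0) {
      message("replicate ", r, "/", spec$reps)
    }
  }
  ok <- stats::complete.cases(P)
  rates <- colMeans(P[ok, , drop = FALSE] < spec$alpha)
  list(rates = rates, reps_used = sum(ok), failures = failures, pvalues = P)
}
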