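test_that("exact independence reference matches closed-form chi-square tails", {
  expect_equal(exact_independent_pvalue(0, c(2, 2)), 1)
  expect_equal(exact_independent_pvalue(4, c(2, 2)), chisq4_tail(4),
               tolerance = 1e-12)
  expect_equal(exact_independent_pvalue(9.4877, c(2, 2)),
               chisq4_tail(9.4877), tolerance = 1e-12)
  expect_equal(chisq4_tail(9.4877), 0.05, tolerance = 1e-4)
})

test_that("Satterthwaite parameters come from the moment-matching formulas", {
  p <- satterthwaite_params(list(mean = 4, variance = 8))
  expect_equal(p$c, 1)
  expect_equal(p$v, 4)
  p <- satterthwaite_params(list(mean = 4, variance = 12))
  expect_equal(p$c, 2 / 3)
  expect_equal(p$v, 8 / 3)
  p <- satterthwaite_params(list(mean = 6, variance = 24))
  expect_equal(p$c, 0.5)
  expect_equal(p$v, 3)
  expect_error(satterthwaite_params(list(mean = 0, variance = 1)), "positive")
})

test_that("method A reduces to the exact chi-square tail", {
  expect_equal(tail_prob_TA(4, list(c = 1, v = 4)), chisq4_tail(4),
               tolerance = 1e-12)
  expect_equal(tail_prob_TA(0, list(c = 0.7, v = 3)), 1)
  expect_equal(tail_prob_TA(6, list(c = 2 / 3, v = 8 / 3)),
               stats::pgamma(4, shape = 4 / 3, scale = 2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("approximations B-E agree with exact chi-square tails at stated tolerances", {
  tol <- c(TB = 0.01, TC = 0.005, TD = 0.002, TE = 0.002)
  for (v in c(3, 8, 20, 50, 100)) {
    m <- list(mean = v, variance = 2 * v)  # c = 1: scaled statistic is chi2_v
    for (alpha in c(0.2, 0.1, 0.05, 0.01, 0.001)) {
      Tq <- stats::qgamma(alpha, shape = v / 2, scale = 2, lower.tail = FALSE)
      got <- c(
        TB = normal_approx_pvalue(Tq, m, v, "fisher"),
        TC = normal_approx_pvalue(Tq, m, v, "wilson_hilferty"),
        TD = cornish_fisher_pvalue(Tq, m, v),
        TE = saddlepoint_pvalue(Tq, m, v)
      )
      for (meth in names(got)) {
        expect_lt(abs(got[[meth]] - alpha), tol[[meth]],
                  label = sprintf("%s v=%g alpha=%g err", meth, v, alpha))
      }
    }
  }
})

test_that("Cornish-Fisher expansion matches its analytic median value and the quantile oracle", {
  expect_equal(cornish_fisher_quantile(0.5, 4), 4 - 2 / 3 + 32 / (405 * 4),
               tolerance = 1e-12)
  expect_equal(cornish_fisher_quantile(0.5, 4), 3.35309, tolerance = 1e-5)
  expect_lt(abs(cornish_fisher_quantile(0.95, 20) - stats::qchisq(0.95, 20)),
            0.05)
  expect_lt(abs(cornish_fisher_quantile(0.05, 20) - stats::qchisq(0.05, 20)),
            0.05)
  expect_error(cornish_fisher_quantile(1.2, 4), "\\(0, 1\\)")
})

test_that("Cornish-Fisher p-value inverts its own quantile and clamps", {
  v <- 11
  m <- list(mean = 30, variance = 2 * 30^2 / v)
  for (alpha in c(0.2, 0.5, 0.9, 0.99)) {
    Tq <- cornish_fisher_quantile(alpha, v) * m$mean / v
    expect_equal(cornish_fisher_pvalue(Tq, m, v), 1 - alpha,
                 tolerance = 1e-7)
  }
  expect_equal(cornish_fisher_pvalue(0, m, v), 1)
})

test_that("saddlepoint handles the mean point and its neighborhood smoothly", {
  v <- 20
  m <- list(mean = v, variance = 2 * v)
  expect_equal(saddlepoint_pvalue(v, m, v),
               stats::pchisq(v, v, lower.tail = FALSE), tolerance = 2e-3)
  # continuity across the singularity guard
  p_grid <- vapply(seq(0.999, 1.001, length.out = 41) * v,
                   function(Tv) saddlepoint_pvalue(Tv, m, v), numeric(1))
  expect_true(all(diff(p_grid) <= 1e-6))
  expect_lt(max(abs(diff(p_grid))), 5e-4)
  expect_equal(saddlepoint_pvalue(0, m, v), 1)
})

test_that("all methods are monotone in T and bounded in [0, 1] on adversarial grids", {
  set.seed(41)
  for (i in 1:10) {
    w <- rexp(5) + 0.2
    swt <- sum(w)
    m <- list(mean = swt, variance = 2 * swt * runif(1, 0.5, 4))
    par <- satterthwaite_params(m)
    Ts <- sort(c(0, 10^runif(12, -3, 3.5)))
    for (fn in list(
      function(T) tail_prob_TA(T, par),
      function(T) normal_approx_pvalue(T, m, par$v, "fisher"),
      function(T) normal_approx_pvalue(T, m, par$v, "wilson_hilferty"),
      function(T) cornish_fisher_pvalue(T, m, par$v),
      function(T) saddlepoint_pvalue(T, m, par$v)
    )) {
      ps <- vapply(Ts, fn, numeric(1))
      expect_true(all(ps >= 0 & ps <= 1))
      expect_true(all(diff(ps) <= 1e-8))
    }
  }
})

test_that("combine_pvalues reduces exactly to the independence case when rho is null", {
  r <- combine_pvalues(c(0.5, 0.5), c(2, 2))
  expect_equal(r$statistic, -2 * log(0.25), tolerance = 1e-10)
  expect_equal(unname(r$pvalues["TA"]), chisq4_tail(r$statistic),
               tolerance = 1e-12)
  expect_equal(unname(r$pvalues["TA"]), unname(r$pvalues["independent"]),
               tolerance = 1e-14)
  expect_equal(r$params$c, 1)
  expect_equal(r$params$v, 4)
  r1 <- combine_pvalues(rep(1, 4), rep(2, 4))
  expect_equal(r1$statistic, 0)
  expect_true(all(r1$pvalues == 1))
})

test_that("combine_pvalues responds to a supplied covariance", {
  rho <- matrix(c(0, 2, 2, 0), 2)
  r <- combine_pvalues(c(0.01, 0.02), c(2, 2), rho = rho)
  r0 <- combine_pvalues(c(0.01, 0.02), c(2, 2))
  # positive correlation means less evidence than independence suggests
  expect_gt(r$pvalues[["TA"]], r0$pvalues[["TA"]])
  expect_equal(r$moments$variance, 8 + 4)
  expect_equal(names(r$pvalues),
               c("independent", "TA", "TB", "TC", "TD", "TE"))
})
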