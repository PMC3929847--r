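test_that("LD config validates its domain and exposes D_max", {
  expect_error(ld_config(maf = 0.6), "maf")
  expect_error(ld_config(D = 0.25), "D_max")
  expect_error(ld_config(gene_sizes = c(3, 0)), "positive")
  cfg <- ld_config(D = 0.21)
  expect_equal(cfg$d_max, 0.21)
  # D = D_max means P(minor | minor neighbor) = 1: perfect dependence
  expect_equal((0.3 * 0.3 + 0.21) / 0.3, 1)
})

test_that("simulated genotypes reproduce marginal MAF and adjacent correlation R = D / (q(1-q))", {
  cfg <- ld_config(gene_sizes = c(40), maf = 0.3, D = 0.15,
                   ploidy = "haploid", n_subjects = 100000)
  H <- simulate_genotypes(cfg, seed = 71)
  freq <- colMeans(H)
  se <- sqrt(0.3 * 0.7 / 100000)
  expect_true(all(abs(freq - 0.3) < 4 * se))
  r_adj <- mapply(function(j) cor(H[, j], H[, j + 1]), 1:39)
  expect_equal(mean(r_adj), 0.15 / 0.21, tolerance = 0.01)
  # chain locality: correlation at lag k decays as R^k
  R <- 0.15 / 0.21
  for (k in 2:4) {
    r_k <- mean(mapply(function(j) cor(H[, j], H[, j + k]), 1:(40 - k)))
    expect_equal(r_k, R^k, tolerance = 0.03)
  }
})

test_that("D = 0 gives independent loci and genes are always independent", {
  cfg <- ld_config(gene_sizes = c(10, 10), maf = 0.3, D = 0,
                   ploidy = "haploid", n_subjects = 50000)
  H <- simulate_genotypes(cfg, seed = 72)
  r_adj <- mean(mapply(function(j) cor(H[, j], H[, j + 1]), 1:9))
  expect_lt(abs(r_adj), 3 / sqrt(50000))
  cfg2 <- ld_config(gene_sizes = c(5, 5), maf = 0.3, D = 0.2,
                    ploidy = "haploid", n_subjects = 50000)
  H2 <- simulate_genotypes(cfg2, seed = 73)
  expect_lt(abs(cor(H2[, 5], H2[, 6])), 3 / sqrt(50000))  # gene boundary
})

test_that("diploid genotypes are 0/1/2 with doubled allele frequency and same correlation", {
  cfg <- ld_config(gene_sizes = c(12), maf = 0.3, D = 0.15,
                   ploidy = "diploid", n_subjects = 60000)
  G <- simulate_genotypes(cfg, seed = 74)
  expect_true(all(G %in% 0:2))
  expect_equal(mean(G[, 1]), 0.6, tolerance = 0.01)
  expect_equal(cor(G[, 1], G[, 2]), 0.15 / 0.21, tolerance = 0.02)
})

test_that("seeds make the simulator reproducible", {
  cfg <- ld_config(n_subjects = 100, D = "uniform")
  expect_identical(simulate_genotypes(cfg, seed = 8),
                   simulate_genotypes(cfg, seed = 8))
  expect_false(identical(simulate_genotypes(cfg, seed = 8),
                         simulate_genotypes(cfg, seed = 9)))
})

test_that("disease models carry the printed term structure", {
  m4 <- disease_model("IV", beta = 0.4)
  expect_true(any(vapply(m4$terms, function(t)
    identical(t, c("G1.8", "G1.10", "G1.11")), logical(1))))
  m1 <- disease_model("I")
  expect_equal(unlist(m1$terms), c("G1.2", "G1.5", "G1.7", "G1.8", "G1.12"))
  m6 <- disease_model("VI")
  expect_length(m6$terms, 6)
})

test_that("phenotype has prevalence one half under the null and responds to beta", {
  cfg <- ld_config(n_subjects = 20000, D = 0.15)
  G <- simulate_genotypes(cfg, seed = 81)
  y0 <- simulate_phenotype(G, disease_model("I", beta = 0), seed = 82)
  expect_equal(mean(y0), 0.5, tolerance = 3 * 0.5 / sqrt(20000))
  y1 <- simulate_phenotype(G, disease_model("I", beta = 0.6), seed = 82)
  # positive effects raise prevalence above one half
  expect_gt(mean(y1), 0.55)
  # causal variant association is detectable
  p_causal <- per_variant_test(G, y1)["G1.2"]
  expect_lt(p_causal, 1e-6)
  expect_error(simulate_phenotype(G[, 1:3], disease_model("I")), "lacks")
})

test_that("trend test is calibrated under the null and matches its scalar oracle", {
  d <- make_null_data(n = 300, D = 0, seed = 91)
  p <- per_variant_test(d$G, d$y)
  expect_equal(unname(p["G1.1"]), trend_test_scalar(d$G[, 1], d$y),
               tolerance = 1e-12)
  # pooled null p-values across replicates are uniform
  set.seed(92)
  pool <- replicate(150, {
    y <- as.integer(runif(300) < 0.5)
    per_variant_test(d$G[, c(1, 13, 21)], y)
  })
  ks <- suppressWarnings(stats::ks.test(as.vector(pool), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate and extreme variants follow the documented rules", {
  set.seed(93)
  G <- cbind(const = rep(1L, 60), ok = rbinom(60, 2, 0.4))
  y <- as.integer(runif(60) < 0.5)
  p <- per_variant_test(G, y)
  expect_equal(unname(p["const"]), 1)
  # perfectly separating variant: tiny p, no crash
  G2 <- cbind(sep = c(rep(0L, 30), rep(2L, 30)))
  y2 <- c(rep(0L, 30), rep(1L, 30))
  expect_lt(per_variant_test(G2, y2)[1], 1e-10)
  expect_error(per_variant_test(G, rep(0, 60)), "both classes")
})

test_that("trend and logistic Wald tests agree asymptotically", {
  d <- make_null_data(n = 400, D = 0.15, seed = 95)
  y <- simulate_phenotype(d$G, disease_model("I", beta = 0.3), seed = 96)
  p_tr <- per_variant_test(d$G, y, method = "trend")
  p_lg <- per_variant_test(d$G, y, method = "logistic")
  mid <- p_tr > 0.001 & p_tr < 0.999
  expect_true(all(abs(log(p_tr[mid]) - log(p_lg[mid])) < 0.25))
})
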