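#' Configuration for the LD pathway simulator
#'
#' Describes a pathway of genes, each a run of SNP loci with constant minor
#' allele frequency and first-order (Markov-chain) linkage disequilibrium
#' between adjacent within-gene loci. Genes are mutually independent.
#'
#' @param gene_sizes positive integers, number of SNPs per gene. Default is
#'   the five-gene pathway G1(12), G2(8), G3(5), G4(3), G5(2).
#' @param maf minor allele frequency shared by all loci, in `(0, 0.5]`.
#' @param D pairwise LD coefficient for adjacent within-gene loci, or the
#'   string `"uniform"` to draw an independent `D ~ U(0, D_max)` per
#'   adjacent pair. `D_max = maf * (1 - maf)` when both loci share `maf`.
#' @param ploidy `"diploid"` (0/1/2 minor-allele counts, the sum of two
#'   independent haplotypes; the default) or `"haploid"` (0/1 alleles).
#' @param n_subjects number of subjects to simulate.
#' @return list of class `"ld_config"`.
#' @export
ld_config <- function(gene_sizes = c(12, 8, 5, 3, 2), maf = 0.3, D = 0,
                      ploidy = c("diploid", "haploid"), n_subjects = 200) {
  ploidy <- match.arg(ploidy)
  if (any(gene_sizes < 1) || any(gene_sizes != floor(gene_sizes))) {
    stop("'gene_sizes' must be positive integers")
  }
  if (maf <= 0 || maf > 0.5) stop("'maf' must be in (0, 0.5]")
  d_max <- maf * (1 - maf)
  if (!identical(D, "uniform")) {
    if (!is.numeric(D) || length(D) != 1L) {
      stop("'D' must be a single number or \"uniform\"")
    }
    if (D < -min(maf^2, (1 - maf)^2) || D > d_max) {
      stop("'D' out of bounds; admissible range is [",
           format(-min(maf^2, (1 - maf)^2)), ", ", format(d_max),
           "] (D_max = ", format(d_max), ") for maf = ", maf)
    }
  }
  if (n_subjects < 1) stop("'n_subjects' must be >= 1")
  structure(
    list(gene_sizes = gene_sizes, maf = maf, D = D, ploidy = ploidy,
         n_subjects = n_subjects, d_max = d_max),
    class = "ld_config"
  )
}

# One haplotype block: subjects x loci 0/1 matrix, adjacent loci coupled
# through the two-locus conditional law
#   P(A|B) = (qA qB + D)/qB,  P(A|b) = (qA(1-qB) - D)/(1-qB),
# which preserves the marginal allele frequency at every locus.
.simulate_haplotypes <- function(n_subj, n_loci, q, D) {
  h <- matrix(0L, n_subj, n_loci)
  h[, 1] <- as.integer(stats::runif(n_subj) < q)
  if (n_loci >= 2) {
    for (j in 2:n_loci) {
      d_j <- if (identical(D, "uniform")) stats::runif(1, 0, q * (1 - q)) else D
      p_AB <- (q * q + d_j) / q        # P(minor | left neighbor minor)
      p_Ab <- (q * (1 - q) - d_j) / (1 - q)
      prob <- ifelse(h[, j - 1] == 1L, p_AB, p_Ab)
      h[, j] <- as.integer(stats::runif(n_subj) < prob)
    }
  }
  h
}

#' Simulate pathway genotypes under pairwise LD
#'
#' Within each gene, locus 1 is Bernoulli(`maf`) and each subsequent locus
#' is drawn conditionally on its left neighbor from the two-locus LD law,
#' so adjacent within-gene loci have allelic correlation
#' `R = D / (maf * (1 - maf))` and loci `k` apart have correlation `R^k`.
#' Genes are independent. Diploid genotypes are the sum of two independent
#' haplotypes (0/1/2 coding).
#'
#' @param cfg an [ld_config()] object.
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @return integer matrix, subjects in rows, variants in columns; column
#'   names `G<gene>.<locus>`.
#' @examples
#' g <- simulate_genotypes(ld_config(n_subjects = 50, D = 0.15), seed = 1)
#' dim(g)
#' @export
simulate_genotypes <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "ld_config"))
  if (!is.null(seed)) set.seed(seed)
  n_hap <- if (cfg$ploidy == "diploid") 2L else 1L
  blocks <- lapply(seq_along(cfg$gene_sizes), function(g) {
    n_loci <- cfg$gene_sizes[g]
    gm <- .simulate_haplotypes(cfg$n_subjects, n_loci, cfg$maf, cfg$D)
    if (n_hap == 2L) {
      gm <- gm + .simulate_haplotypes(cfg$n_subjects, n_loci, cfg$maf, cfg$D)
    }
    colnames(gm) <- paste0("G", g, ".", seq_len(n_loci))
    gm
  })
  do.call(cbind, blocks)
}

#' Logistic disease models I-VI for the five-gene pathway
#'
#' Returns the term structure of one of six disease-susceptibility models
#' on the G1(12)...G5(2) pathway. Each term is a set of variant labels
#' whose genotype product enters the linear predictor with a shared
#' coefficient `beta`; multi-variant terms are epistatic interactions
#' (e.g. case IV carries the three-way product G1.8 x G1.10 x G1.11).
#'
#' @param case one of `"I"`..`"VI"`.
#' @param beta shared effect size for all coefficients.
#' @return list of class `"disease_model"` with `case`, `beta`, and
#'   `terms` (list of character vectors of variant names).
#' @export
disease_model <- function(case = c("I", "II", "III", "IV", "V", "VI"),
                          beta = 0) {
  case <- match.arg(case)
  terms <- switch(case,
    I   = list("G1.2", "G1.5", "G1.7", "G1.8", "G1.12"),
    II  = list("G2.2", "G2.4", "G2.6", "G3.2", "G3.3"),
    III = list("G3.2", "G3.4", "G4.1", "G4.3", "G5.1"),
    IV  = list("G1.1", "G1.3", "G1.7",
               c("G1.8", "G1.10", "G1.11"), "G1.12"),
    V   = list("G3.1", "G3.3", "G4.2",
               c("G3.2", "G3.4"), c("G4.3", "G5.1")),
    VI  = list("G1.2", "G2.2", "G3.3", "G5.2",
               c("G1.5", "G1.7"), c("G3.3", "G5.1"))
  )
  structure(list(case = case, beta = beta, terms = terms),
            class = "disease_model")
}

#' Simulate a binary phenotype under a logistic disease model
#'
#' The linear predictor is `eta = sum_k beta * prod(genotypes in term k)`
#' with no intercept, so under the null (`beta = 0`, or all genotypes 0)
#' the disease prevalence is exactly 0.5. `Y ~ Bernoulli(plogis(eta))`.
#'
#' @param genotypes subject x variant matrix with variant column names.
#' @param model a [disease_model()].
#' @param seed integer seed.
#' @return integer 0/1 vector, one per subject.
#' @export
simulate_phenotype <- function(genotypes, model, seed = NULL) {
  stopifnot(inherits(model, "disease_model"))
  vars <- unique(unlist(model$terms))
  missing_v <- setdiff(vars, colnames(genotypes))
  if (length(missing_v) > 0) {
    stop("genotype matrix lacks model variants: ",
         paste(missing_v, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  eta <- rep(0, nrow(genotypes))
  for (term in model$terms) {
    prod_g <- genotypes[, term[1]]
    if (length(term) > 1) {
      for (v in term[-1]) prod_g <- prod_g * genotypes[, v]
    }
    eta <- eta + model$beta * prod_g
  }
  as.integer(stats::runif(nrow(genotypes)) < stats::plogis(eta))
}

#' Per-variant association tests against a binary phenotype
#'
#' `trend` is the score test of the logistic model (equivalent to the
#' Cochran-Armitage trend test on allele counts): `U = sum g (y - ybar)`,
#' `Var(U) = ybar (1 - ybar) sum (g - gbar)^2`, two-sided normal p-value
#' from `z = U / sqrt(Var(U))`. Closed-form, so millions of tests run in
#' vectorized matrix arithmetic. `logistic` fits a single-variant logistic
#' regression per variant and reports the Wald p-value (asymptotically
#' equivalent, much slower).
#'
#' A constant genotype column carries no information and is assigned
#' `p = 1`.
#'
#' @param genotypes subject x variant matrix.
#' @param phenotype 0/1 vector with both classes present.
#' @param method `"trend"` or `"logistic"`.
#' @return named numeric vector of two-sided p-values, one per variant.
#' @export
per_variant_test <- function(genotypes, phenotype,
                             method = c("trend", "logistic")) {
  method <- match.arg(method)
  y <- as.numeric(phenotype)
  if (length(unique(y)) < 2) {
    stop("phenotype must contain both classes")
  }
  if (method == "trend") {
    p <- trend_test_matrix(genotypes, matrix(y, ncol = 1))[, 1]
  } else {
    p <- apply(genotypes, 2, function(g) {
      if (stats::var(g) == 0) return(1)
      fit <- suppressWarnings(
        stats::glm(y ~ g, family = stats::binomial())
      )
      co <- summary(fit)$coefficients
      if (nrow(co) < 2 || !is.finite(co[2, 4])) 1 else co[2, 4]
    })
  }
  stats::setNames(pmax(p, .Machine$double.xmin), colnames(genotypes))
}

#' Vectorized trend tests for many phenotype vectors at once
#'
#' Workhorse behind [per_variant_test()] and the permutation covariance
#' estimator: computes the score-test p-value for every (variant,
#' phenotype-column) pair in one matrix product.
#'
#' @param genotypes subject x variant matrix.
#' @param Y subject x replicate 0/1 matrix (each column a phenotype).
#' @return variant x replicate matrix of two-sided p-values.
#' @keywords internal
trend_test_matrix <- function(genotypes, Y) {
  G <- as.matrix(genotypes)
  Gc <- sweep(G, 2, colMeans(G))           # center variants
  ss_g <- colSums(Gc^2)
  ybar <- colMeans(Y)
  U <- crossprod(Gc, Y)                    # variant x replicate scores
  vy <- ybar * (1 - ybar)                  # per-replicate Bernoulli var
  V <- outer(ss_g, vy)                     # Var(U) = vy * ss_g
  z2 <- matrix(0, nrow(U), ncol(U))
  ok <- V > 0
  z2[ok] <- U[ok]^2 / V[ok]
  p <- matrix(1, nrow(U), ncol(U))
  p[ok] <- stats::pchisq(z2[ok], df = 1, lower.tail = FALSE)
  rownames(p) <- colnames(G)
  p
}

#' Per-test weights for a pathway genotype layout
#'
#' Expands gene sizes into one weight per variant: every SNP in gene `g`
#' gets the weight implied by that gene's size under the chosen scheme.
#'
#' @param gene_sizes positive integers per gene.
#' @inheritParams weights_from_gene_sizes
#' @return numeric weight vector of length `sum(gene_sizes)`.
#' @export
pathway_weights <- function(gene_sizes, scheme = "inv") {
  rep(weights_from_gene_sizes(gene_sizes, scheme), times = gene_sizes)
}
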