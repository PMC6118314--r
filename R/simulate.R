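#' Simulate founder genotypes
#'
#' Founders are fully homozygous inbred lines at `p` unlinked biallelic
#' loci, coded -1/+1 for the two homozygotes. Per-locus allele frequencies
#' are drawn uniformly on `[freq_range[1], freq_range[2]]` and genotypes
#' sampled independently per line.
#'
#' @param n Number of founder lines (>= 2).
#' @param p Number of loci (>= 2).
#' @param seed Optional integer seed.
#' @param freq_range Allele-frequency range, default `c(0.05, 0.95)`.
#' @return An n x p matrix of -1/+1 genotypes with line identifiers as row
#'   names and the sampled frequencies as attribute `"freq"`.
#' @export
simulate_founders <- function(n, p, seed = NULL, freq_range = c(0.05, 0.95)) {
  if (n < 2 || p < 2) stop("`n` and `p` must both be at least 2")
  if (!is.null(seed)) set.seed(seed)
  f <- stats::runif(p, freq_range[1], freq_range[2])
  X <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    X[, j] <- ifelse(stats::runif(n) < f[j], 1L, -1L)
  }
  rownames(X) <- sprintf("L%04d", seq_len(n))
  attr(X, "freq") <- f
  X
}

#' Sample univariate gene effects
#'
#' Effect magnitudes are iid Gamma(shape = 2, scale = 2); signs are random
#' +/- by default (`signs = "positive"` keeps all effects positive, for a
#' trait whose alleles all act in one direction).
#'
#' @param p Number of loci.
#' @param shape,scale Gamma parameters (default 2 and 2).
#' @param signs `"random"` (default) or `"positive"`.
#' @param seed Optional integer seed.
#' @return A length-p effect vector.
#' @export
sample_effects_univariate <- function(p, shape = 2, scale = 2,
                                      signs = c("random", "positive"),
                                      seed = NULL) {
  signs <- match.arg(signs)
  if (p < 1) stop("`p` must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  b <- stats::rgamma(p, shape = shape, scale = scale)
  if (signs == "random") b <- b * sample(c(-1, 1), p, replace = TRUE)
  b
}

#' Default genetic-correlation targets of the three-trait design
#'
#' Correlation matrix with r(T1,T2) = -0.37, r(T2,T3) = 0.34 and
#' r(T1,T3) = -0.02: one antagonistic pair, one favorable pair and one
#' near-independent pair.
#'
#' @return A 3 x 3 correlation matrix.
#' @export
default_cor_targets <- function() {
  matrix(c(1, -0.37, -0.02,
           -0.37, 1, 0.34,
           -0.02, 0.34, 1), 3, 3,
         dimnames = list(c("T1", "T2", "T3"), c("T1", "T2", "T3")))
}

#' Sample pleiotropic multi-trait gene effects
#'
#' Fully pleiotropic architecture: each locus carries a t-vector of effects
#' drawn iid from `MVN(0, Sigma_b)` where `Sigma_b` has unit variances and
#' the target correlations. Because genotypes are independent across loci,
#' the expected correlation of true breeding values equals the effect
#' correlation, so founder TBV correlations approximate the targets.
#'
#' @param p Number of loci.
#' @param cor_targets Target correlation matrix (default
#'   [default_cor_targets()]).
#' @param sd Per-trait effect standard deviations (default 1).
#' @param seed Optional integer seed.
#' @return A p x t effect matrix.
#' @export
sample_effects_multitrait <- function(p, cor_targets = default_cor_targets(),
                                      sd = NULL, seed = NULL) {
  C <- as.matrix(cor_targets)
  t_tr <- nrow(C)
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("correlation target matrix is not positive definite")
  if (is.null(sd)) sd <- rep(1, t_tr)
  Sigma <- diag(sd) %*% C %*% diag(sd)
  if (!is.null(seed)) set.seed(seed)
  B <- .rmvn(p, rep(0, t_tr), Sigma)
  colnames(B) <- colnames(C)
  B
}

#' Trait architecture: effects plus residual calibration
#'
#' Binds gene effects to target heritabilities and derives per-trait
#' residual variances `sigma2_e = sigma2_g * (1 - h2) / h2` from the
#' realized genetic variance of a reference (founder) population. The
#' residual variance is calibrated once here and, by default, held fixed
#' across cycles so realized heritability drifts as genetic variance
#' erodes.
#'
#' A target `h2 = 0` denotes a pure-noise trait: the phenotype carries no
#' genetic signal at all (the ratio formula is undefined there), and the
#' residual variance is set to the founder genetic variance.
#'
#' @param effects p-vector or p x t matrix of gene effects.
#' @param h2 Target narrow-sense heritabilities, one per trait, in `[0, 1]`.
#' @param founders Founder genotype matrix used to realize genetic variances.
#' @return An object of class `"trait_architecture"`: list with `effects`
#'   (p x t matrix), `h2`, `sigma2_e`, `sigma2_g_founder`, `n_traits`.
#' @export
trait_architecture <- function(effects, h2, founders) {
  B <- if (is.matrix(effects)) effects else matrix(effects, ncol = 1)
  t_tr <- ncol(B)
  if (length(h2) == 1) h2 <- rep(h2, t_tr)
  if (length(h2) != t_tr) stop("`h2` length must match the trait count")
  if (any(h2 < 0 | h2 > 1)) stop("`h2` must lie in [0, 1]")
  TBV <- founders %*% B
  vg <- apply(TBV, 2, stats::var)
  if (any(vg <= 0 & h2 > 0)) stop("zero realized genetic variance with h2 > 0")
  s2e <- numeric(t_tr)
  for (k in seq_len(t_tr)) {
    s2e[k] <- if (h2[k] == 0) vg[k]
      else if (h2[k] == 1) 0
      else vg[k] * (1 - h2[k]) / h2[k]
  }
  structure(
    list(effects = B, h2 = h2, sigma2_e = s2e, sigma2_g_founder = vg,
         n_traits = t_tr),
    class = "trait_architecture"
  )
}

#' Simulate phenotypes for a population
#'
#' True breeding values are `TBV = X b`; phenotypes add iid normal residuals
#' with the architecture's per-trait residual variances (optionally
#' recalibrated to the current population's genetic variance). For a trait
#' with target `h2 = 0` the phenotype is residual noise only, independent
#' of the genotype.
#'
#' @param genotypes n x p genotype matrix.
#' @param arch A [trait_architecture()].
#' @param seed Optional integer seed.
#' @param recalibrate Recompute `sigma2_e` from the current population's
#'   genetic variance instead of the founder calibration (default `FALSE`).
#' @return A list of class `"population"`: `genotypes`, `tbv` (n x t),
#'   `phenotypes` (n x t), `arch`.
#' @export
simulate_phenotypes <- function(genotypes, arch, seed = NULL, recalibrate = FALSE) {
  stopifnot(inherits(arch, "trait_architecture"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  TBV <- genotypes %*% arch$effects
  s2e <- arch$sigma2_e
  if (recalibrate) {
    vg <- apply(TBV, 2, stats::var)
    for (k in seq_len(arch$n_traits)) {
      if (arch$h2[k] > 0 && arch$h2[k] < 1) s2e[k] <- vg[k] * (1 - arch$h2[k]) / arch$h2[k]
    }
  }
  E <- matrix(stats::rnorm(n * arch$n_traits), n, arch$n_traits) %*% diag(sqrt(s2e), arch$n_traits)
  Y <- matrix(0, n, arch$n_traits)
  for (k in seq_len(arch$n_traits)) {
    Y[, k] <- if (arch$h2[k] == 0) E[, k] else TBV[, k] + E[, k]
  }
  rownames(TBV) <- rownames(Y) <- rownames(genotypes)
  colnames(TBV) <- colnames(Y) <- colnames(arch$effects)
  structure(list(genotypes = genotypes, tbv = TBV, phenotypes = Y, arch = arch),
            class = "population")
}

#' Cross selected parents to produce offspring
#'
#' Doubled-haploid convention on fully homozygous parents: every offspring
#' comes from a uniformly drawn pair of distinct parents, and at each locus
#' the doubled gamete carries one of the two parental alleles with equal
#' probability, so genotypes stay in -1/+1. Loci assort independently.
#'
#' @param parents Genotype matrix of the selected parents (>= 2 rows).
#' @param n_offspring Number of offspring to produce.
#' @param seed Optional integer seed.
#' @return An n_offspring x p genotype matrix with new line identifiers and
#'   a `"pedigree"` attribute (two-column matrix of parent row indices).
#' @export
make_crosses <- function(parents, n_offspring, seed = NULL) {
  parents <- as.matrix(parents)
  np <- nrow(parents)
  if (np < 2) stop("at least two selected parents are required")
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(parents)
  ped <- t(vapply(seq_len(n_offspring),
                  function(i) sample.int(np, 2, replace = FALSE),
                  integer(2)))
  P1 <- parents[ped[, 1], , drop = FALSE]
  P2 <- parents[ped[, 2], , drop = FALSE]
  pick <- matrix(stats::runif(n_offspring * p) < 0.5, n_offspring, p)
  off <- ifelse(pick, P1, P2)
  rownames(off) <- sprintf("O%04d", seq_len(n_offspring))
  attr(off, "pedigree") <- ped
  off
}
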