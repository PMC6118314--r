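# Independent oracles used across tests. These deliberately avoid the code
# paths they check: plain numerical integration, rejection sampling and
# hand-written densities.

# E(Y | Y >= yc) for Y ~ N(mu, s2) by quadrature
oracle_trunc_mean <- function(mu, s2, yc) {
  s <- sqrt(s2)
  z <- stats::pnorm(yc, mu, s, lower.tail = FALSE)
  stats::integrate(function(y) y * stats::dnorm(y, mu, s) / z,
                   yc, Inf, rel.tol = 1e-10)$value
}

# KL divergence between the left-truncated N(mu1, s2) and N(mu2, s2) by
# direct quadrature of the defining integral
oracle_kl_integral <- function(mu1, s2, yc, mu2) {
  s <- sqrt(s2)
  z <- stats::pnorm(yc, mu1, s, lower.tail = FALSE)
  f <- function(y) {
    lt <- stats::dnorm(y, mu1, s, log = TRUE) - log(z)
    (lt - stats::dnorm(y, mu2, s, log = TRUE)) * exp(lt)
  }
  stats::integrate(f, yc, Inf, rel.tol = 1e-10)$value
}

# CRPS of N(mu2, s2) against target point by quadrature of the
# (F(x) - 1(x >= target))^2 integral
oracle_crps_integral <- function(mu2, s2, target) {
  s <- sqrt(s2)
  lo <- min(mu2, target) - 12 * s
  hi <- max(mu2, target) + 12 * s
  stats::integrate(function(x) (stats::pnorm(x, mu2, s) - (x >= target))^2,
                   lo, hi, rel.tol = 1e-10)$value
}

# hand-written MVN log density
oracle_dmvnorm_log <- function(x, mu, S) {
  t_tr <- length(mu)
  ch <- chol(S)
  logdet <- 2 * sum(log(diag(ch)))
  d <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * (t_tr * log(2 * pi) + logdet + sum(d^2))
}

# rejection sampler for the upper-orthant-truncated MVN
oracle_tmvn_sample <- function(n_keep, mu, S, yc) {
  ch <- chol(S)
  acc <- matrix(numeric(0), 0, length(mu))
  while (nrow(acc) < n_keep) {
    Z <- matrix(stats::rnorm(5e4 * length(mu)), 5e4)
    X <- sweep(Z %*% ch, 2, mu, `+`)
    keep <- rep(TRUE, nrow(X))
    for (k in seq_along(yc)) keep <- keep & (X[, k] >= yc[k])
    acc <- rbind(acc, X[keep, , drop = FALSE])
  }
  acc[seq_len(n_keep), , drop = FALSE]
}

# small homozygote-coded genotype matrix with non-degenerate columns
make_test_genotypes <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(sample(c(-1, 1), n * p, replace = TRUE), n, p)
  rownames(X) <- sprintf("L%04d", seq_len(n))
  X
}
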