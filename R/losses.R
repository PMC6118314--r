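#' Univariate Kullback-Leibler loss
#'
#' Kullback-Leibler divergence between a candidate's distribution
#' `N(mu2, sigma2)` and the truncated-normal distribution of the selected
#' parents, used as a selection loss:
#' `-log(z) + [(muS - mu2)^2 - (muS - mu1)^2] / (2 sigma2)`.
#' Algebraically this equals `-log(z) + 0.5 * ((S - R)^2 / sigma2 - i^2)`
#' with `R = mu2 - mu1`.
#'
#' @param trunc A [truncated_normal_summary()] for the base population.
#' @param mu2 Candidate mean(s); vectorized.
#' @return Loss value(s), one per element of `mu2`.
#' @examples
#' tr <- truncated_normal_summary(0, 1, 0)
#' kl_univariate(tr, 0)       # -log(0.5)
#' kl_univariate(tr, tr$muS)  # candidate matching the selected parents
#' @export
kl_univariate <- function(trunc, mu2) {
  stopifnot(inherits(trunc, "truncation_summary"))
  if (trunc$z <= 0) stop("degenerate truncation: z must be positive")
  -log(trunc$z) +
    ((trunc$muS - mu2)^2 - (trunc$muS - trunc$mu1)^2) / (2 * trunc$sigma2)
}

#' Univariate Kullback-Leibler loss in heritability form
#'
#' Closed heritability form of [kl_univariate()]:
#' `-log(z) + 0.5 * i^2 * h2 * (h2 - 2)`, obtained by substituting the
#' breeder's equation `R = h2 * S`. Strictly decreasing in `h2` for fixed
#' intensity `i > 0`.
#'
#' @param i Selection intensity (>= 0); vectorized.
#' @param h2 Narrow-sense heritability in `[0, 1]`; vectorized.
#' @param z Retained (truncation) probability in (0, 1].
#' @return Loss value(s).
#' @export
kl_univariate_h2 <- function(i, h2, z) {
  if (any(z <= 0 | z > 1)) stop("`z` must lie in (0, 1]")
  if (any(h2 < 0 | h2 > 1)) stop("`h2` must lie in [0, 1]")
  -log(z) + 0.5 * i^2 * h2 * (h2 - 2)
}

#' Continuous Ranked Probability Score loss
#'
#' CRPS between the candidate predictive distribution `N(mu2, sigma^2)` and
#' the selected-parent mean `muS`, written in terms of the deviation
#' `e = muS - mu2`:
#' `-sigma * (c - 2*phi(e/sigma) - (e/sigma) * (2*Phi(e/sigma) - 1))`.
#' The default convention takes `c = 1/pi`; `constant = "sqrt_pi"` uses
#' `1/sqrt(pi)`, which makes the expression the exact closed-form CRPS of a
#' Gaussian. The two differ by a candidate-independent offset proportional
#' to `sigma`, so rankings of candidates sharing `sigma` are identical
#' under either constant.
#'
#' @param e Deviation(s) `muS - mu2`; vectorized.
#' @param sigma Predictive standard deviation (> 0).
#' @param constant `"pi"` (default) or `"sqrt_pi"`.
#' @return Loss value(s).
#' @examples
#' crps_univariate(0, 1)                           # 0.4796
#' crps_univariate(0, 1, constant = "sqrt_pi")  # sigma * (2*phi(0) - 1/sqrt(pi))
#' @export
crps_univariate <- function(e, sigma = 1, constant = c("pi", "sqrt_pi")) {
  constant <- match.arg(constant)
  if (any(sigma <= 0)) stop("`sigma` must be positive")
  k <- if (constant == "pi") 1 / pi else 1 / sqrt(pi)
  u <- e / sigma
  -sigma * (k - 2 * stats::dnorm(u) - u * (2 * stats::pnorm(u) - 1))
}

#' CRPS loss in heritability form
#'
#' Heritability form of [crps_univariate()] obtained from
#' `e = sigma * i * (1 - h2)`; decreasing in `h2` for fixed `i > 0`.
#'
#' @inheritParams kl_univariate_h2
#' @inheritParams crps_univariate
#' @export
crps_h2 <- function(i, h2, sigma = 1, constant = c("pi", "sqrt_pi")) {
  if (any(h2 < 0 | h2 > 1)) stop("`h2` must lie in [0, 1]")
  crps_univariate(sigma * i * (1 - h2), sigma, constant = match.arg(constant))
}

#' Linear-linear (pinball) loss
#'
#' Asymmetric piecewise-linear loss `(alpha - 1(e < 0)) * e`: a deviation
#' `e = muS - mu2 > 0` (candidate mean short of the selected-parent mean) is
#' penalized with slope `alpha`, an overshoot with slope `1 - alpha`. At
#' `alpha = 0.5` the loss is symmetric.
#'
#' @param e Deviation(s); vectorized.
#' @param alpha Asymmetry parameter in (0, 1).
#' @return Non-negative loss value(s).
#' @examples
#' linlin(2, 0.9)   # 1.8
#' linlin(-2, 0.9)  # 0.2
#' @export
linlin <- function(e, alpha) {
  if (length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single value in (0, 1)")
  }
  (alpha - (e < 0)) * e
}

#' Multivariate Kullback-Leibler loss
#'
#' KL divergence between a candidate's multivariate-normal distribution
#' `MVN(mu2, P)` and the truncated-MVN distribution of the selected parents:
#' `-log(z) + 0.5 * (e' P^-1 e - S' P^-1 S)` with `e = muS - mu2` and
#' `S = muS - mu1`.
#'
#' @param trunc A [mv_truncation_summary()] for the base population.
#' @param mu2 Candidate mean vector (length t).
#' @return Loss value.
#' @seealso [kl_multivariate_struct()] for the structural form in terms of
#'   `S`, `G` and `P`.
#' @export
kl_multivariate <- function(trunc, mu2) {
  stopifnot(inherits(trunc, "mv_truncation_summary"))
  if (trunc$z <= 0) stop("degenerate truncation: z must be positive")
  e <- trunc$muS - as.numeric(mu2)
  Pinv_e <- solve(trunc$P, e)
  Pinv_S <- solve(trunc$P, trunc$S)
  -log(trunc$z) + 0.5 * (sum(e * Pinv_e) - sum(trunc$S * Pinv_S))
}

#' Multivariate Kullback-Leibler loss, structural form
#'
#' Evaluates the multivariate KL loss with the candidate mean eliminated via
#' the matrix breeder's equation `R = G P^-1 S`:
#' `-log(z) + 0.5 * S' [(I - G P^-1)' P^-1 (I - G P^-1) - P^-1] S`.
#' At t = 1 with `G = h2 * P` this reduces to the univariate heritability
#' form [kl_univariate_h2()].
#'
#' @param S Selection-differential vector (length t).
#' @param G Genotypic covariance matrix (t x t).
#' @param P Phenotypic covariance matrix (t x t, positive definite).
#' @param z Orthant (retained) probability in (0, 1].
#' @return Loss value.
#' @export
kl_multivariate_struct <- function(S, G, P, z) {
  S <- as.numeric(S); G <- as.matrix(G); P <- as.matrix(P)
  if (z <= 0 || z > 1) stop("`z` must lie in (0, 1]")
  Pinv <- tryCatch(solve(P), error = function(e) stop("covariance `P` is singular"))
  A <- diag(length(S)) - G %*% Pinv
  M <- t(A) %*% Pinv %*% A - Pinv
  -log(z) + 0.5 * as.numeric(t(S) %*% M %*% S)
}

#' Energy score
#'
#' Monte-Carlo estimator of the energy score between a predictive sample of
#' the candidate vector `Yo` and the selected-parent mean `muS`:
#' `E||Yo - muS|| - 0.5 * E||Yo - Yo'||`, with the two independent copies
#' realized by splitting the draw stream into disjoint halves (or taken from
#' `draws2` when supplied). This is the multivariate generalization of the
#' CRPS; in one dimension with `Yo ~ N(muS, sigma^2)` it converges to
#' `sigma * (2*phi(0) - 1/sqrt(pi))`.
#'
#' @param draws Matrix of predictive draws (m x t), or a numeric vector for
#'   a single trait. Each row is one draw of `Yo`.
#' @param muS Selected-parent mean: a length-t vector, or an m x t matrix
#'   giving one target per draw.
#' @param draws2 Optional second independent draw stream (m2 x t).
#' @return Estimated energy score (non-negative in expectation).
#' @export
energy_score <- function(draws, muS, draws2 = NULL) {
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1)
  m <- nrow(draws)
  if (m < 2) stop("at least 2 predictive draws are required")
  if (is.matrix(muS)) {
    if (nrow(muS) != m || ncol(muS) != ncol(draws)) {
      stop("per-draw `muS` must be an m x t matrix")
    }
    D1 <- draws - muS
  } else {
    D1 <- sweep(draws, 2, as.numeric(muS))
  }
  term1 <- mean(sqrt(rowSums(D1^2)))
  if (is.null(draws2)) {
    half <- m %/% 2
    A <- draws[seq_len(half), , drop = FALSE]
    B <- draws[half + seq_len(half), , drop = FALSE]
  } else {
    if (is.vector(draws2)) draws2 <- matrix(draws2, ncol = 1)
    k <- min(m, nrow(draws2))
    A <- draws[seq_len(k), , drop = FALSE]
    B <- draws2[seq_len(k), , drop = FALSE]
  }
  term2 <- mean(sqrt(rowSums((A - B)^2)))
  term1 - 0.5 * term2
}

#' Multivariate asymmetric loss function (MALF)
#'
#' Asymmetric generalization of the linear-linear loss to trait vectors. In
#' the L2 form the loss is `(||e|| + tau'e) * ||e||` with `||.||` the
#' Euclidean norm; the L1 form is `sum(|e|) + tau'e`. In one dimension with
#' `tau = 2*alpha - 1` the L1 form equals twice the linear-linear loss.
#' Positivity is only guaranteed for `||tau|| <= 1` (L2) or `max|tau| <= 1`
#' (L1); a larger asymmetry vector triggers a warning, not an error.
#'
#' @param e Deviation vector `muS - mu2` (length t).
#' @param tau Asymmetry vector (length t).
#' @param norm `"L2"` (default) or `"L1"`.
#' @return Loss value.
#' @examples
#' malf(2, 0.8, norm = "L1")    # 3.6 = 2 * linlin(2, 0.9)
#' malf(c(3, 4), c(0, 0))       # 25 = ||e||^2
#' @export
malf <- function(e, tau, norm = c("L2", "L1")) {
  norm <- match.arg(norm)
  e <- as.numeric(e); tau <- as.numeric(tau)
  if (length(e) != length(tau)) stop("`e` and `tau` must have the same length")
  if (norm == "L2") {
    if (sqrt(sum(tau^2)) > 1) {
      warning("||tau|| > 1: the L2 MALF can take negative values")
    }
    ne <- sqrt(sum(e^2))
    (ne + sum(tau * e)) * ne
  } else {
    if (max(abs(tau)) > 1) {
      warning("max|tau| > 1: the L1 MALF can take negative values")
    }
    sum(abs(e)) + sum(tau * e)
  }
}
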