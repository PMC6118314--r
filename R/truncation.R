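#' Truncation threshold from a selection pressure
#'
#' Converts a selection pressure (the fraction of the population retained in
#' the upper tail) into the phenotypic truncation threshold `yc` under a
#' normal base population, i.e. the `yc` such that `Pr(Y > yc) = q` for
#' `Y ~ N(mu1, sigma2)`.
#'
#' @param mu1 Base-population mean.
#' @param sigma2 Base-population variance (> 0).
#' @param q Selection pressure in (0, 1): the retained upper-tail fraction.
#' @return The truncation threshold `yc` on the phenotype scale.
#' @examples
#' truncation_point_from_pressure(0, 1, 0.5)   # 0
#' truncation_point_from_pressure(10, 4, 0.1)
#' @export
truncation_point_from_pressure <- function(mu1, sigma2, q) {
  stopifnot(is.numeric(mu1), is.numeric(sigma2), is.numeric(q))
  if (sigma2 <= 0) stop("`sigma2` must be positive")
  if (any(q <= 0 | q >= 1)) stop("selection pressure `q` must lie in (0, 1)")
  stats::qnorm(q, mean = mu1, sd = sqrt(sigma2), lower.tail = FALSE)
}

#' Truncated-normal selection summary
#'
#' All selection-theory quantities implied by upper-tail truncation of a
#' normal base population at threshold `yc`: the truncation (retained)
#' probability `z = 1 - Phi((yc - mu1)/sigma)`, the selected-parent mean
#' `muS = mu1 + sigma * phi(d)/(1 - Phi(d))` with `d = (yc - mu1)/sigma`,
#' the selection differential `S = muS - mu1`, and the selection intensity
#' `i = S / sigma`.
#'
#' @param mu1 Base-population mean.
#' @param sigma2 Base-population variance (> 0).
#' @param yc Truncation threshold; `-Inf` means no truncation.
#' @return An object of class `"truncation_summary"`: a list with elements
#'   `mu1`, `sigma2`, `sigma`, `yc`, `z`, `muS`, `S`, `i`.
#' @examples
#' s <- truncated_normal_summary(0, 1, 0)
#' s$z    # 0.5
#' s$muS  # 0.7979
#' @export
truncated_normal_summary <- function(mu1, sigma2, yc) {
  stopifnot(is.numeric(mu1), is.numeric(sigma2), is.numeric(yc))
  if (sigma2 <= 0) stop("`sigma2` must be positive")
  sigma <- sqrt(sigma2)
  d <- (yc - mu1) / sigma
  z <- stats::pnorm(d, lower.tail = FALSE)
  if (z < 1e-12) {
    stop("degenerate truncation: retained probability below 1e-12")
  }
  # inverse Mills ratio, computed on the log scale for upper-tail stability
  i <- if (is.infinite(d) && d < 0) 0 else
    exp(stats::dnorm(d, log = TRUE) - stats::pnorm(d, lower.tail = FALSE, log.p = TRUE))
  muS <- mu1 + sigma * i
  structure(
    list(mu1 = mu1, sigma2 = sigma2, sigma = sigma, yc = yc,
         z = z, muS = muS, S = sigma * i, i = i),
    class = "truncation_summary"
  )
}

#' @export
print.truncation_summary <- function(x, ...) {
  cat("Truncated-normal selection summary\n")
  cat(sprintf("  base population : N(%.4g, %.4g)\n", x$mu1, x$sigma2))
  cat(sprintf("  threshold yc    : %.4g\n", x$yc))
  cat(sprintf("  retained z      : %.4g\n", x$z))
  cat(sprintf("  selected mean   : %.4g  (S = %.4g, i = %.4g)\n", x$muS, x$S, x$i))
  invisible(x)
}

# draws from MVN(mu, Sigma) via the upper Cholesky factor; internal
.rmvn <- function(n, mu, Sigma) {
  t <- length(mu)
  L <- chol(Sigma)  # upper, Sigma = t(L) %*% L
  Z <- matrix(stats::rnorm(n * t), n, t)
  sweep(Z %*% L, 2, mu, `+`)
}

.check_cov <- function(P, name = "P") {
  if (!is.matrix(P) || nrow(P) != ncol(P)) stop(sprintf("`%s` must be a square matrix", name))
  if (max(abs(P - t(P))) > 1e-8 * max(1, max(abs(P)))) stop(sprintf("`%s` must be symmetric", name))
  ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev
}

#' Multivariate-normal orthant probability
#'
#' Estimates `z = Pr(Y >= yc)` componentwise for `Y ~ MVN(mu1, P)` — the
#' normalization constant of the truncated multivariate normal distribution
#' of the selected parents. The univariate case is evaluated exactly; for
#' `t > 1` a seeded Monte-Carlo estimator is used.
#'
#' @param mu1 Mean vector (length t).
#' @param P Phenotypic covariance matrix (t x t, positive definite).
#' @param yc Threshold vector (length t); `-Inf` entries impose no truncation
#'   on that trait.
#' @param n_samples Monte-Carlo sample count (default 1e5).
#' @param seed Optional integer seed for the estimator.
#' @return Estimated orthant probability in (0, 1].
#' @examples
#' mvn_orthant_probability(c(0, 0), diag(2), c(0, 0), seed = 1)  # ~0.25
#' @export
mvn_orthant_probability <- function(mu1, P, yc, n_samples = 1e5, seed = NULL) {
  mu1 <- as.numeric(mu1); yc <- as.numeric(yc)
  if (length(mu1) != length(yc)) stop("`mu1` and `yc` must have the same length")
  if (length(mu1) == 1L) {
    P <- as.matrix(P)
    if (P[1, 1] <= 0) stop("covariance must be positive definite")
    return(stats::pnorm(yc, mu1, sqrt(P[1, 1]), lower.tail = FALSE))
  }
  ev <- .check_cov(P)
  if (min(ev) <= 0) stop("covariance `P` must be positive definite")
  if (nrow(P) != length(mu1)) stop("dimensions of `mu1` and `P` disagree")
  if (!is.null(seed)) set.seed(seed)
  X <- .rmvn(n_samples, mu1, P)
  keep <- rep(TRUE, n_samples)
  for (k in seq_along(yc)) keep <- keep & (X[, k] >= yc[k])
  mean(keep)
}

#' Mean of a truncated multivariate normal distribution
#'
#' Estimates `E(Y | Y >= yc)` for `Y ~ MVN(mu1, P)` by seeded rejection
#' sampling; the moment has no closed form for t > 1. The sampler tops up
#' in batches until at least `min_accept` draws land in the selection
#' orthant, and declares the truncation degenerate when the acceptance rate
#' indicates `z < 1e-12`.
#'
#' @inheritParams mvn_orthant_probability
#' @param min_accept Minimum number of accepted draws (default 1000).
#' @return The estimated mean vector of the selected parents.
#' @examples
#' tmvn_mean(c(0, 0), diag(2), c(0, 0), seed = 1)  # ~ (0.798, 0.798)
#' @export
tmvn_mean <- function(mu1, P, yc, n_samples = 1e5, min_accept = 1000, seed = NULL) {
  mu1 <- as.numeric(mu1); yc <- as.numeric(yc)
  P <- as.matrix(P)
  if (length(mu1) == 1L) {
    s <- truncated_normal_summary(mu1, P[1, 1], yc)
    return(s$muS)
  }
  ev <- .check_cov(P)
  if (min(ev) <= 0) stop("covariance `P` must be positive definite")
  if (all(is.infinite(yc) & yc < 0)) return(mu1)
  if (!is.null(seed)) set.seed(seed)
  acc <- matrix(numeric(0), 0, length(mu1))
  drawn <- 0
  repeat {
    X <- .rmvn(n_samples, mu1, P)
    keep <- rep(TRUE, nrow(X))
    for (k in seq_along(yc)) keep <- keep & (X[, k] >= yc[k])
    acc <- rbind(acc, X[keep, , drop = FALSE])
    drawn <- drawn + n_samples
    if (nrow(acc) >= min_accept) break
    if (drawn >= 1e8 || (drawn >= 1e7 && nrow(acc) == 0)) {
      stop("degenerate truncation: orthant probability too small to sample")
    }
  }
  colMeans(acc)
}

#' Truncated-multivariate-normal selection summary
#'
#' Multi-trait analogue of [truncated_normal_summary()]: the orthant
#' probability `z`, selected-parent mean vector `muS`, selection-differential
#' vector `S = muS - mu1`, and the response vector from the multivariate
#' breeder's equation `R = G P^-1 S`, where `P` is the phenotypic and `G`
#' the genotypic covariance matrix. When `G = P` (unit heritability in every
#' direction), `R = S`.
#'
#' @inheritParams mvn_orthant_probability
#' @param G Genotypic covariance matrix (t x t, positive semi-definite).
#' @param n_samples Monte-Carlo sample count for z and muS.
#' @param seed Optional integer seed.
#' @return An object of class `"mv_truncation_summary"`: a list with
#'   `mu1`, `P`, `G`, `yc`, `z`, `muS`, `S`, `R`.
#' @export
mv_truncation_summary <- function(mu1, P, G, yc, n_samples = 1e5, seed = NULL) {
  mu1 <- as.numeric(mu1); yc <- as.numeric(yc)
  P <- as.matrix(P); G <- as.matrix(G)
  evG <- .check_cov(G, "G")
  if (min(evG) < -1e-8 * max(1, max(abs(G)))) {
    stop("covariance `G` must be positive semi-definite")
  }
  if (!is.null(seed)) set.seed(seed)
  z <- mvn_orthant_probability(mu1, P, yc, n_samples = n_samples)
  if (z < 1e-12) stop("degenerate truncation: orthant probability below 1e-12")
  muS <- tmvn_mean(mu1, P, yc, n_samples = n_samples)
  S <- muS - mu1
  R <- as.numeric(G %*% solve(P, S))
  structure(
    list(mu1 = mu1, P = P, G = G, yc = yc, z = z, muS = muS, S = S, R = R),
    class = "mv_truncation_summary"
  )
}

#' @export
print.mv_truncation_summary <- function(x, ...) {
  cat("Truncated-MVN selection summary (", length(x$mu1), " traits)\n", sep = "")
  cat("  z   :", format(x$z, digits = 4), "\n")
  cat("  muS :", paste(format(x$muS, digits = 4), collapse = ", "), "\n")
  cat("  S   :", paste(format(x$S, digits = 4), collapse = ", "), "\n")
  cat("  R   :", paste(format(x$R, digits = 4), collapse = ", "), "\n")
  invisible(x)
}
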