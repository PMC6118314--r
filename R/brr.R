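#' MCMC chain settings
#'
#' Convenience constructor for Gibbs-sampler chain settings. The `"full"`
#' profile retains 10,000 samples after a 30,000-iteration burn-in; the
#' `"fast"` profile (500 retained after 500) is meant for tests and quick
#' exploration.
#'
#' @param profile `"full"` or `"fast"`, or `NULL` when giving the numbers
#'   directly.
#' @param niter Total iterations (including burn-in).
#' @param burnin Burn-in iterations discarded from the front of the chain.
#' @param thin Thinning interval.
#' @return A list with elements `niter`, `burnin`, `thin`.
#' @export
mcmc_settings <- function(profile = NULL, niter = 40000L, burnin = 30000L, thin = 1L) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("full", "fast"))
    if (profile == "full") { niter <- 40000L; burnin <- 30000L }
    else { niter <- 1000L; burnin <- 500L }
    thin <- 1L
  }
  stopifnot(niter > burnin, burnin >= 0, thin >= 1)
  list(niter = as.integer(niter), burnin = as.integer(burnin), thin = as.integer(thin))
}

#' Bayesian Ridge Regression Gibbs sampler
#'
#' Fits the whole-genome regression `y = 1*mu + X*beta + e` with independent
#' Gaussian priors `beta_j ~ N(0, sigma2_beta)`, scaled-inverse-chi-squared
#' priors on `sigma2_beta` and `sigma2_e` (df 5, prior modes at a 50/50
#' split of the sample phenotypic variance), and a flat prior on `mu`.
#' Marker effects are drawn jointly per iteration through a one-off
#' eigendecomposition of `X'X`, so the per-iteration cost is two p x p
#' matrix-vector products.
#'
#' @param y Numeric phenotype vector (length n >= 10).
#' @param markers n x p genotype matrix; centered internally, the centering
#'   vector is stored for candidate prediction.
#' @param mcmc Chain settings from [mcmc_settings()].
#' @param seed Optional integer seed; identical seeds give identical chains.
#' @return An object of class `"brr_fit"`: retained draws of `mu` (vector),
#'   `beta` (m x p), `sigma2_beta`, `sigma2_e` (vectors), plus `center`,
#'   `zero_variance` and the chain `settings`.
#' @export
fit_brr <- function(y, markers, mcmc = mcmc_settings("fast"), seed = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 10) stop("at least 10 training records are required")
  X <- if (is.null(attr(markers, "center"))) prepare_markers(markers) else markers
  if (nrow(X) != n) stop("phenotype and marker rows disagree")
  p <- ncol(X)
  if (!is.null(seed)) set.seed(seed)

  vy <- stats::var(y)
  sum_vx <- sum(colMeans(X^2))
  df0 <- 5
  # prior modes: half the phenotypic variance to residual, half to markers
  S0e <- 0.5 * vy * (df0 + 2) / df0
  S0b <- if (sum_vx > 0) 0.5 * vy / sum_vx * (df0 + 2) / df0 else 1e-6 * vy

  XtX <- crossprod(X)
  eg <- eigen(XtX, symmetric = TRUE)
  Q <- eg$vectors
  lam <- pmax(eg$values, 0)
  Xty <- crossprod(X, y)          # X is centered, so X'(y - mu) = X'y
  w <- crossprod(Q, Xty)[, 1]

  mu <- mean(y)
  s2e <- 0.5 * vy
  s2b <- S0b * df0 / (df0 + 2)
  beta <- numeric(p)
  g <- numeric(n)

  keep <- seq(from = mcmc$burnin + 1L, to = mcmc$niter, by = mcmc$thin)
  keep_flag <- logical(mcmc$niter); keep_flag[keep] <- TRUE
  m <- length(keep)
  out_mu <- numeric(m); out_s2b <- numeric(m); out_s2e <- numeric(m)
  out_beta <- matrix(0, m, p)
  k <- 0L
  for (it in seq_len(mcmc$niter)) {
    mu <- stats::rnorm(1, mean(y - g), sqrt(s2e / n))
    lambda <- s2e / s2b
    denom <- lam + lambda
    bt <- w / denom + sqrt(s2e / denom) * stats::rnorm(p)
    beta <- as.numeric(Q %*% bt)
    g <- as.numeric(X %*% beta)
    s2b <- (df0 * S0b + sum(beta^2)) / stats::rchisq(1, df0 + p)
    e <- y - mu - g
    s2e <- (df0 * S0e + sum(e^2)) / stats::rchisq(1, df0 + n)
    if (!is.finite(s2b) || !is.finite(s2e) || anyNA(beta)) {
      stop("sampler produced non-finite draws")
    }
    if (keep_flag[it]) {
      k <- k + 1L
      out_mu[k] <- mu; out_beta[k, ] <- beta
      out_s2b[k] <- s2b; out_s2e[k] <- s2e
    }
  }
  structure(
    list(mu = out_mu, beta = out_beta, sigma2_beta = out_s2b, sigma2_e = out_s2e,
         center = attr(X, "center"), zero_variance = attr(X, "zero_variance"),
         line_ids = rownames(X), settings = mcmc, seed = seed),
    class = "brr_fit"
  )
}

#' @export
print.brr_fit <- function(x, ...) {
  cat(sprintf("Bayesian Ridge Regression fit: %d retained draws, %d markers\n",
              length(x$mu), ncol(x$beta)))
  cat(sprintf("  posterior means: mu=%.4g sigma2_beta=%.4g sigma2_e=%.4g\n",
              mean(x$mu), mean(x$sigma2_beta), mean(x$sigma2_e)))
  invisible(x)
}

#' Predictive breeding-value draws
#'
#' One predictive draw per retained posterior draw per candidate, aligned
#' with the chain. For a BRR fit candidates are described by marker vectors;
#' for a multi-trait fit by rows of the genomic relationship matrix (see
#' [predictive_draws.mtm_fit()]). `type = "bv"` returns draws of the genetic
#' value plus intercept; `type = "phenotype"` adds residual noise drawn from
#' the per-draw residual variance, giving draws of the observable `Yo`.
#'
#' @param object A fitted model.
#' @param ... Method-specific arguments.
#' @return See methods.
#' @export
predictive_draws <- function(object, ...) UseMethod("predictive_draws")

#' @rdname predictive_draws
#' @param markers Candidate marker matrix (rows = candidates) on the same
#'   raw coding as the training matrix; centered with the training means.
#' @param type `"bv"` (default) or `"phenotype"`.
#' @export
predictive_draws.brr_fit <- function(object, markers, type = c("bv", "phenotype"), ...) {
  type <- match.arg(type)
  if (is.vector(markers)) markers <- matrix(markers, nrow = 1)
  if (ncol(markers) != ncol(object$beta)) {
    stop("candidate marker count does not match the fitted model")
  }
  Xc <- sweep(as.matrix(markers), 2, object$center)
  m <- length(object$mu)
  bv <- Xc %*% t(object$beta) + matrix(object$mu, nrow(Xc), m, byrow = TRUE)
  if (type == "phenotype") {
    bv <- bv + matrix(stats::rnorm(length(bv)), nrow(bv), m) *
      matrix(sqrt(object$sigma2_e), nrow(bv), m, byrow = TRUE)
  }
  rownames(bv) <- rownames(markers)
  bv
}
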