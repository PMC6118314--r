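# inverse-Wishart draw via the Wishart on the inverse scale
.riwish <- function(df, S) {
  Si <- solve((S + t(S)) / 2)
  W <- stats::rWishart(1, df, (Si + t(Si)) / 2)[, , 1]
  V <- solve(W)
  (V + t(V)) / 2
}

#' Multi-trait genomic mixed-model Gibbs sampler
#'
#' Fits `Y = 1 m' + U + E` for an n x t phenotype matrix: a fixed intercept
#' per trait, line genetic values `U` with `vec(U) ~ N(0, G (x) K)` for a
#' genomic relationship matrix `K` and genetic covariance `G`, and rows of
#' `E` iid `N(0, Rcov)`. `G` and `Rcov` carry inverse-Wishart priors
#' (df `t + 3`, scale half the sample phenotype covariance). Each iteration
#' works in the eigenbasis of `K` and simultaneously diagonalizes `G`
#' against `Rcov`, so the update of `U` is a fully vectorized elementwise
#' shrinkage — no per-line loops.
#'
#' Single-trait input (t = 1) is accepted; the inverse-Wisharts then reduce
#' to scaled-inverse-chi-squared updates and the model is the GBLUP
#' equivalent of [fit_brr()].
#'
#' @param Y n x t numeric phenotype matrix (column names are trait names).
#' @param K n x n genomic relationship matrix from [grm()], aligned with
#'   the rows of `Y`; jittered by 1e-8 on the diagonal before factorization.
#' @param mcmc Chain settings from [mcmc_settings()].
#' @param seed Optional integer seed.
#' @param store_u Keep the per-draw genetic values (needed for prediction
#'   and posterior-expected-loss work); default `TRUE`.
#' @return An object of class `"mtm_fit"`: draws of `m` (m x t), `G` and
#'   `Rcov` (t x t x m arrays), optionally `U` (n x t x m), plus metadata.
#' @export
fit_mtm <- function(Y, K, mcmc = mcmc_settings("fast"), seed = NULL, store_u = TRUE) {
  Y <- as.matrix(Y)
  n <- nrow(Y); t_tr <- ncol(Y)
  if (!all(dim(K) == n)) stop("`K` must be n x n and conformable with `Y`")
  if (anyNA(Y)) stop("`Y` contains missing values")
  if (!is.null(seed)) set.seed(seed)

  Kj <- (K + t(K)) / 2 + diag(1e-8, n)
  eg <- eigen(Kj, symmetric = TRUE)
  V <- eg$vectors
  d <- pmax(eg$values, 1e-10)
  VtY <- crossprod(V, Y)
  v1 <- crossprod(V, rep(1, n))[, 1]

  SY <- stats::cov(Y)
  if (t_tr == 1) SY <- matrix(SY, 1, 1)
  S0 <- 0.5 * (SY + diag(1e-8 * max(1, diag(SY)), t_tr))
  nu0 <- t_tr + 3

  m_vec <- colMeans(Y)
  G <- S0
  Rcov <- S0
  U <- matrix(0, n, t_tr)
  Ut <- crossprod(V, U)

  keep <- seq(from = mcmc$burnin + 1L, to = mcmc$niter, by = mcmc$thin)
  keep_flag <- logical(mcmc$niter); keep_flag[keep] <- TRUE
  m_keep <- length(keep)
  out_m <- matrix(0, m_keep, t_tr)
  out_G <- array(0, c(t_tr, t_tr, m_keep))
  out_R <- array(0, c(t_tr, t_tr, m_keep))
  out_U <- if (store_u) array(0, c(n, t_tr, m_keep)) else NULL
  k <- 0L
  for (it in seq_len(mcmc$niter)) {
    # intercepts: rows of Y - U are iid N(m, Rcov)
    cm <- colMeans(Y - U)
    m_vec <- cm + as.numeric(t(chol(Rcov)) %*% stats::rnorm(t_tr)) / sqrt(n)

    # genetic values in the K eigenbasis with G, Rcov jointly diagonalized
    Yc <- VtY - outer(v1, m_vec)
    Lr <- t(chol(Rcov))                 # lower, Rcov = Lr %*% t(Lr)
    A <- forwardsolve(Lr, G)
    W <- forwardsolve(Lr, t(A))
    ew <- eigen((W + t(W)) / 2, symmetric = TRUE)
    psi <- pmax(ew$values, 1e-12)
    Tm <- Lr %*% ew$vectors
    Ystar <- Yc %*% t(solve(Tm))
    H <- outer(d, psi)
    shrink <- H / (H + 1)
    Ustar <- shrink * Ystar +
      sqrt(shrink) * matrix(stats::rnorm(n * t_tr), n, t_tr)
    Ut <- Ustar %*% t(Tm)
    U <- V %*% Ut

    # genetic covariance
    SG <- S0 + crossprod(Ut, Ut / d)
    G <- .riwish(nu0 + n, SG)

    # residual covariance
    E <- Y - rep(1, n) %o% m_vec - U
    SR <- S0 + crossprod(E)
    Rcov <- .riwish(nu0 + n, SR)
    if (anyNA(G) || anyNA(Rcov)) stop("sampler produced non-finite draws")

    if (keep_flag[it]) {
      k <- k + 1L
      out_m[k, ] <- m_vec
      out_G[, , k] <- G
      out_R[, , k] <- Rcov
      if (store_u) out_U[, , k] <- U
    }
  }
  structure(
    list(m = out_m, G = out_G, Rcov = out_R, U = out_U,
         eigen_d = d, n = n, t = t_tr, trait_names = colnames(Y),
         line_ids = rownames(Y), settings = mcmc, seed = seed),
    class = "mtm_fit"
  )
}

#' @export
print.mtm_fit <- function(x, ...) {
  cat(sprintf("Multi-trait genomic mixed-model fit: %d lines, %d traits, %d draws\n",
              x$n, x$t, nrow(x$m)))
  Gm <- apply(x$G, c(1, 2), mean)
  cat("  posterior-mean genetic covariance:\n")
  print(round(Gm, 4))
  invisible(x)
}

#' @rdname predictive_draws
#' @param K Full genomic relationship matrix covering training and candidate
#'   lines.
#' @param train Integer or logical index of the rows of `K` the model was
#'   fitted on (in the fitted order).
#' @param cand Index of candidate rows of `K`.
#' @export
predictive_draws.mtm_fit <- function(object, K, train, cand,
                                     type = c("bv", "phenotype"), ...) {
  type <- match.arg(type)
  if (is.null(object$U)) stop("fit was run with store_u = FALSE; cannot predict")
  K11 <- K[train, train, drop = FALSE]
  K11 <- K11 + diag(1e-8, nrow(K11))
  K21 <- K[cand, train, drop = FALSE]
  K22 <- K[cand, cand, drop = FALSE]
  if (nrow(K11) != object$n) stop("`train` does not match the fitted model size")
  B <- K21 %*% solve(K11)
  Schur <- K22 - B %*% t(K21)
  Schur <- (Schur + t(Schur)) / 2 + diag(1e-8, nrow(K22))
  Ls <- t(chol(Schur))
  nc <- nrow(K21); t_tr <- object$t
  m_keep <- nrow(object$m)
  out <- array(0, c(nc, t_tr, m_keep))
  for (j in seq_len(m_keep)) {
    Gj <- matrix(object$G[, , j], t_tr, t_tr)
    Uj <- matrix(object$U[, , j], ncol = t_tr)
    mean_u <- B %*% Uj
    noise <- Ls %*% matrix(stats::rnorm(nc * t_tr), nc, t_tr) %*% chol(Gj)
    draw <- sweep(mean_u + noise, 2, object$m[j, ], `+`)
    if (type == "phenotype") {
      Rj <- matrix(object$Rcov[, , j], t_tr, t_tr)
      draw <- draw + matrix(stats::rnorm(nc * t_tr), nc, t_tr) %*% chol(Rj)
    }
    out[, , j] <- draw
  }
  dimnames(out) <- list(rownames(K)[cand], object$trait_names, NULL)
  out
}
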