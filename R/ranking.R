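# Gibbs sampler for the mean of a TMVN restricted to the upper orthant
# {x >= yc}; robust when the orthant probability is tiny (rejection is not).
.tmvn_gibbs_mean <- function(mu1, P, yc, sweeps = 400, burnin = 100) {
  t_tr <- length(mu1)
  if (t_tr == 1) return(truncated_normal_summary(mu1, P[1, 1], yc)$muS)
  w <- vector("list", t_tr); v <- numeric(t_tr)
  for (k in seq_len(t_tr)) {
    wk <- solve(P[-k, -k, drop = FALSE], P[-k, k])
    w[[k]] <- wk
    v[k] <- max(P[k, k] - sum(P[k, -k] * wk), 1e-12)
  }
  s <- sqrt(v)
  x <- pmax(mu1, ifelse(is.finite(yc), yc + 0.1 * sqrt(diag(P)), mu1))
  acc <- numeric(t_tr); nacc <- 0L
  for (it in seq_len(sweeps)) {
    for (k in seq_len(t_tr)) {
      mk <- mu1[k] + sum(w[[k]] * (x[-k] - mu1[-k]))
      if (is.finite(yc[k])) {
        plo <- stats::pnorm((yc[k] - mk) / s[k])
        u <- stats::runif(1, plo, 1)
        if (u >= 1) {
          x[k] <- yc[k] + 1e-10
        } else {
          x[k] <- mk + s[k] * stats::qnorm(u)
          if (!is.finite(x[k]) || x[k] < yc[k]) x[k] <- yc[k] + 1e-10
        }
      } else {
        x[k] <- stats::rnorm(1, mk, s[k])
      }
    }
    if (it > burnin) { acc <- acc + x; nacc <- nacc + 1L }
  }
  acc / nacc
}

#' Posterior expected loss for candidates, univariate engine
#'
#' Monte-Carlo average over retained posterior draws of a per-draw loss.
#' For every posterior draw the base-population parameters are recomputed
#' from that draw (mean and genetic variance of the base breeding-value
#' draws plus the draw's residual variance), the truncation threshold is
#' re-derived from the selection pressure `q`, and the candidate's loss is
#' evaluated at its predictive breeding value for that draw. The reported
#' expected loss is the arithmetic mean across draws.
#'
#' With `criterion = "Std"` no loss is computed: the returned score is the
#' posterior-mean breeding value (to be ranked descending).
#'
#' @param bv_base n_base x m matrix of base-population breeding-value draws
#'   (base population defines the parental truncated distribution).
#' @param bv_cand n_cand x m matrix of candidate breeding-value draws; row
#'   names are candidate identifiers.
#' @param sigma2_e Length-m vector of residual-variance draws.
#' @param q Selection pressure in (0, 1).
#' @param criterion One of `"KL"`, `"CRPS"`, `"LinLin"`, `"EnergyS"`, `"Std"`.
#' @param alpha LinLin asymmetry parameter.
#' @param constant CRPS constant convention, see [crps_univariate()].
#' @param yo_cand Optional n_cand x m matrix of predictive *phenotype* draws,
#'   required for `"EnergyS"` (the energy score is computed on draws of the
#'   observable, split into disjoint half-streams).
#' @return A data.frame with columns `id`, `criterion`, `expected_loss`, `m`.
#' @export
expected_loss_univariate <- function(bv_base, bv_cand, sigma2_e, q,
                                     criterion = c("KL", "CRPS", "LinLin", "EnergyS", "Std"),
                                     alpha = 0.9, constant = "pi",
                                     yo_cand = NULL) {
  criterion <- match.arg(criterion)
  bv_base <- as.matrix(bv_base); bv_cand <- as.matrix(bv_cand)
  m <- ncol(bv_cand)
  if (ncol(bv_base) != m || length(sigma2_e) != m) {
    stop("draw counts of base, candidates and variances must agree")
  }
  ids <- rownames(bv_cand)
  if (is.null(ids)) ids <- sprintf("C%03d", seq_len(nrow(bv_cand)))
  if (anyDuplicated(ids)) stop("duplicate candidate identifiers")
  if (criterion == "Std") {
    return(data.frame(id = ids, criterion = "Std",
                      expected_loss = rowMeans(bv_cand), m = m,
                      stringsAsFactors = FALSE))
  }
  nb <- nrow(bv_base)
  mu1 <- colMeans(bv_base)
  vg <- colSums(sweep(bv_base, 2, mu1)^2) / (nb - 1)
  sig2 <- vg + sigma2_e
  sd_p <- sqrt(sig2)
  dq <- stats::qnorm(q, lower.tail = FALSE)  # threshold from pressure => z = q
  z <- q
  i_int <- stats::dnorm(dq) / q
  S <- sd_p * i_int
  muS <- mu1 + S
  E <- matrix(muS, nrow(bv_cand), m, byrow = TRUE) - bv_cand
  loss <- switch(criterion,
    KL = {
      num <- sweep(E^2, 2, S^2, `-`)
      sweep(num, 2, 2 * sig2, `/`) - log(z)
    },
    CRPS = {
      U <- sweep(E, 2, sd_p, `/`)
      k <- if (constant == "pi") 1 / pi else 1 / sqrt(pi)
      core <- -(k - 2 * stats::dnorm(U) - U * (2 * stats::pnorm(U) - 1))
      sweep(core, 2, sd_p, `*`)
    },
    LinLin = {
      if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
      (alpha - (E < 0)) * E
    },
    EnergyS = {
      if (is.null(yo_cand)) stop("EnergyS requires predictive phenotype draws `yo_cand`")
      half <- m %/% 2
      D1 <- abs(matrix(muS, nrow(yo_cand), m, byrow = TRUE) - yo_cand)
      t1 <- rowMeans(D1)
      t2 <- rowMeans(abs(yo_cand[, seq_len(half), drop = FALSE] -
                           yo_cand[, half + seq_len(half), drop = FALSE]))
      el <- t1 - 0.5 * t2
      return(data.frame(id = ids, criterion = criterion, expected_loss = el,
                        m = m, stringsAsFactors = FALSE))
    }
  )
  data.frame(id = ids, criterion = criterion, expected_loss = rowMeans(loss),
             m = m, stringsAsFactors = FALSE)
}

#' Posterior expected loss for candidates, multivariate engine
#'
#' Multi-trait analogue of [expected_loss_univariate()]. Per posterior draw,
#' the base-population mean vector and phenotypic covariance
#' `P = cov(BV) + Rcov` are recomputed, per-trait thresholds are re-derived
#' from the pressure `q`, the selected-parent mean is estimated with a
#' seeded truncated-MVN Gibbs sampler, and the orthant probability with a
#' small Monte-Carlo sample. The `-log(z)` term is common to all candidates
#' within a draw, so its Monte-Carlo noise never affects the ranking.
#'
#' @param bv_base n_base x t x m array of base-population breeding-value draws.
#' @param bv_cand n_cand x t x m array of candidate draws (dimnames give ids).
#' @param Rcov_draws t x t x m array of residual-covariance draws.
#' @param q Selection pressure in (0, 1), applied marginally per trait.
#' @param criterion One of `"mKL"`, `"EnergyS"`, `"MALF"`.
#' @param tau MALF asymmetry vector (length t).
#' @param malf_norm `"L2"` or `"L1"`.
#' @param yo_cand Optional n_cand x t x m array of predictive phenotype
#'   draws for `"EnergyS"`.
#' @param z_samples Monte-Carlo sample count for the orthant probability.
#' @param gibbs_sweeps Sweeps of the truncated-MVN Gibbs sampler per draw.
#' @param seed Optional seed for the truncation estimators.
#' @return A data.frame with columns `id`, `criterion`, `expected_loss`, `m`.
#' @export
expected_loss_multivariate <- function(bv_base, bv_cand, Rcov_draws, q,
                                       criterion = c("mKL", "EnergyS", "MALF"),
                                       tau = NULL, malf_norm = "L2",
                                       yo_cand = NULL, z_samples = 2000,
                                       gibbs_sweeps = 400, seed = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(length(dim(bv_base)) == 3, length(dim(bv_cand)) == 3)
  t_tr <- dim(bv_base)[2]
  m <- dim(bv_base)[3]
  nc <- dim(bv_cand)[1]
  if (dim(bv_cand)[3] != m) stop("draw counts of base and candidates must agree")
  ids <- dimnames(bv_cand)[[1]]
  if (is.null(ids)) ids <- sprintf("C%03d", seq_len(nc))
  if (anyDuplicated(ids)) stop("duplicate candidate identifiers")
  if (criterion == "MALF") {
    if (is.null(tau)) stop("MALF requires `tau`")
    if (length(tau) != t_tr) stop("`tau` length must equal the trait count")
  }
  if (criterion == "EnergyS" && is.null(yo_cand)) {
    stop("EnergyS requires predictive phenotype draws `yo_cand`")
  }
  if (!is.null(seed)) set.seed(seed)

  muS_d <- matrix(0, m, t_tr)
  logz_d <- numeric(m)
  S_d <- matrix(0, m, t_tr)
  P_list <- vector("list", m)
  for (j in seq_len(m)) {
    base_j <- matrix(bv_base[, , j], ncol = t_tr)
    mu1 <- colMeans(base_j)
    P <- stats::cov(base_j) + matrix(Rcov_draws[, , j], t_tr, t_tr)
    P <- (P + t(P)) / 2
    yc <- stats::qnorm(q, mu1, sqrt(diag(P)), lower.tail = FALSE)
    X <- .rmvn(z_samples, mu1, P)
    keep <- rep(TRUE, z_samples)
    for (k in seq_len(t_tr)) keep <- keep & (X[, k] >= yc[k])
    zj <- max(mean(keep), 0.5 / z_samples)
    muS <- .tmvn_gibbs_mean(mu1, P, yc, sweeps = gibbs_sweeps)
    muS_d[j, ] <- muS
    S_d[j, ] <- muS - mu1
    logz_d[j] <- log(zj)
    P_list[[j]] <- P
  }

  el <- numeric(nc)
  if (criterion == "mKL") {
    for (j in seq_len(m)) {
      Pinv <- solve(P_list[[j]])
      Ej <- matrix(muS_d[j, ], nc, t_tr, byrow = TRUE) -
        matrix(bv_cand[, , j], ncol = t_tr)
      qf_e <- rowSums((Ej %*% Pinv) * Ej)
      qf_s <- as.numeric(t(S_d[j, ]) %*% Pinv %*% S_d[j, ])
      el <- el + (-logz_d[j] + 0.5 * (qf_e - qf_s))
    }
    el <- el / m
  } else if (criterion == "MALF") {
    for (j in seq_len(m)) {
      Ej <- matrix(muS_d[j, ], nc, t_tr, byrow = TRUE) -
        matrix(bv_cand[, , j], ncol = t_tr)
      if (malf_norm == "L2") {
        ne <- sqrt(rowSums(Ej^2))
        el <- el + (ne + as.numeric(Ej %*% tau)) * ne
      } else {
        el <- el + rowSums(abs(Ej)) + as.numeric(Ej %*% tau)
      }
    }
    el <- el / m
  } else { # EnergyS
    half <- m %/% 2
    t1 <- numeric(nc); t2 <- numeric(nc)
    for (j in seq_len(m)) {
      Dj <- matrix(yo_cand[, , j], ncol = t_tr) -
        matrix(muS_d[j, ], nc, t_tr, byrow = TRUE)
      t1 <- t1 + sqrt(rowSums(Dj^2))
    }
    for (j in seq_len(half)) {
      Dj <- matrix(yo_cand[, , j], ncol = t_tr) -
        matrix(yo_cand[, , half + j], ncol = t_tr)
      t2 <- t2 + sqrt(rowSums(Dj^2))
    }
    el <- t1 / m - 0.5 * t2 / half
  }
  data.frame(id = ids, criterion = criterion, expected_loss = el, m = m,
             stringsAsFactors = FALSE)
}

#' Rank candidates by expected loss
#'
#' Orders an expected-loss table: ascending expected loss (the best
#' candidate has rank 1), or descending score for the `"Std"` criterion
#' (whose score column holds posterior-mean breeding values). Ties are
#' broken by candidate identifier so selections are deterministic.
#'
#' @param table A data.frame from one of the expected-loss engines, holding
#'   a single criterion.
#' @return The table sorted by rank, with a `rank` column added.
#' @export
rank_candidates <- function(table) {
  stopifnot(is.data.frame(table), all(c("id", "criterion", "expected_loss") %in% names(table)))
  if (length(unique(table$criterion)) != 1) stop("rank one criterion at a time")
  if (anyDuplicated(table$id)) stop("duplicate candidate identifiers")
  if (any(!is.finite(table$expected_loss))) stop("non-finite scores cannot be ranked")
  desc <- table$criterion[1] == "Std"
  key <- if (desc) -table$expected_loss else table$expected_loss
  ord <- order(key, table$id)
  out <- table[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the top fraction of ranked candidates
#'
#' @param ranked A ranked table from [rank_candidates()].
#' @param q Selection pressure in (0, 1); `round(q * n)` candidates are kept.
#' @return An object of class `"selection_decision"`: a list with
#'   `criterion`, `pressure`, `n_selected`, `selected` (identifier vector).
#' @examples
#' # 10% of 320 candidates -> 32 selected
#' @export
select_top <- function(ranked, q) {
  stopifnot(is.data.frame(ranked), "rank" %in% names(ranked))
  if (q <= 0 || q >= 1) stop("selection pressure `q` must lie in (0, 1)")
  n_sel <- round(q * nrow(ranked))
  if (n_sel == 0) stop("empty selection: round(q * n) is zero")
  sel <- ranked$id[ranked$rank <= n_sel]
  structure(
    list(criterion = ranked$criterion[1], pressure = q,
         n_selected = n_sel, selected = sel),
    class = "selection_decision"
  )
}

#' @export
print.selection_decision <- function(x, ...) {
  cat(sprintf("Selection (%s, pressure %.2f): %d lines\n",
              x$criterion, x$pressure, x$n_selected))
  cat(" ", paste(utils::head(x$selected, 10), collapse = ", "),
      if (x$n_selected > 10) "..." else "", "\n")
  invisible(x)
}

#' Standard (baseline) selection on posterior-mean breeding values
#'
#' The conventional genomic-selection baseline: rank candidates by their
#' posterior-mean predicted breeding value, descending, and keep the top
#' `round(q * n)`.
#'
#' @param bv_cand n_cand x m matrix of candidate breeding-value draws with
#'   identifiers as row names.
#' @param q Selection pressure in (0, 1).
#' @return A `"selection_decision"`, as from [select_top()].
#' @export
std_selection <- function(bv_cand, q) {
  tbl <- expected_loss_univariate(
    bv_base = bv_cand, bv_cand = bv_cand,
    sigma2_e = rep(1, ncol(bv_cand)), q = q, criterion = "Std"
  )
  select_top(rank_candidates(tbl), q)
}
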