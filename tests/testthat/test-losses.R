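test_that("univariate KL loss matches quadrature and its algebraic forms", {
  tr <- truncated_normal_summary(0, 1, 0)
  # candidate equal to the base population: the bracket vanishes
  expect_equal(kl_univariate(tr, 0), -log(0.5), tolerance = 1e-12)
  # candidate matching the selected parents
  expect_equal(kl_univariate(tr, tr$muS), -log(0.5) - tr$i^2 / 2, tolerance = 1e-12)
  expect_equal(kl_univariate(tr, tr$muS),
               oracle_kl_integral(0, 1, 0, tr$muS), tolerance = 1e-7)

  set.seed(7)
  for (k in 1:25) {
    mu1 <- runif(1, -2, 2); s2 <- runif(1, 0.5, 4)
    yc <- mu1 + runif(1, -1.5, 1.5) * sqrt(s2)
    mu2 <- mu1 + runif(1, -1, 2) * sqrt(s2)
    t1 <- truncated_normal_summary(mu1, s2, yc)
    # closed form vs quadrature of the defining integral
    expect_equal(kl_univariate(t1, mu2), oracle_kl_integral(mu1, s2, yc, mu2),
                 tolerance = 1e-6)
    # selection-theory form: -log z + ((S-R)^2/s2 - i^2)/2
    R <- mu2 - mu1
    alt <- -log(t1$z) + 0.5 * ((t1$S - R)^2 / s2 - t1$i^2)
    expect_equal(kl_univariate(t1, mu2), alt, tolerance = 1e-12)
    # heritability form at mu2 = mu1 + h2*S
    h2 <- runif(1)
    expect_equal(kl_univariate(t1, mu1 + h2 * t1$S),
                 kl_univariate_h2(t1$i, h2, t1$z), tolerance = 1e-12)
  }
})

test_that("heritability-form KL behaves at the boundary and decreases in h2", {
  expect_equal(kl_univariate_h2(0.8, 0, 0.4), -log(0.4))
  expect_equal(kl_univariate_h2(0, 0.7, 0.4), -log(0.4))
  tr <- truncated_normal_summary(0, 1, 0)
  expect_equal(kl_univariate_h2(tr$i, 1, 0.5), kl_univariate(tr, tr$muS),
               tolerance = 1e-12)
  h2 <- seq(0, 1, by = 0.05)
  for (i_int in c(0.5, 1, 2)) {
    vals <- kl_univariate_h2(i_int, h2, 0.3)
    expect_true(all(diff(vals) < 0))
  }
  expect_error(kl_univariate_h2(1, 0.5, 0), "\\(0, 1]")
  expect_error(kl_univariate_h2(1, 1.5, 0.5), "\\[0, 1]")
})

test_that("CRPS loss: printed constant, tail limit, heritability form, calibrated variant", {
  # at e = 0: -(1/pi - 2*phi(0))
  expect_equal(crps_univariate(0, 1), 2 * dnorm(0) - 1 / pi, tolerance = 1e-12)
  # upper tail: value -> e - sigma/pi
  expect_equal(crps_univariate(50, 1), 50 - 1 / pi, tolerance = 1e-10)
  # heritability form vs deviation form on a random grid
  set.seed(8)
  for (k in 1:20) {
    i_int <- runif(1, 0, 2); h2 <- runif(1); s <- runif(1, 0.5, 3)
    expect_equal(crps_h2(i_int, h2, s),
                 crps_univariate(s * i_int * (1 - h2), s), tolerance = 1e-12)
  }
  # h2 = 1 collapses to the e = 0 case
  expect_equal(crps_h2(1.2, 1, 2), crps_univariate(0, 2), tolerance = 1e-14)
  # decreasing in h2 for fixed positive intensity
  vals <- crps_h2(1, seq(0, 1, by = 0.05), 1.5)
  expect_true(all(diff(vals) < 0))
  # calibrated constant recovers the true CRPS of a Gaussian vs a point
  for (e in c(0, 0.7, -1.3)) {
    expect_equal(crps_univariate(e, 1.3, constant = "sqrt_pi"),
                 oracle_crps_integral(0, 1.3^2, e), tolerance = 1e-7)
  }
  # the two constants differ by a candidate-independent offset
  d <- crps_univariate(c(0, 1, 2), 2) - crps_univariate(c(0, 1, 2), 2, constant = "sqrt_pi")
  expect_equal(d, rep(d[1], 3), tolerance = 1e-12)
})

test_that("linear-linear loss is an asymmetric pinball", {
  expect_equal(linlin(2, 0.9), 1.8)
  expect_equal(linlin(-2, 0.9), 0.2)
  expect_equal(linlin(2, 0.5), 1.0)
  expect_equal(linlin(-2, 0.5), 1.0)
  expect_true(all(linlin(seq(-5, 5, by = 0.5), 0.7) >= 0))
  # asymmetry: undershoot penalized harder for alpha > 0.5
  expect_gt(linlin(1.5, 0.8), linlin(-1.5, 0.8))
  expect_error(linlin(1, 1.2), "alpha")
  expect_error(linlin(1, 0), "alpha")
})

test_that("multivariate KL: identical distributions, univariate reduction, e-form equivalence", {
  P <- matrix(c(1, 0.3, 0.3, 1), 2)
  # no truncation and matching distributions: zero loss
  s <- mv_truncation_summary(c(0, 0), P, G = P, yc = c(-Inf, -Inf))
  expect_equal(kl_multivariate(s, c(0, 0)), 0, tolerance = 1e-12)
  expect_equal(kl_multivariate_struct(c(0, 0), P, P, 1), 0, tolerance = 1e-12)

  # t = 1 with G = h2 * P reduces to the heritability form
  tr <- truncated_normal_summary(0, 1, 0)
  for (h2 in c(0, 0.3, 0.6, 1)) {
    expect_equal(
      kl_multivariate_struct(S = tr$S, G = matrix(h2), P = matrix(1), z = 0.5),
      kl_univariate_h2(tr$i, h2, 0.5), tolerance = 1e-12)
  }

  # structural form equals the deviation form under the breeder's equation
  set.seed(3)
  for (k in 1:10) {
    A <- matrix(rnorm(9, sd = 0.4), 3); Pk <- crossprod(A) + diag(3)
    H <- matrix(rnorm(9, sd = 0.2), 3); Gk <- crossprod(H) + 0.3 * diag(3)
    S <- rnorm(3); z <- runif(1, 0.05, 1)
    e <- as.numeric((diag(3) - Gk %*% solve(Pk)) %*% S)
    eform <- -log(z) + 0.5 * (sum(e * solve(Pk, e)) - sum(S * solve(Pk, S)))
    expect_equal(kl_multivariate_struct(S, Gk, Pk, z), eform, tolerance = 1e-10)
  }
  expect_error(kl_multivariate_struct(c(1, 1), diag(2), matrix(0, 2, 2), 0.5),
               "singular")
})

test_that("multivariate KL agrees with Monte-Carlo evaluation of the defining integral", {
  # E_TMVN[log(f_TMVN / f_MVN(mu2, P))] by rejection sampling
  P <- matrix(c(1.5, 0.5, 0.5, 1), 2)
  G <- matrix(c(0.8, 0.1, 0.1, 0.5), 2)
  mu1 <- c(0, 0); yc <- c(0.4, 0.2)
  set.seed(19)
  z_ref <- mvn_orthant_probability(mu1, P, yc, n_samples = 5e5)
  draws <- oracle_tmvn_sample(4e4, mu1, P, yc)
  muS <- colMeans(oracle_tmvn_sample(2e5, mu1, P, yc))
  S <- muS - mu1
  mu2 <- mu1 + as.numeric(G %*% solve(P, S))
  lr <- apply(draws, 1, function(x) {
    oracle_dmvnorm_log(x, mu1, P) - log(z_ref) - oracle_dmvnorm_log(x, mu2, P)
  })
  mc <- mean(lr); mc_se <- sd(lr) / sqrt(length(lr))
  val <- kl_multivariate_struct(S, G, P, z_ref)
  expect_lt(abs(val - mc), 3 * mc_se + 0.01)
})

test_that("energy score: point mass, translation invariance, 1-D closed form, MC convergence", {
  draws <- matrix(rep(c(1, 2), each = 50), 50, 2)
  expect_equal(energy_score(draws, c(1, 2)), 0)

  set.seed(4)
  D <- matrix(rnorm(400), 200, 2)
  shift <- c(3, -5)
  expect_equal(energy_score(D, c(0, 0)),
               energy_score(sweep(D, 2, shift, `+`), shift), tolerance = 1e-12)

  # 1-D: ES -> sigma * (2*phi(0) - 1/sqrt(pi)) for draws from N(muS, sigma^2)
  sigma <- 1.7; m <- 1e5
  set.seed(5)
  y <- rnorm(m, 3, sigma)
  est <- energy_score(y, 3)
  truth <- sigma * (2 * dnorm(0) - 1 / sqrt(pi))
  half <- m %/% 2
  se_est <- sqrt(var(abs(y - 3)) / m +
                 0.25 * var(abs(y[1:half] - y[half + 1:half])) / half)
  expect_lt(abs(est - truth), 3 * se_est)

  # estimator error shrinks roughly as 1/sqrt(m)
  err_at <- function(m, reps = 30) {
    mean(vapply(seq_len(reps), function(r) {
      abs(energy_score(rnorm(m), 0) - (2 * dnorm(0) - 1 / sqrt(pi)))
    }, 0))
  }
  set.seed(6)
  e_small <- err_at(200); e_big <- err_at(20000)
  expect_lt(e_big, e_small / 3)  # expect ~1/10, allow slack

  expect_error(energy_score(matrix(1, 1, 1), 0), "2 predictive draws")
})

test_that("MALF: zero deviation, LinLin correspondence, symmetric L2 case, positivity warning", {
  expect_equal(malf(c(0, 0), c(0.5, 0.5)), 0)
  expect_equal(malf(c(0, 0), c(0.5, 0.5), norm = "L1"), 0)
  # univariate L1 with tau = 2*alpha - 1 is twice the LinLin loss
  for (e in c(2, -2, 0.3, -1.7)) {
    for (alpha in c(0.9, 0.7, 0.5)) {
      expect_equal(malf(e, 2 * alpha - 1, norm = "L1"), 2 * linlin(e, alpha),
                   tolerance = 1e-14)
    }
  }
  expect_equal(malf(c(3, 4), c(0, 0)), 25)
  expect_warning(malf(c(1, 1), c(0.9, 0.9)), "negative")
  expect_warning(malf(c(1, 1), c(1.4, 0), norm = "L1"), "negative")
  expect_error(malf(c(1, 2), 0.5), "same length")
})
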