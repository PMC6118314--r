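test_that("posterior expected loss equals a brute-force loop over draws and candidates", {
  set.seed(51)
  m <- 200; nb <- 25; nc <- 5
  bv_base <- matrix(rnorm(nb * m, 2, 1), nb, m)
  bv_cand <- matrix(rnorm(nc * m, 2.5, 0.8), nc, m)
  rownames(bv_cand) <- sprintf("C%03d", 1:nc)
  s2e <- runif(m, 0.5, 1.5)
  q <- 0.2; alpha <- 0.9

  brute <- function(criterion) {
    sapply(seq_len(nc), function(o) {
      mean(sapply(seq_len(m), function(j) {
        mu1 <- mean(bv_base[, j])
        s2 <- var(bv_base[, j]) + s2e[j]
        yc <- truncation_point_from_pressure(mu1, s2, q)
        tr <- truncated_normal_summary(mu1, s2, yc)
        switch(criterion,
               KL = kl_univariate(tr, bv_cand[o, j]),
               CRPS = crps_univariate(tr$muS - bv_cand[o, j], tr$sigma),
               LinLin = linlin(tr$muS - bv_cand[o, j], alpha))
      }))
    })
  }
  for (criterion in c("KL", "CRPS", "LinLin")) {
    tbl <- expected_loss_univariate(bv_base, bv_cand, s2e, q, criterion, alpha = alpha)
    expect_equal(tbl$expected_loss, brute(criterion), tolerance = 1e-10)
    expect_equal(tbl$m, rep(m, nc))
  }

  # a single draw: expected loss is that draw's loss
  t1 <- expected_loss_univariate(bv_base[, 1, drop = FALSE],
                                 bv_cand[, 1, drop = FALSE], s2e[1], q, "KL")
  mu1 <- mean(bv_base[, 1]); s2 <- var(bv_base[, 1]) + s2e[1]
  tr <- truncated_normal_summary(mu1, s2, truncation_point_from_pressure(mu1, s2, q))
  expect_equal(t1$expected_loss[1], unname(kl_univariate(tr, bv_cand[1, 1])),
               tolerance = 1e-12)
})

test_that("multivariate expected loss is deterministic given a seed and ranks sensibly", {
  set.seed(61)
  m <- 60; nb <- 30; nc <- 6; t_tr <- 2
  bv_base <- array(rnorm(nb * t_tr * m), c(nb, t_tr, m))
  # candidates 1..6 have increasing mean on both traits
  shift <- seq(-1, 1.5, length.out = nc)
  bv_cand <- array(rnorm(nc * t_tr * m, sd = 0.3), c(nc, t_tr, m)) +
    array(rep(shift, t_tr * m), c(nc, t_tr, m))
  dimnames(bv_cand) <- list(sprintf("C%d", 1:nc), NULL, NULL)
  Rd <- array(0, c(t_tr, t_tr, m)); for (j in 1:m) Rd[, , j] <- diag(t_tr)

  a <- expected_loss_multivariate(bv_base, bv_cand, Rd, 0.2, "mKL", seed = 5)
  b <- expected_loss_multivariate(bv_base, bv_cand, Rd, 0.2, "mKL", seed = 5)
  expect_identical(a$expected_loss, b$expected_loss)
  # the best candidate is the one with the highest means
  expect_equal(rank_candidates(a)$id[1], "C6")

  mal <- expected_loss_multivariate(bv_base, bv_cand, Rd, 0.2, "MALF",
                                    tau = c(0.9, 0.9), seed = 5)
  expect_equal(rank_candidates(mal)$id[1], "C6")
  yo <- bv_cand + array(rnorm(length(bv_cand)), dim(bv_cand))
  es <- expected_loss_multivariate(bv_base, bv_cand, Rd, 0.2, "EnergyS",
                                   yo_cand = yo, seed = 5)
  expect_equal(rank_candidates(es)$id[1], "C6")
  expect_error(expected_loss_multivariate(bv_base, bv_cand, Rd, 0.2, "MALF",
                                          tau = 0.9), "length")
})

test_that("ranking is ascending with identifier tie-breaks and shift-invariant", {
  tbl <- data.frame(id = c("a", "b", "c"), criterion = "KL",
                    expected_loss = c(0.2, 0.1, 0.3), m = 10)
  r <- rank_candidates(tbl)
  expect_equal(r$id, c("b", "a", "c"))
  expect_equal(r$rank, 1:3)

  ties <- data.frame(id = c("z", "m", "a"), criterion = "KL",
                     expected_loss = 1, m = 10)
  expect_equal(rank_candidates(ties)$id, c("a", "m", "z"))

  shifted <- tbl; shifted$expected_loss <- tbl$expected_loss + 100
  expect_equal(rank_candidates(shifted)$id, r$id)

  # Std ranks descending
  std <- data.frame(id = c("a", "b"), criterion = "Std",
                    expected_loss = c(1, 2), m = 10)
  expect_equal(rank_candidates(std)$id, c("b", "a"))
  expect_error(rank_candidates(rbind(tbl, tbl)), "duplicate")
})

test_that("top-fraction selection counts candidates correctly", {
  mk <- function(n) data.frame(id = sprintf("L%04d", 1:n), criterion = "KL",
                               expected_loss = seq_len(n) / n, m = 5)
  r320 <- rank_candidates(mk(320))
  expect_equal(select_top(r320, 0.10)$n_selected, 32)
  expect_equal(select_top(rank_candidates(mk(100)), 0.30)$n_selected, 30)
  allr <- rank_candidates(mk(10))
  expect_equal(select_top(allr, 0.96)$n_selected, 10)
  expect_error(select_top(rank_candidates(mk(3)), 0.1), "empty")
  expect_error(select_top(r320, 1.2), "pressure")
})

test_that("standard selection picks highest posterior-mean breeding values", {
  bv <- rbind(lo = rep(1, 50), hi = rep(2, 50))
  sel <- std_selection(bv, 0.5)
  expect_equal(sel$selected, "hi")
  expect_equal(sel$criterion, "Std")

  set.seed(71)
  bv2 <- matrix(rnorm(10 * 100, rep(1:10, 100)), 10, 100)
  rownames(bv2) <- sprintf("C%02d", 1:10)
  s1 <- std_selection(bv2, 0.3)
  s2 <- std_selection(bv2[, sample(100)], 0.3)  # draw order is irrelevant
  expect_equal(s1$selected, s2$selected)
})

test_that("symmetric losses agree with Std under common dispersion; LinLin can reorder", {
  set.seed(81)
  m <- 3000
  base <- matrix(rnorm(20 * m, 0, 1), 20, m)
  s2e <- rep(1, m)
  # location-family candidates: identical noise, shifted means, all below muS
  common <- rnorm(m, 0, 0.2)
  shifts <- c(A = 0.5, B = 1.1, C = 0.2, D = 0.9)
  cand <- t(sapply(shifts, function(s) s + common))
  std_r <- rank_candidates(expected_loss_univariate(base, cand, s2e, 0.1, "Std"))
  kl_r <- rank_candidates(expected_loss_univariate(base, cand, s2e, 0.1, "KL"))
  crps_r <- rank_candidates(expected_loss_univariate(base, cand, s2e, 0.1, "CRPS"))
  expect_equal(kl_r$id, std_r$id)
  expect_equal(crps_r$id, std_r$id)

  # asymmetric loss penalizes predictive dispersion: B (high mean, huge
  # variance) loses to A (slightly lower mean, tight)
  tight <- matrix(rnorm(m, 1.0, 0.1), 1, m)
  wide <- matrix(rnorm(m, 1.05, 2), 1, m)
  duo <- rbind(A = tight[1, ], B = wide[1, ])
  std2 <- rank_candidates(expected_loss_univariate(base, duo, s2e, 0.1, "Std"))
  lin2 <- rank_candidates(expected_loss_univariate(base, duo, s2e, 0.1, "LinLin", alpha = 0.9))
  expect_equal(std2$id[1], "B")
  expect_equal(lin2$id[1], "A")
})

test_that("selection overlap matches brute-force set comparison", {
  set.seed(91)
  for (k in 1:5) {
    A <- sample(sprintf("L%03d", 1:60), 32)
    B <- sample(sprintf("L%03d", 1:60), 32)
    ov <- selection_overlap(A, B)
    expect_equal(ov$n_differing, sum(!(A %in% B)))
    expect_equal(ov$fraction, sum(!(A %in% B)) / 32)
  }
  expect_equal(selection_overlap(letters[1:5], letters[1:5])$fraction, 0)
  expect_equal(selection_overlap(letters[1:5], letters[6:10])$fraction, 1)
  expect_error(selection_overlap(letters[1:3], letters[1:4]), "equal size")
})
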