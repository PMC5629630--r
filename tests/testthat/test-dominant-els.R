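test_that("phenotype tally matches direct counting", {
  # all triple-recessive
  gm <- dominant_matrix_from_counts(c(4, 0, 0, 0, 0, 0, 0, 0))
  tal <- tally_dominant_phenotypes(gm, c("a", "b", "c"))
  expect_equal(unname(tal$Qhat), c(1, rep(0, 7)))
  expect_equal(tal$n_used, 4)

  # one individual in each of the 8 classes
  gm <- dominant_matrix_from_counts(rep(1, 8))
  expect_equal(unname(tally_dominant_phenotypes(gm, c("a", "b", "c"))$Qhat),
               rep(0.125, 8))

  # 100 individuals drawn from exact class probabilities, hand-counted
  set.seed(21)
  q <- c(0.2, 0.1, 0.1, 0.1)
  counts <- as.integer(rmultinom(1, 100, bf_dominant_freqs(q)))
  gm <- dominant_matrix_from_counts(counts)
  tal <- tally_dominant_phenotypes(gm, c("a", "b", "c"))
  expect_equal(unname(tal$Qhat), counts / 100)

  # missing calls exclude only the affected individuals
  calls <- gm$calls
  calls[1:10, 2] <- NA
  gm2 <- genotype_matrix(calls, gm$markers, "dominant")
  expect_equal(tally_dominant_phenotypes(gm2, c("a", "b", "c"))$n_used, 90)

  expect_error(tally_dominant_phenotypes(gm, c("a", "b", "z")), "not found")
})

test_that("forward model agrees with brute-force zygote enumeration", {
  set.seed(31)
  for (i in 1:20) {
    q <- random_q()
    expect_equal(expected_dominant_freqs(q), bf_dominant_freqs(q),
                 tolerance = 1e-12)
  }
  # and sums to 1
  expect_equal(sum(expected_dominant_freqs(random_q())), 1)
})

test_that("complement re-estimation reproduces the hand-derived identity", {
  # exact frequencies of q = (0.2, 0.1, 0.1, 0.1):
  # Q1 = 0.04, Q2 = Q3 = Q4 = 0.05, Q5 = Q6 = Q7 = 0.11, excess Q = 0.06
  Qhat <- expected_dominant_freqs(c(0.2, 0.1, 0.1, 0.1))
  expect_equal(unname(Qhat[1:7]),
               c(0.04, 0.05, 0.05, 0.05, 0.11, 0.11, 0.11))
  cc <- complement_and_combine(Qhat)
  expect_equal(cc$Q, 0.06)
  expect_equal(unname(cc$Qsharp), rep(0.05, 3))
  expect_equal(unname(cc$Qstar), rep(0.05, 3))
})

test_that("degenerate weight rules switch to the defined estimate", {
  # Q#k <= 0 -> use the observed Qhat_k alone
  Qhat <- c(0.04, 0.05, 0.05, 0.05, 0.10, 0.10, 0.10, 0.51)
  cc <- complement_and_combine(Qhat, E = 0.12)   # forces Q# = -0.02
  expect_equal(unname(cc$Qsharp), rep(-0.02, 3))
  expect_equal(unname(cc$Qstar), c(0.05, 0.05, 0.05))
  # Q#k > 0 and Qhat_k = 0 -> use the complement estimate alone
  Qhat <- c(0.04, 0, 0, 0, 0.10, 0.10, 0.10, 0.66)
  cc <- complement_and_combine(Qhat, E = 0.06)   # Q# = 0.04
  expect_equal(unname(cc$Qstar), rep(0.04, 3))
})

test_that("ELS inverts noise-free class frequencies", {
  cfg <- els_config()
  # worked case
  q <- c(0.2, 0.1, 0.1, 0.1)
  est <- els_estimate(expected_dominant_freqs(q), cfg)
  expect_lt(max(abs(as.numeric(est) - q)), 2 * cfg$delta)
  expect_lte(attr(est, "S2"), cfg$tol)
  # free recombination is a fixed point: q1_0 = sqrt(Q1) = 0.125 already optimal
  est <- els_estimate(expected_dominant_freqs(rep(0.125, 4)), cfg)
  expect_lt(max(abs(as.numeric(est) - 0.125)), cfg$delta)
  expect_equal(attr(est, "iterations"), 0)
  # property: recovery over random interior q
  set.seed(41)
  for (i in 1:25) {
    q <- random_q(0.01, 0.35)
    est <- els_estimate(expected_dominant_freqs(q), cfg)
    expect_lt(max(abs(as.numeric(est) - q)), 2 * cfg$delta)
  }
})

test_that("returned criterion is self-consistent and the path non-increasing", {
  set.seed(51)
  for (i in 1:10) {
    Qhat <- as.numeric(rmultinom(1, 150, expected_dominant_freqs(random_q()))) / 150
    est <- els_estimate(Qhat)
    q <- as.numeric(est)
    EQ <- expected_dominant_freqs(q)
    expect_equal(attr(est, "S2"), sum((Qhat[2:7] - EQ[2:7])^2),
                 tolerance = 1e-12)
    expect_true(all(q >= 0 & q <= 0.5))
    trace <- attr(est, "trace")
    expect_true(all(diff(trace$S2) < 0))   # accepted moves strictly improve
  }
})

test_that("line search agrees with the exhaustive grid oracle", {
  cfg <- els_config(tol = 1e-14)
  set.seed(61)
  for (i in 1:10) {
    Qhat <- as.numeric(rmultinom(1, 200, expected_dominant_freqs(random_q()))) / 200
    est <- els_estimate(Qhat, cfg)
    orc <- els_grid_oracle(Qhat, step = cfg$delta, config = cfg)
    expect_lte(abs(est[1] - as.numeric(orc)), cfg$delta + 1e-12)
  }
  # noise-free: oracle grid point sits within half a step of the exact optimum
  q <- c(0.2, 0.1, 0.1, 0.1)
  orc <- els_grid_oracle(expected_dominant_freqs(q), step = 1e-3)
  expect_equal(as.numeric(orc), 0.2, tolerance = 1e-9)
})

test_that("an all-dominant-absent class (Qhat1 = 0) stays in the domain", {
  Qhat <- c(0, 0.1, 0.1, 0.1, 0.2, 0.2, 0.2, 0.1)
  est <- els_estimate(Qhat)
  expect_true(all(is.finite(as.numeric(est))))
  expect_true(all(as.numeric(est) >= 0 & as.numeric(est) <= 0.5))
  orc <- els_grid_oracle(Qhat, step = 1e-3)
  expect_true(is.finite(as.numeric(orc)) && as.numeric(orc) >= 0)
})

test_that("ELS is unbiased at simulation scale", {
  set.seed(71)
  q <- c(0.18, 0.07, 0.15, 0.10)
  P <- expected_dominant_freqs(q)
  est <- t(replicate(100, {
    Qhat <- as.numeric(rmultinom(1, 300, P)) / 300
    as.numeric(els_estimate(Qhat))
  }))
  se <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(colMeans(est) - q) < 3 * se))
})
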