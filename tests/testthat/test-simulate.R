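# The scenario generator: block factors, tau calibration, count draws.

test_that("pre-jitter block values follow the canonical design", {
  fl <- build_true_factors(seed = 1)
  F0 <- fl$F0; L0 <- fl$L0
  expect_equal(F0[50, 1], 2)
  expect_equal(F0[100, 1], 1.7)
  expect_equal(F0[10, 2], 1.8)
  expect_equal(F0[50, 2], 0.9)
  expect_equal(F0[10, 3], 1.7)
  expect_equal(F0[150, 3], 0)
  expect_equal(L0[70, 1], 1.7)
  expect_equal(L0[40, 2], 1.7)
  expect_equal(L0[70, 2], 1)
  expect_equal(L0[10, 3], 1.7)
  expect_equal(L0[30, 3], 0.9)
  expect_equal(L0[10, 1], 0)
})

test_that("jitter has the stated standard deviations", {
  devF <- devL <- NULL
  for (s in 1:20) {
    fl <- build_true_factors(seed = s)
    devF <- c(devF, as.numeric(fl$F - fl$F0))
    devL <- c(devL, as.numeric(fl$L - fl$L0))
  }
  expect_lt(abs(sd(devF) - 0.06), 0.002)
  expect_lt(abs(sd(devL) - 0.05), 0.002)
})

test_that("the literal block-label reading is available behind a flag", {
  fl <- build_true_factors(seed = 1, strict_block_typos = TRUE)
  expect_equal(fl$F0[50, 2], 0)     # overwritten by the literal column-3 line
  expect_equal(fl$L0[70, 2], 0.9)
  expect_equal(fl$L0[30, 3], 0)
})

test_that("tau calibration hits its target and flags unattainable ones", {
  fl <- build_true_factors(seed = 2)
  eta <- fl$F %*% t(fl$L)
  for (target in c(0.2, 0.4)) {
    tau <- calibrate_tau(eta, 1, target)
    phi <- phi_from_lambda(exp(eta), tau)
    p0 <- exp(-exp(eta) / (1 + 0.2 * exp(eta)))
    expect_equal(mean(phi * (1 - p0)), target, tolerance = 1e-6)
  }
  # at lambda = 1 the logit link pins phi at 0.5 whatever tau, so a total
  # zero probability of 0.20 is unattainable
  eta1 <- matrix(0, 10, 10)
  expect_error(calibrate_tau(eta1, 1, 0.2, zero_mode = "total"), "unattainable")
  # a larger target yields a larger mean phi on the same rates
  t20 <- calibrate_tau(eta, 1, 0.2)
  t40 <- calibrate_tau(eta, 1, 0.4)
  expect_gt(mean(phi_from_lambda(exp(eta), t40)),
            mean(phi_from_lambda(exp(eta), t20)))
})

test_that("generated zero fraction matches the generator's expectation", {
  for (sc in c(1, 2, 4, 5, 6)) {
    sim <- simulate_scenario(scenario_spec(sc, 0.2, seed = 30 + sc))
    expect_lt(abs(mean(sim$Y == 0) - sim$expected_zero_fraction), 0.03)
  }
})

test_that("generation is bit-identical under a fixed spec", {
  s1 <- simulate_scenario(scenario_spec(1, 0.2, n = 50, m = 25, seed = 9))
  s2 <- simulate_scenario(scenario_spec(1, 0.2, n = 50, m = 25, seed = 9))
  expect_identical(s1$Y, s2$Y)
  expect_identical(s1$F_true, s2$F_true)
  s3 <- simulate_scenario(scenario_spec(1, 0.2, n = 50, m = 25, seed = 10))
  expect_false(identical(s1$Y, s3$Y))
})

test_that("scenario 4 holds the structural-zero probability fixed per taxon", {
  sim <- simulate_scenario(scenario_spec(4, 0.2, n = 40, m = 15, seed = 3))
  expect_true(all(apply(sim$Phi_true, 2, function(x) diff(range(x))) == 0))
  expect_lt(abs(mean(sim$Phi_true[1, ]) - 0.2), 0.08)
})

test_that("scenario 5 counts are conditionally Poisson", {
  sp <- scenario_spec(5, 0.2, seed = 4)
  sim <- simulate_scenario(sp)
  # within a narrow high-rate band structural zeros are rare and the rate is
  # ~ constant, so the variance/mean ratio should be ~ 1
  lam <- exp(sim$logLambda_true)
  idx <- which(abs(lam - exp(4.3)) / exp(4.3) < 0.05)
  y <- sim$Y[idx][sim$Y[idx] > 0]
  expect_lt(abs(var(y) / mean(y) - 1), 0.35)
})

test_that("GP draws in scenario 1 show the GP mean-variance relation", {
  sp <- scenario_spec(1, 0.2, seed = 5)
  sim <- simulate_scenario(sp)
  lam <- exp(sim$logLambda_true)
  idx <- which(abs(lam - exp(4.3)) / exp(4.3) < 0.05 & sim$Phi_true < 0.05)
  y <- sim$Y[idx][sim$Y[idx] > 0]  # structural zeros are ~ absent here
  mu <- mean(y)
  expect_lt(abs(var(y) / (mu * (1 + 0.2 * mu)^2) - 1), 0.3)
})
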