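# Generalized Poisson and ZIGP probability computations.

test_that("GP log-pmf matches closed forms and direct evaluation", {
  # y = 0 collapses the pmf to exp(-mu/(1+alpha*mu))
  expect_equal(gp_logpmf(0, mu = 2, alpha = 0.2), -2 / 1.4)
  # alpha = 0 reduces to the Poisson pmf
  expect_equal(gp_logpmf(3, mu = 2, alpha = 0), dpois(3, 2, log = TRUE))
  # term-by-term evaluation of the pmf as an independent oracle
  direct <- function(y, mu, a) {
    -lgamma(y + 1) + y * log(mu / (1 + a * mu)) +
      (y - 1) * log(1 + a * y) - mu * (1 + a * y) / (1 + a * mu)
  }
  for (y in c(1, 5, 17)) {
    expect_equal(gp_logpmf(y, mu = 3, alpha = 0.2), direct(y, 3, 0.2))
  }
  expect_error(dgpois(-1, 2, 0.2), "non-negative")
  expect_error(dgpois(1, -2, 0.2), "positive")
  expect_error(dgpois(1, 2, -0.1), "non-negative")
})

test_that("GP pmf normalizes and matches the Poisson limit on a grid", {
  for (mu in c(0.1, 1, 5, 20)) {
    for (a in c(0, 0.1, 0.3)) {
      expect_gte(sum(dgpois(0:2000, mu, a)), 1 - 1e-8)
    }
    expect_lt(max(abs(dgpois(0:50, mu, 0, log = TRUE) -
                        dpois(0:50, mu, log = TRUE))), 1e-10)
  }
})

test_that("ZIGP log-pmf mixes the point mass and the GP mass stably", {
  # degenerate mixture equals the GP pmf
  expect_equal(zigp_logpmf(3, phi = 0, mu = 2, alpha = 0.2),
               gp_logpmf(3, 2, 0.2))
  # Poisson limit closed form at a positive count
  expect_equal(zigp_logpmf(1, phi = 0.5, mu = 1, alpha = 0), log(0.5 * exp(-1)))
  # direct mixture evaluation at zero
  expect_equal(zigp_logpmf(0, phi = 0.3, mu = 2, alpha = 0.2),
               log(0.3 + 0.7 * exp(-2 / 1.4)))
  expect_error(dzigpois(0, 2, 0.2, phi = 1), "\\[0, 1\\)")
})

test_that("zero links map rates to structural-zero probabilities", {
  # logit link pins phi = 0.5 at lambda = 1 for any tau
  for (tau in c(-3, 0, 0.5, 7)) {
    expect_equal(phi_from_lambda(1, tau), 0.5)
  }
  expect_equal(phi_from_lambda(exp(1), tau = 2), 1 / (1 + exp(2)))
  expect_equal(phi_from_lambda(1, 1, "loglog"), exp(-1))
  expect_equal(phi_from_lambda(1, 1, "cloglog"), 1 - exp(-1))
  # negative relationship between phi and lambda when tau > 0
  lam <- exp(seq(-2, 3, length.out = 40))
  expect_true(all(diff(phi_from_lambda(lam, tau = 0.7)) < 0))
})

test_that("GP sampling matches the pmf's moments and zero mass", {
  set.seed(11)
  x <- rgpois(1e5, mu = 4, alpha = 0)
  expect_lt(abs(mean(x) - 4), 3 * sqrt(4 / 1e5))
  y <- rgpois(1e5, mu = 2, alpha = 0.2)
  p0 <- exp(-2 / 1.4)
  expect_lt(abs(mean(y == 0) - p0), 4 * sqrt(p0 * (1 - p0) / 1e5))
  # mean and variance against GP theory: var = mu (1 + alpha mu)^2
  expect_lt(abs(mean(y) - 2), 4 * sqrt(2 * 1.4^2 / 1e5))
  expect_lt(abs(var(y) - 2 * 1.4^2) / (2 * 1.4^2), 0.05)
  # determinism under a fixed seed
  expect_identical(gp_sample(rep(3, 50), 0.2, seed = 99),
                   gp_sample(rep(3, 50), 0.2, seed = 99))
})

test_that("total zero probability combines structural and sampling zeros", {
  expect_equal(zigp_total_zero_prob(0, mu = 2, alpha = 0), exp(-2))
  expect_equal(zigp_total_zero_prob(0.3, 2, 0.2), 0.3 + 0.7 * exp(-10 / 7))
  expect_gt(zigp_total_zero_prob(1 - 1e-10, 5, 0.2), 1 - 1e-9)
  # the additive (unweighted) variant drops the 1 - phi factor
  expect_equal(zigp_total_zero_prob(0.3, 2, 0.2, mixture_weighted = FALSE),
               0.3 + exp(-10 / 7))
})
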