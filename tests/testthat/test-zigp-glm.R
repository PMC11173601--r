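# ZIGP regression: likelihood, EM fitting, stacked fits with shared (tau, alpha).

test_that("regression log-likelihood matches a per-row brute-force sum", {
  set.seed(3)
  n <- 20
  X <- cbind(1, rnorm(n))
  beta <- c(0.5, 0.3)
  off <- rnorm(n, 0, 0.3)
  y <- rpois(n, exp(drop(X %*% beta) + off))
  tau <- 0.8; alpha <- 0.15
  eta <- drop(X %*% beta)
  brute <- sum(vapply(seq_len(n), function(i) {
    zigp_logpmf(y[i], phi = 1 / (1 + exp(tau * eta[i])),
                mu = exp(eta[i] + off[i]), alpha = alpha)
  }, numeric(1)))
  expect_equal(zigp_loglik(y, X, beta, tau, alpha, offset_log = off), brute)
  # homogeneous all-zero closed form: lambda = 1, tau = 0 gives phi = 0.5
  y0 <- rep(0, n); X0 <- matrix(1, n, 1)
  expect_equal(zigp_loglik(y0, X0, beta = 0, tau = 0, alpha = 0.1),
               n * log(0.5 + 0.5 * exp(-1 / 1.1)))
  # single observation, Poisson limit
  expect_equal(zigp_loglik(2, matrix(1), beta = 0, tau = 0, alpha = 0),
               log(0.5 * exp(-1) / 2))
})

test_that("EM recovers generating parameters on model-simulated data", {
  d <- sim_regression(n = 2000, seed = 21)
  fit <- zigp_em(d$y, d$X)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$beta - d$beta)), 0.1)
  expect_lt(abs(fit$tau - d$tau), 0.3)
  expect_lt(abs(fit$alpha - d$alpha), 0.08)
  # posterior weights vanish at positive counts
  expect_true(all(fit$z[d$y > 0] == 0))
})

test_that("EM log-likelihood trace is non-decreasing", {
  for (seed in 1:3) {
    d <- sim_regression(n = 300, seed = seed)
    fit <- zigp_em(d$y, d$X, tau = 0.3, alpha = 0.4)
    expect_true(all(diff(fit$loglik_trace) >=
                      -1e-8 * (abs(fit$loglik) + 1)))
  }
})

test_that("with no zeros and degenerate mixture the fit matches a Poisson GLM", {
  set.seed(8)
  n <- 400
  X <- cbind(1, runif(n, 0.5, 1.5))
  beta <- c(1.5, 0.8)          # lambda >= e, so phi under tau = 30 is ~ 0
  y <- rpois(n, exp(drop(X %*% beta)))
  y[y == 0] <- 1               # ensure a zero-free response
  fit <- zigp_em(y, X, tau = 30, alpha = 0, fix_params = TRUE)
  ref <- glm(y ~ X - 1, family = poisson())
  expect_lt(max(abs(fit$beta - coef(ref))), 1e-4)
})

test_that("profile gradient in (tau, alpha) is ~ zero at convergence", {
  d <- sim_regression(n = 800, seed = 5)
  fit <- zigp_em(d$y, d$X)
  h <- 1e-5
  ll <- function(tt, aa) zigp_loglik(d$y, d$X, fit$beta, tt, aa)
  gt <- (ll(fit$tau + h, fit$alpha) - ll(fit$tau - h, fit$alpha)) / (2 * h)
  expect_lt(abs(gt) / (abs(fit$loglik) + 1), 1e-3)
  if (fit$alpha > 1e-4) {
    ga <- (ll(fit$tau, fit$alpha + h) - ll(fit$tau, fit$alpha - h)) / (2 * h)
    expect_lt(abs(ga) / (abs(fit$loglik) + 1), 1e-3)
  }
})

test_that("stacked fit degenerates correctly and beats naive averaging", {
  d <- sim_regression(n = 120, seed = 9)
  pb <- list(y = d$y, X = d$X)
  # m = 1: same answer as a free EM fit, up to tolerance
  single <- zigp_em(d$y, d$X)
  stacked <- zigp_stacked_fit(list(pb))
  expect_lt(max(abs(stacked$coefficients[[1]] - single$beta)), 0.02)
  expect_lt(abs(stacked$tau - single$tau), 0.05)
  expect_lt(abs(stacked$alpha - single$alpha), 0.02)
  # two identical blocks: identical coefficients, same (tau, alpha)
  two <- zigp_stacked_fit(list(pb, pb))
  expect_equal(two$coefficients[[1]], two$coefficients[[2]], tolerance = 1e-6)
  expect_lt(abs(two$tau - single$tau), 0.05)
  # shared-parameter optimum dominates fitting blocks freely then averaging
  d2 <- sim_regression(n = 50, seed = 10, beta = c(0.8, -0.4))
  pbs <- lapply(1:5, function(k) {
    set.seed(100 + k)
    lam <- exp(drop(d2$X %*% d2$beta))
    phi <- 1 / (1 + lam)
    list(y = ifelse(runif(50) < phi, 0, rgpois(50, lam, 0.2)), X = d2$X)
  })
  st <- zigp_stacked_fit(pbs)
  free <- lapply(pbs, function(p) zigp_em(p$y, p$X))
  tau_bar <- mean(vapply(free, `[[`, numeric(1), "tau"))
  alpha_bar <- max(0, mean(vapply(free, `[[`, numeric(1), "alpha")))
  ll_avg <- sum(vapply(seq_along(pbs), function(j) {
    zigp_loglik(pbs[[j]]$y, pbs[[j]]$X, free[[j]]$beta, tau_bar, alpha_bar)
  }, numeric(1)))
  expect_gte(st$loglik, ll_avg - 1e-6 * abs(ll_avg))
})

test_that("degenerate and ill-posed problems are flagged", {
  X <- cbind(1, rep(1, 20))   # rank deficient
  expect_error(zigp_em(rpois(20, 2), X), "rank deficient")
  expect_warning(zigp_em(rep(0, 20), matrix(1, 20, 1)), "all included responses")
})
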