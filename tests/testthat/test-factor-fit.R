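# The alternating maximum-likelihood factor algorithm.

test_that("relative library size follows the median-normalized row sums", {
  Y <- matrix(1, 3, 4) * c(10, 20, 30) / 4
  Y <- rbind(rep(2.5, 4), rep(5, 4), rep(7.5, 4))
  expect_equal(relative_library_size(Y), c(0.5, 1, 1.5))
  expect_equal(relative_library_size(matrix(3, 5, 4)), rep(1, 5))
  Y4 <- rbind(rep(1, 4), rep(2, 4), rep(2, 4), rep(25, 4))
  expect_equal(relative_library_size(Y4), c(0.5, 1, 1, 12.5))
  Yz <- rbind(a = c(0, 0), b = c(1, 2))
  expect_error(relative_library_size(Yz), "a")
})

test_that("SVD initialization gives the best rank-K approximation", {
  set.seed(4)
  Y <- matrix(rpois(200, 10), 20, 10)
  T <- relative_library_size(Y)
  Yt <- sweep(log(Y + 1), 1, log(T), "-")
  s <- svd(Yt)
  for (K in c(1, 3)) {
    ini <- svd_init(Y, K)
    resid <- frobenius_loss(ini$F %*% t(ini$L), Yt)
    expect_equal(resid, sqrt(sum(s$d[-seq_len(K)]^2)))
  }
  # rank-1 toy: F0 L0' is sigma1 u1 v1'
  A <- outer(c(1, 2, 3), c(2, 1, 2))
  Ytoy <- round(exp(log(A)))  # positive integer, exactly rank 1 in logs? use A
  ini <- svd_init(A, 1, T = rep(1, 3))
  st <- svd(log(A + 1))
  expect_equal(ini$F %*% t(ini$L), st$d[1] * st$u[, 1] %*% t(st$v[, 1]))
  expect_error(svd_init(A, 5), "K")
})

test_that("alternating fit: monotone likelihood and SVD-step invariance", {
  sim <- small_sim(seed = 2)
  fit <- gzigpfa(sim$Y, 3, T = sim$spec$T)
  tr <- fit$loglik_trace$loglik
  expect_true(all(diff(tr) >= -1e-6 * (abs(tr[-1]) + 1)))
  # the re-identified factors reproduce the product and are orthogonal
  P <- fit$F %*% t(fit$L)
  sv <- svd(P, nu = 3, nv = 3)
  expect_lt(max(abs(sweep(sv$u, 2, sv$d[1:3], "*") %*% t(sv$v) - P)), 1e-8)
  expect_equal(crossprod(fit$L), diag(3), tolerance = 1e-8)
  off <- crossprod(fit$F)
  expect_lt(max(abs(off[upper.tri(off)])) / max(diag(off)), 1e-8)
})

test_that("fitted model recovers the generating log-rate structure", {
  sim <- small_sim(seed = 3, n = 100, m = 50)
  fit <- gzigpfa(sim$Y, 3, T = sim$spec$T)
  loss_fit <- frobenius_loss(fit$F %*% t(fit$L), sim$logLambda_true)
  loss_pca <- frobenius_loss(log_pca(sim$Y, 3)$logLambda_hat, sim$logLambda_true)
  expect_lt(loss_fit, loss_pca)
  # global shape and dispersion are close to the generating values
  expect_lt(abs(fit$tau - sim$tau_used), 0.3)
  expect_lt(abs(fit$alpha - sim$spec$alpha), 0.1)
})

test_that("saturated rank dominates the true parameters on a tiny GP matrix", {
  set.seed(6)
  eta <- outer(seq(0.5, 1.3, length.out = 5), seq(0.6, 1.4, length.out = 4))
  Y <- matrix(rgpois(20, exp(eta), 0.1), 5, 4)
  Y[1, 1] <- max(Y[1, 1], 1)  # keep every row/column informative
  fit <- gzigpfa(Y, K = 4, T = rep(1, 5))
  logT <- rep(0, 5)
  ll_true <- gzigpfa:::.gz_obs_loglik(Y, eta, logT, fit$tau, fit$alpha,
                                      matrix(1, 5, 4))
  expect_gte(fit$loglik, ll_true - 1e-6 * abs(ll_true))
})

test_that("masked entries are excluded from fitting and likelihood", {
  sim <- small_sim(seed = 5)
  mask <- matrix(TRUE, nrow(sim$Y), ncol(sim$Y))
  set.seed(5); mask[sample(length(mask), 150)] <- FALSE
  fit <- gzigpfa(sim$Y, 2, T = sim$spec$T, mask = mask)
  # total likelihood splits into train + held-out parts
  ll_all <- gzigpfa_loglik(fit, sim$Y)
  ll_train <- gzigpfa_loglik(fit, sim$Y, mask)
  ll_test <- gzigpfa_loglik(fit, sim$Y, !mask)
  expect_equal(ll_all, ll_train + ll_test)
  expect_equal(ll_train, fit$loglik, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  expect_error(gzigpfa(matrix(0, 5, 4), 2), "all zero")
  expect_error(gzigpfa(matrix(rpois(20, 3), 5, 4), 6), "K")
})

test_that("predicted zero-probability matrix matches a per-entry loop", {
  sim <- small_sim(seed = 8)
  fit <- gzigpfa(sim$Y, 2, T = sim$spec$T)
  P <- predicted_zero_matrix(fit)
  eta <- fit$F %*% t(fit$L)
  for (idx in list(c(1, 1), c(7, 3), c(40, 20))) {
    i <- idx[1]; j <- idx[2]
    lam <- exp(eta[i, j])
    phi <- 1 / (1 + lam^fit$tau)
    mu <- fit$T[i] * lam
    expect_equal(P[i, j], phi + (1 - phi) * exp(-mu / (1 + fit$alpha * mu)))
  }
  expect_true(all(P > 0 & P < 1))
  # constant-rate sanity: lambda = 1 everywhere gives Phi = 0.5 + GP zero mass
  fit1 <- fit; fit1$F <- matrix(0, nrow(fit$F), 2)
  P1 <- predicted_zero_matrix(fit1)
  expect_equal(unique(round(as.numeric(P1[1, ]), 12)),
               round(0.5 + 0.5 * exp(-fit$T[1] / (1 + fit$alpha * fit$T[1])), 12))
})
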