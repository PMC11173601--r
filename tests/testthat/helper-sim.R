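# Small simulated fixtures shared across tests.

# a modest scenario-1 dataset (scaled-down canonical design)
small_sim <- function(seed = 1, n = 60, m = 30, scenario = 1, zero_target = 0.2) {
  simulate_scenario(scenario_spec(scenario, zero_target, n = n, m = m, seed = seed))
}

# a ZIGP regression problem drawn from the model itself
sim_regression <- function(n = 500, beta = c(1.2, 0.7), tau = 1, alpha = 0.2,
                           seed = 1) {
  set.seed(seed)
  X <- cbind(1, rnorm(n))
  lambda <- exp(drop(X %*% beta))
  phi <- 1 / (1 + lambda^tau)
  y <- ifelse(runif(n) < phi, 0, rgpois(n, lambda, alpha))
  list(y = y, X = X, beta = beta, tau = tau, alpha = alpha)
}
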