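# ZIGP regression by EM.
#
# Model for one regression block: y_i ~ ZIGP(T_i * lambda_i, alpha, phi_i)
# with log(lambda_i) = x_i' beta and logit(phi_i) = -tau * log(lambda_i).
# Because phi depends on beta and tau, the M-step does not separate into a
# logistic part and a GP part; the expected complete-data log-likelihood is
# maximized jointly by L-BFGS-B with analytic gradients.

#' Control parameters for ZIGP fitting
#'
#' @param em_tol relative observed-data log-likelihood tolerance of the EM
#'   loop.
#' @param em_maxit maximum EM iterations per regression fit.
#' @param outer_tol relative tolerance of the stacked block-coordinate loop
#'   alternating coefficient updates with the shared `(tau, alpha)` update.
#' @param outer_maxit maximum stacked alternations.
#' @param fit_tol relative total-log-likelihood tolerance of the alternating
#'   factor algorithm.
#' @param fit_maxit maximum outer iterations of the factor algorithm.
#' @param alpha_max upper box constraint for the dispersion.
#' @param beta_bound box constraint on regression coefficients; keeps the
#'   linear predictor finite for degenerate (all-zero) responses.
#' @return a named list of control values.
#' @export
zigp_control <- function(em_tol = 1e-6, em_maxit = 200, outer_tol = 1e-5,
                         outer_maxit = 25, fit_tol = 1e-4, fit_maxit = 30,
                         alpha_max = 5, beta_bound = 30) {
  list(em_tol = em_tol, em_maxit = em_maxit, outer_tol = outer_tol,
       outer_maxit = outer_maxit, fit_tol = fit_tol, fit_maxit = fit_maxit,
       alpha_max = alpha_max, beta_bound = beta_bound)
}

# optim() wrapper: qg(par) must return list(value, grad) of the objective to
# MINIMIZE; caches the last evaluation so each L-BFGS-B step costs one pass.
.optim_qg <- function(par, qg, lower, upper, maxit = 100) {
  cache <- new.env(parent = emptyenv())
  fn <- function(p) {
    v <- qg(p)
    cache$par <- p
    cache$grad <- v$grad
    v$value
  }
  gr <- function(p) {
    if (!is.null(cache$par) && identical(p, cache$par)) return(cache$grad)
    qg(p)$grad
  }
  stats::optim(par, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = maxit))
}

.as_problem <- function(y, X, offset_log = NULL, mask = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (is.null(offset_log)) offset_log <- rep(0, n)
  offset_log <- rep_len(offset_log, n)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (any(y < 0) || any(y != floor(y))) stop("responses must be non-negative integers")
  if (qr(X[mask, , drop = FALSE])$rank < ncol(X)) {
    stop("design matrix is rank deficient on included rows")
  }
  list(y = as.numeric(y), X = X, offset_log = as.numeric(offset_log),
       mask = as.logical(mask))
}

#' ZIGP regression log-likelihood
#'
#' Observed-data log-likelihood of a ZIGP regression with log link and
#' offset: `lambda = exp(X beta)`, GP mean `exp(offset_log) * lambda`,
#' `logit(phi) = -tau * log(lambda)`.
#'
#' @param y non-negative integer response vector.
#' @param X design matrix (`length(y)` rows).
#' @param beta coefficient vector.
#' @param tau,alpha shared ZIGP shape and dispersion parameters.
#' @param offset_log log relative library sizes (default 0).
#' @param mask optional logical inclusion vector (for held-out entries).
#' @return the summed log-likelihood over included rows.
#' @export
zigp_loglik <- function(y, X, beta, tau, alpha, offset_log = NULL, mask = NULL) {
  pb <- .as_problem(y, X, offset_log, mask)
  eta <- drop(pb$X %*% beta)
  ll <- .gz_obs_loglik(cbind(pb$y), cbind(eta), pb$offset_log, tau, alpha,
                       cbind(as.numeric(pb$mask)))
  if (!is.finite(ll)) {
    bad <- which(!is.finite(.gz_gp_logpmf(pb$y, exp(eta + pb$offset_log), alpha)))
    stop("non-finite ZIGP log-likelihood at rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  ll
}

# E-step posterior structural-zero weights for a vector problem
.estep_vec <- function(y, eta, offset_log, tau, alpha) {
  drop(.gz_estep(cbind(y), cbind(eta), offset_log, tau, alpha))
}

.default_beta_init <- function(y, X, offset_log, mask) {
  w <- as.numeric(mask)
  z <- log(y + 1) - offset_log
  fit <- stats::lm.wfit(X, z, w)
  b <- fit$coefficients
  b[!is.finite(b)] <- 0
  b
}

#' Fit a ZIGP regression by the EM algorithm
#'
#' The latent indicator of each observed zero being structural is integrated
#' by EM: the E-step computes `z_i = phi_i / (phi_i + (1-phi_i) p(0))` for
#' zero entries, and the M-step maximizes the expected complete-data
#' log-likelihood jointly over `beta` (and over `tau, alpha` unless
#' `fix_params`) by L-BFGS-B with analytic gradients, with
#' `alpha` box-constrained to `[0, alpha_max]`.  The observed-data
#' log-likelihood is non-decreasing across iterations.
#'
#' @inheritParams zigp_loglik
#' @param init optional initial coefficient vector; defaults to a
#'   least-squares fit of `log(y + 1) - offset_log` on `X`.
#' @param tau,alpha initial (or fixed) shape and dispersion.
#' @param fix_params keep `(tau, alpha)` fixed at their supplied values?
#' @param control see [zigp_control()].
#' @return a list with elements `beta`, `tau`, `alpha`, `loglik`,
#'   `loglik_trace`, `n_em_iters`, `converged`, `degenerate`, and the
#'   posterior zero weights `z`.
#' @export
zigp_em <- function(y, X, offset_log = NULL, mask = NULL, init = NULL,
                    tau = 1, alpha = 0.05, fix_params = FALSE,
                    control = zigp_control()) {
  pb <- .as_problem(y, X, offset_log, mask)
  K <- ncol(pb$X)
  beta <- if (is.null(init)) {
    .default_beta_init(pb$y, pb$X, pb$offset_log, pb$mask)
  } else {
    stopifnot(length(init) == K)
    as.numeric(init)
  }
  bb <- control$beta_bound
  beta <- pmin(pmax(beta, -bb), bb)
  degenerate <- all(pb$y[pb$mask] == 0)
  if (degenerate) warning("all included responses are zero; lambda is unidentifiable downward")

  Ym <- cbind(pb$y); Wm <- cbind(as.numeric(pb$mask)); lt <- pb$offset_log
  obs_ll <- function(beta, tau, alpha) {
    .gz_obs_loglik(Ym, cbind(drop(pb$X %*% beta)), lt, tau, alpha, Wm)
  }
  ll <- obs_ll(beta, tau, alpha)
  trace <- ll
  converged <- FALSE
  iter <- 0
  while (iter < control$em_maxit) {
    iter <- iter + 1
    eta <- drop(pb$X %*% beta)
    Z <- .gz_estep(Ym, cbind(eta), lt, tau, alpha)
    if (fix_params) {
      qg <- function(p) {
        g <- .gz_q_grad(Ym, Z, cbind(drop(pb$X %*% p)), lt, tau, alpha, Wm)
        list(value = -g$Q, grad = -drop(crossprod(pb$X, g$Geta)))
      }
      opt <- .optim_qg(beta, qg, lower = rep(-bb, K), upper = rep(bb, K))
      beta <- opt$par
    } else {
      qg <- function(p) {
        b <- p[seq_len(K)]; tt <- p[K + 1]; aa <- p[K + 2]
        g <- .gz_q_grad(Ym, Z, cbind(drop(pb$X %*% b)), lt, tt, aa, Wm)
        list(value = -g$Q,
             grad = -c(drop(crossprod(pb$X, g$Geta)), g$gtau, g$galpha))
      }
      opt <- .optim_qg(c(beta, tau, alpha), qg,
                       lower = c(rep(-bb, K), -50, 0),
                       upper = c(rep(bb, K), 50, control$alpha_max))
      beta <- opt$par[seq_len(K)]
      tau <- opt$par[K + 1]
      alpha <- opt$par[K + 2]
    }
    ll_new <- obs_ll(beta, tau, alpha)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) <= control$em_tol * (abs(ll) + 1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  if (!converged) warning("EM did not converge within ", control$em_maxit, " iterations")
  eta <- drop(pb$X %*% beta)
  list(beta = beta, tau = tau, alpha = alpha, loglik = ll,
       loglik_trace = trace, n_em_iters = iter, converged = converged,
       degenerate = degenerate,
       z = .estep_vec(pb$y, eta, lt, tau, alpha))
}

#' Fit several ZIGP regressions with shared (tau, alpha)
#'
#' Block-coordinate scheme for a list of regression problems that share the
#' shape and dispersion parameters: (a) given `(tau, alpha)`, each block is
#' fitted by [zigp_em()] with `fix_params = TRUE`; (b) given all coefficient
#' vectors, the summed observed-data log-likelihood is maximized over
#' `(tau, alpha)` by 2-D bounded optimization with analytic gradients.  The
#' two phases alternate until the total log-likelihood stabilizes.
#'
#' @param problems list of problems, each a list with elements `y`, `X` and
#'   optionally `offset_log`, `mask`.
#' @param inits optional list of initial coefficient vectors.
#' @param tau,alpha initial shared parameters.
#' @param control see [zigp_control()].
#' @return list with `coefficients` (list of per-block vectors), `tau`,
#'   `alpha`, `loglik` (total), `n_outer`, `converged`, `fits` (per-block EM
#'   results from the final pass).
#' @export
zigp_stacked_fit <- function(problems, inits = NULL, tau = 1, alpha = 0.05,
                             control = zigp_control()) {
  pbs <- lapply(problems, function(p) {
    .as_problem(p$y, p$X, p$offset_log, p$mask)
  })
  m <- length(pbs)
  betas <- vector("list", m)
  for (j in seq_len(m)) {
    betas[[j]] <- if (!is.null(inits)) as.numeric(inits[[j]]) else
      .default_beta_init(pbs[[j]]$y, pbs[[j]]$X, pbs[[j]]$offset_log, pbs[[j]]$mask)
  }
  total_ll <- function(tau, alpha) {
    sum(vapply(seq_len(m), function(j) {
      p <- pbs[[j]]
      .gz_obs_loglik(cbind(p$y), cbind(drop(p$X %*% betas[[j]])),
                     p$offset_log, tau, alpha, cbind(as.numeric(p$mask)))
    }, numeric(1)))
  }
  ll <- total_ll(tau, alpha)
  converged <- FALSE
  fits <- NULL
  it <- 0
  while (it < control$outer_maxit) {
    it <- it + 1
    fits <- vector("list", m)
    for (j in seq_len(m)) {
      p <- pbs[[j]]
      fits[[j]] <- tryCatch(
        zigp_em(p$y, p$X, p$offset_log, p$mask, init = betas[[j]],
                tau = tau, alpha = alpha, fix_params = TRUE, control = control),
        error = function(e) stop("block ", j, ": ", conditionMessage(e))
      )
      betas[[j]] <- fits[[j]]$beta
    }
    qg <- function(p) {
      acc <- c(0, 0, 0)
      for (j in seq_len(m)) {
        pp <- pbs[[j]]
        v <- .gz_obs_ta_grad(cbind(pp$y), cbind(drop(pp$X %*% betas[[j]])),
                             pp$offset_log, p[1], p[2],
                             cbind(as.numeric(pp$mask)))
        acc <- acc + v
      }
      list(value = -acc[1], grad = -acc[2:3])
    }
    opt <- .optim_qg(c(tau, alpha), qg, lower = c(-50, 0),
                     upper = c(50, control$alpha_max))
    tau <- opt$par[1]; alpha <- opt$par[2]
    ll_new <- total_ll(tau, alpha)
    if (abs(ll_new - ll) <= control$outer_tol * (abs(ll) + 1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  list(coefficients = betas, tau = tau, alpha = alpha, loglik = ll,
       n_outer = it, converged = converged, fits = fits)
}
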