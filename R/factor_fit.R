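# The alternating maximum-likelihood algorithm for the ZIGP factor model:
#   Step 1  update the loading matrix L (and tau, alpha) by ZIGP regressions
#           of the m columns of Y on the current scores F,
#   Step 2  update the score matrix F (and tau, alpha) by ZIGP regressions of
#           the n rows of Y on the new loadings L,
#   Step 3  re-identify (F, L) by an SVD of F L' (likelihood-invariant),
# repeated until the total likelihood stabilizes.
#
# The per-step update is the same block-coordinate scheme as
# zigp_stacked_fit(): the per-block EMs share (tau, alpha), and because the
# expected complete-data log-likelihood and its gradient are block-separable,
# all blocks are updated in one joint L-BFGS-B call on the full coefficient
# matrix, which is exactly the per-block EM but vectorized over the matrix.

.validate_counts <- function(Y) {
  Y <- as.matrix(Y)
  if (!is.numeric(Y)) stop("'Y' must be a numeric matrix")
  if (any(!is.finite(Y)) || any(Y < 0) || any(Y != floor(Y))) {
    stop("'Y' must contain finite non-negative integers")
  }
  if (all(Y == 0)) stop("'Y' is all zero")
  Y
}

.validate_mask <- function(Y, mask) {
  if (is.null(mask)) return(matrix(1, nrow(Y), ncol(Y)))
  mask <- as.matrix(mask) * 1
  stopifnot(dim(mask) == dim(Y))
  if (any(rowSums(mask) == 0) || any(colSums(mask) == 0)) {
    stop("mask leaves an all-masked row or column")
  }
  mask
}

#' Relative library size
#'
#' Per-sample total count divided by the median total count, used as a
#' multiplicative offset on the GP rate:
#' \eqn{T_i = \sum_j y_{ij} / \mathrm{median}_i(\sum_j y_{ij})}.  For even
#' `n` the median is the midpoint of the two central order statistics, so
#' `median(T)` is 1 up to that convention.
#'
#' @param Y count matrix (samples in rows).
#' @return positive numeric vector of length `nrow(Y)`.
#' @examples
#' relative_library_size(rbind(a = c(4, 6), b = c(8, 12), c = c(12, 18)))
#' @export
relative_library_size <- function(Y) {
  Y <- as.matrix(Y)
  rs <- rowSums(Y)
  if (any(rs == 0)) {
    bad <- if (!is.null(rownames(Y))) rownames(Y)[rs == 0] else which(rs == 0)
    stop("sample(s) with zero total count: ", paste(bad, collapse = ", "))
  }
  as.numeric(rs / stats::median(rs))
}

#' SVD initialization of the factor matrices
#'
#' Initial scores and loadings from the SVD of the log-transformed matrix
#' \eqn{\tilde Y_{ij} = \log((y_{ij} + 1) / T_i)}: with
#' \eqn{\tilde Y = U \Sigma V'}, the first `K` right singular vectors give
#' `L0` and `F0` absorbs the singular values,
#' \eqn{F0 = (U_{,1}\Sigma_{11}, \ldots, U_{,K}\Sigma_{KK})}.  The pseudo
#' count handles zeros and the division by `T` matches the model offset, so
#' `F0 %*% t(L0)` is the best rank-`K` approximation of a crude estimate of
#' `log(Lambda)`.
#'
#' @param Y count matrix.
#' @param K rank, at most `min(dim(Y))`.
#' @param T relative library sizes; computed from `Y` when `NULL`.
#' @return list with matrices `F` (n x K) and `L` (m x K).
#' @export
svd_init <- function(Y, K, T = NULL) {
  Y <- .validate_counts(Y)
  if (K < 1 || K > min(dim(Y))) stop("'K' must lie in 1..min(n, m)")
  if (is.null(T)) T <- relative_library_size(Y)
  Yt <- sweep(log(Y + 1), 1, log(T), "-")
  s <- svd(Yt, nu = K, nv = K)
  list(F = sweep(s$u, 2, s$d[seq_len(K)], "*"), L = s$v)
}

# One factor-update step: EM with shared (tau, alpha), alternated with the
# 2-D (tau, alpha) maximization of the observed-data likelihood.
# what = "loadings": Eta = design %*% t(B), B is m x K (design = F, n x K)
# what = "scores":   Eta = B %*% t(design), B is n x K (design = L, m x K)
.stacked_update <- function(Y, W, logT, design, B, tau, alpha, what, control) {
  K <- ncol(design)
  # box constraint on the coefficients: wide enough never to bind a genuine
  # optimum (after re-identification the scores absorb the singular values,
  # so the scale of B is data-dependent), but finite so that degenerate
  # all-zero blocks cannot run away
  bb <- max(1e3, 4 * max(abs(B)))
  dims <- dim(B)
  eta_of <- if (what == "loadings") {
    function(B) design %*% t(B)
  } else {
    function(B) B %*% t(design)
  }
  grad_of <- if (what == "loadings") {
    function(G) crossprod(G, design)
  } else {
    function(G) G %*% design
  }
  obj_ll <- function(B, tau, alpha) {
    .gz_obs_loglik(Y, eta_of(B), logT, tau, alpha, W)
  }
  ll <- obj_ll(B, tau, alpha)
  for (outer in seq_len(control$outer_maxit)) {
    # (a) EM over the coefficient blocks at fixed (tau, alpha)
    for (emit in seq_len(control$em_maxit)) {
      Z <- .gz_estep(Y, eta_of(B), logT, tau, alpha)
      qg <- function(p) {
        Bp <- matrix(p, dims[1], dims[2])
        g <- .gz_q_grad(Y, Z, eta_of(Bp), logT, tau, alpha, W)
        list(value = -g$Q, grad = -as.numeric(grad_of(g$Geta)))
      }
      opt <- .optim_qg(as.numeric(B), qg, lower = rep(-bb, length(B)),
                       upper = rep(bb, length(B)), maxit = 100)
      B <- matrix(opt$par, dims[1], dims[2])
      ll_em <- obj_ll(B, tau, alpha)
      if (abs(ll_em - ll) <= control$em_tol * (abs(ll) + 1)) { ll <- ll_em; break }
      ll <- ll_em
    }
    # (b) shared (tau, alpha) update on the observed-data likelihood
    Eta <- eta_of(B)
    qg_ta <- function(p) {
      v <- .gz_obs_ta_grad(Y, Eta, logT, p[1], p[2], W)
      list(value = -v[1], grad = -v[2:3])
    }
    opt <- .optim_qg(c(tau, alpha), qg_ta, lower = c(-50, 0),
                     upper = c(50, control$alpha_max), maxit = 100)
    tau <- opt$par[1]; alpha <- opt$par[2]
    ll_new <- obj_ll(B, tau, alpha)
    if (abs(ll_new - ll) <= control$outer_tol * (abs(ll) + 1)) { ll <- ll_new; break }
    ll <- ll_new
  }
  list(B = B, tau = tau, alpha = alpha, loglik = ll)
}

#' Fit the ZIGP factor model
#'
#' Maximum-likelihood estimation of the rank-`K` factor model
#' \eqn{\log(\Lambda) = F L'} for a ZIGP count matrix, by the alternating
#' algorithm: SVD initialization, then repeated loading updates (column
#' regressions on `F`), score updates (row regressions on `L`) — each an EM
#' with the shared `(tau, alpha)` re-maximized — and an SVD re-identification
#' of `(F, L)` that leaves `F L'` (hence the likelihood) unchanged and makes
#' the columns orthogonal.  Iteration stops when the relative change in total
#' log-likelihood falls below `control$fit_tol`.
#'
#' @param Y non-negative integer count matrix, samples in rows.
#' @param K rank of the factorization.
#' @param T relative library sizes (length `nrow(Y)`); computed from the data
#'   by [relative_library_size()] when `NULL`.
#' @param mask optional logical/0-1 inclusion matrix; excluded entries are
#'   dropped from every regression and from the total likelihood (used by the
#'   cross-validation).
#' @param init optional warm start: a list with `F`, `L` and optionally
#'   `tau`, `alpha`.
#' @param tau,alpha initial shared parameters.
#' @param init_jitter_sd SD of optional Gaussian jitter added to the SVD
#'   initialization (default 0: the fit is a deterministic function of the
#'   data); requires `seed` when positive.
#' @param seed integer seed for the initialization jitter.
#' @param control see [zigp_control()].
#' @param verbose print per-iteration log-likelihoods?
#' @return an object of class `gzigpfa_fit` with elements `F`, `L`, `tau`,
#'   `alpha`, `T`, `loglik`, `loglik_trace` (per step), `n_iters`,
#'   `converged`, `K`, `mask`, `sample_ids`, `taxon_ids`.
#' @examples
#' sim <- simulate_scenario(scenario_spec(1, n = 40, m = 20, seed = 1))
#' fit <- gzigpfa(sim$Y, K = 3, T = sim$spec$T)
#' fit
#' @export
gzigpfa <- function(Y, K, T = NULL, mask = NULL, init = NULL, tau = 1,
                    alpha = 0.05, init_jitter_sd = 0, seed = NULL,
                    control = zigp_control(), verbose = FALSE) {
  Y <- .validate_counts(Y)
  n <- nrow(Y); m <- ncol(Y)
  if (K < 1 || K > min(n, m)) stop("'K' must lie in 1..min(n, m)")
  W <- .validate_mask(Y, mask)
  if (is.null(T)) T <- relative_library_size(Y)
  T <- rep_len(as.numeric(T), n)
  if (any(T <= 0)) stop("'T' must be positive")
  logT <- log(T)
  if (is.null(init)) {
    ini <- svd_init(Y, K, T)
    Fm <- ini$F; Lm <- ini$L
    if (init_jitter_sd > 0) {
      if (!is.null(seed)) set.seed(seed)
      Fm <- Fm + matrix(rnorm(length(Fm), 0, init_jitter_sd), n, K)
      Lm <- Lm + matrix(rnorm(length(Lm), 0, init_jitter_sd), m, K)
    }
  } else {
    Fm <- as.matrix(init$F); Lm <- as.matrix(init$L)
    stopifnot(dim(Fm) == c(n, K), dim(Lm) == c(m, K))
    if (!is.null(init$tau)) tau <- init$tau
    if (!is.null(init$alpha)) alpha <- init$alpha
  }
  ll <- .gz_obs_loglik(Y, Fm %*% t(Lm), logT, tau, alpha, W)
  trace <- data.frame(iter = 0L, step = "init", loglik = ll)
  converged <- FALSE
  it <- 0
  while (it < control$fit_maxit) {
    it <- it + 1
    s1 <- .stacked_update(Y, W, logT, Fm, Lm, tau, alpha, "loadings", control)
    Lm <- s1$B; tau <- s1$tau; alpha <- s1$alpha
    trace <- rbind(trace, data.frame(iter = it, step = "loadings", loglik = s1$loglik))
    s2 <- .stacked_update(Y, W, logT, Lm, Fm, tau, alpha, "scores", control)
    Fm <- s2$B; tau <- s2$tau; alpha <- s2$alpha
    trace <- rbind(trace, data.frame(iter = it, step = "scores", loglik = s2$loglik))
    # Step 3: SVD re-identification, keeping F L' bit-identical up to
    # floating error (the likelihood is invariant to this rotation)
    sv <- svd(Fm %*% t(Lm), nu = K, nv = K)
    Fm <- sweep(sv$u, 2, sv$d[seq_len(K)], "*")
    Lm <- sv$v
    ll_new <- s2$loglik
    if (verbose) message(sprintf("iter %d: loglik %.4f (tau %.3f, alpha %.3f)",
                                 it, ll_new, tau, alpha))
    if (abs(ll_new - ll) <= control$fit_tol * (abs(ll) + 1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  if (!converged) warning("alternating algorithm did not converge in ",
                          control$fit_maxit, " iterations")
  structure(list(F = Fm, L = Lm, tau = tau, alpha = alpha, T = T,
                 loglik = ll, loglik_trace = trace, n_iters = it,
                 converged = converged, K = K,
                 mask = if (is.null(mask)) NULL else W,
                 sample_ids = rownames(Y), taxon_ids = colnames(Y)),
            class = "gzigpfa_fit")
}

#' Total log-likelihood of a fitted factor model on arbitrary entries
#'
#' Evaluates the ZIGP log-likelihood of `Y` at the fitted `(F, L, tau,
#' alpha)` over the entries selected by `mask` — used by the entry-wise
#' cross-validation to score held-out cells.
#'
#' @param fit a `gzigpfa_fit`.
#' @param Y the count matrix.
#' @param mask logical/0-1 matrix of entries to include (default: all).
#' @return the summed log-likelihood.
#' @export
gzigpfa_loglik <- function(fit, Y, mask = NULL) {
  Y <- .validate_counts(Y)
  # evaluation masks may select any subset of entries (e.g. a held-out fold
  # whose complement covers whole rows), so no row/column coverage check here
  W <- if (is.null(mask)) matrix(1, nrow(Y), ncol(Y)) else {
    m <- as.matrix(mask) * 1
    stopifnot(dim(m) == dim(Y))
    m
  }
  .gz_obs_loglik(Y, fit$F %*% t(fit$L), log(fit$T), fit$tau, fit$alpha, W)
}

#' Predicted total zero-probability matrix
#'
#' Entry-wise total probability of observing a zero under the fitted model:
#' \eqn{\hat\phi_{ij} + (1-\hat\phi_{ij}) \exp\{-T_i\hat\lambda_{ij} /
#' (1+\hat\alpha T_i \hat\lambda_{ij})\}} with
#' \eqn{logit(\hat\Phi) = -\hat\tau \log(\hat\Lambda)}.  Comparing its
#' ordering against the observed zero pattern shows how well the model
#' captures the excess-zero structure.
#'
#' @param fit a `gzigpfa_fit`.
#' @param mixture_weighted see [zigp_total_zero_prob()].
#' @return an n x m matrix of probabilities.
#' @export
predicted_zero_matrix <- function(fit, mixture_weighted = TRUE) {
  eta <- fit$F %*% t(fit$L)
  lambda <- exp(eta)
  phi <- phi_from_lambda(lambda, fit$tau)
  mu <- sweep(lambda, 1, fit$T, "*")
  out <- zigp_total_zero_prob(phi, mu, fit$alpha, mixture_weighted)
  dimnames(out) <- list(fit$sample_ids, fit$taxon_ids)
  out
}
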