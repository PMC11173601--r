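# The log-PCA baseline and the simulation benchmark harness.

#' Log-PCA estimate of the log-rate matrix
#'
#' The standard pseudo-count baseline: zeros are replaced by a small value,
#' the matrix is log-transformed, column-centred, and reconstructed at rank
#' `K` from its truncated SVD with the column means added back.
#'
#' @param Y count matrix.
#' @param K rank of the reconstruction (`K = 0` gives the column-mean
#'   matrix).
#' @param pseudo positive value replacing zeros before the log transform.
#' @param center column-centre before the SVD (the standard PCA definition);
#'   `FALSE` gives the raw truncated SVD of the log matrix.
#' @return list with `logLambda_hat` (n x m), `rank`, and `method`.
#' @export
log_pca <- function(Y, K, pseudo = 0.5, center = TRUE) {
  Y <- as.matrix(Y)
  if (pseudo <= 0) stop("'pseudo' must be positive")
  Z <- log(ifelse(Y == 0, pseudo, Y))
  mu <- if (center) colMeans(Z) else rep(0, ncol(Z))
  Zc <- sweep(Z, 2, mu)
  est <- if (K >= 1) {
    s <- svd(Zc, nu = K, nv = K)
    sweep(s$u, 2, s$d[seq_len(K)], "*") %*% t(s$v)
  } else {
    matrix(0, nrow(Z), ncol(Z))
  }
  list(logLambda_hat = sweep(est, 2, mu, "+"), rank = K, method = "log_pca")
}

#' Frobenius loss between estimated and true log-rate matrices
#'
#' \eqn{\|\hat{M} - M\|_F = \sqrt{\sum_{ij} (\hat m_{ij} - m_{ij})^2}}.
#'
#' @param logLambda_hat,logLambda_true conformable numeric matrices.
#' @return the Frobenius norm of the difference.
#' @export
frobenius_loss <- function(logLambda_hat, logLambda_true) {
  if (!all(dim(logLambda_hat) == dim(logLambda_true))) {
    stop("matrices are not conformable")
  }
  sqrt(sum((logLambda_hat - logLambda_true)^2))
}

#' Replicated simulation benchmark for one scenario cell
#'
#' Generates `n_replicates` datasets from the scenario (seeds
#' `base_seed + 1, ..., base_seed + n_replicates`), estimates the rank-3
#' log-rate matrix with the requested method, and records the loss against
#' the true `log(Lambda)` per replicate.
#'
#' Losses are summarized on the column-normalized Frobenius scale
#' \eqn{\|\hat{M}-M\|_F / \sqrt{m}} by default — the scale on which losses
#' are comparable across matrix widths; `normalize = "none"` reports the raw
#' Frobenius norm.
#'
#' @param spec a [scenario_spec()]; its seed field is ignored in favour of
#'   `base_seed + replicate`.
#' @param method `"gzigpfa"` or `"log_pca"`.
#' @param n_replicates number of replicate datasets.
#' @param base_seed integer; replicate r uses seed `base_seed + r`.
#' @param K fitted rank (default 3, the generating rank).
#' @param normalize `"per_taxon"` (divide by `sqrt(m)`) or `"none"`.
#' @param pseudo pseudo count for the log-PCA baseline.
#' @param control see [zigp_control()].
#' @param verbose print per-replicate losses?
#' @return an object of class `loss_summary`: list with
#'   `per_replicate_losses`, `mean`, `sd`, `n_replicates`, `n_failed`,
#'   `method`, `normalize`, and `spec`.
#' @export
run_scenario_bench <- function(spec, method = c("gzigpfa", "log_pca"),
                               n_replicates = 10, base_seed = 0, K = 3,
                               normalize = c("per_taxon", "none"),
                               pseudo = 0.5, control = zigp_control(),
                               verbose = FALSE) {
  method <- match.arg(method)
  normalize <- match.arg(normalize)
  scale <- if (normalize == "per_taxon") sqrt(spec$m) else 1
  losses <- rep(NA_real_, n_replicates)
  for (r in seq_len(n_replicates)) {
    sp <- spec
    sp$seed <- as.integer(base_seed + r)
    sim <- simulate_scenario(sp)
    est <- tryCatch({
      if (method == "gzigpfa") {
        fit <- gzigpfa(sim$Y, K, T = sp$T, control = control)
        fit$F %*% t(fit$L)
      } else {
        log_pca(sim$Y, K, pseudo = pseudo)$logLambda_hat
      }
    }, error = function(e) {
      warning("replicate ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(est)) losses[r] <- frobenius_loss(est, sim$logLambda_true) / scale
    if (verbose && !is.na(losses[r])) {
      message(sprintf("replicate %d (%s): loss %.4f", r, method, losses[r]))
    }
  }
  ok <- losses[!is.na(losses)]
  structure(list(per_replicate_losses = losses,
                 mean = mean(ok),
                 sd = if (length(ok) > 1) stats::sd(ok) else NA_real_,
                 n_replicates = n_replicates,
                 n_failed = sum(is.na(losses)),
                 method = method, normalize = normalize, spec = spec),
            class = "loss_summary")
}

#' @export
print.loss_summary <- function(x, ...) {
  cat(sprintf("%s, scenario %d, zero level %.2f: mean loss %.4f (sd %.4f) over %d replicates\n",
              x$method, x$spec$scenario, x$spec$zero_target, x$mean,
              x$sd, x$n_replicates - x$n_failed))
  invisible(x)
}
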