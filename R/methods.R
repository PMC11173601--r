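# S3 methods for fitted objects.

#' @export
print.gzigpfa_fit <- function(x, ...) {
  cat("Zero-inflated generalized Poisson factor model\n")
  cat(sprintf("  %d samples x %d taxa, rank K = %d\n",
              nrow(x$F), nrow(x$L), x$K))
  cat(sprintf("  tau = %.4f, alpha = %.4f\n", x$tau, x$alpha))
  cat(sprintf("  log-likelihood %.2f after %d iteration%s (%s)\n",
              x$loglik, x$n_iters, if (x$n_iters == 1) "" else "s",
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Tidy a fitted factor model
#'
#' Returns the factor scores or loadings in long form: one row per
#' (sample or taxon, factor) pair.
#'
#' @param x a `gzigpfa_fit`.
#' @param matrix `"scores"` (F) or `"loadings"` (L).
#' @param ... unused.
#' @return a data frame with columns `id`, `factor`, `value`.
#' @export
tidy.gzigpfa_fit <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  M <- if (matrix == "scores") x$F else x$L
  ids <- if (matrix == "scores") x$sample_ids else x$taxon_ids
  if (is.null(ids)) {
    ids <- paste0(if (matrix == "scores") "S" else "T", seq_len(nrow(M)))
  }
  data.frame(id = rep(ids, ncol(M)),
             factor = rep(seq_len(ncol(M)), each = nrow(M)),
             value = as.numeric(M))
}

#' One-row model summary
#'
#' @param x a `gzigpfa_fit`.
#' @param ... unused.
#' @return a one-row data frame with `K`, `tau`, `alpha`, `loglik`,
#'   `n_iters`, `converged`.
#' @export
glance.gzigpfa_fit <- function(x, ...) {
  data.frame(K = x$K, tau = x$tau, alpha = x$alpha, loglik = x$loglik,
             n_iters = x$n_iters, converged = x$converged)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
plot.gzigpfa_fit <- function(x, ...) {
  graphics::matplot(x$loglik_trace$loglik, type = "b", pch = 1,
                    xlab = "update step", ylab = "total log-likelihood",
                    main = "Alternating-algorithm likelihood trace", ...)
  invisible(x)
}

#' @export
print.gzigpfa_cv <- function(x, ...) {
  cat("Entry-wise cross-validation for rank selection\n")
  for (i in seq_along(x$ranks)) {
    cat(sprintf("  rank %d: held-out loglik %.2f%s\n", x$ranks[i],
                x$cv_loglik[i],
                if (x$ranks[i] == x$selected_rank) "  <- selected" else ""))
  }
  invisible(x)
}

#' @export
plot.gzigpfa_cv <- function(x, ...) {
  graphics::plot(x$ranks, x$cv_loglik, type = "b", xlab = "rank",
                 ylab = "summed held-out log-likelihood",
                 main = "Cross-validated rank selection", ...)
  graphics::abline(v = x$selected_rank, lty = 2)
  invisible(x)
}
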