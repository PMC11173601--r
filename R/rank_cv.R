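# Entry-wise N-fold cross-validation for rank selection: individual matrix
# cells (not whole rows) are partitioned into folds, the model is fitted on
# the complement of each fold, and the held-out cells are scored by their
# ZIGP log-likelihood at the fitted parameters.  The summed held-out
# likelihood over the folds, as a function of the candidate rank, peaks at
# the rank that generalizes best.

#' Random entry-wise fold assignment
#'
#' Partitions the `n * m` matrix cells uniformly at random into `N` folds of
#' sizes differing by at most one, redrawing (boundedly) if any fold's
#' training complement would leave a row or column empty.
#'
#' @param n,m matrix dimensions.
#' @param N number of folds (>= 2).
#' @param seed optional integer seed.
#' @return an `n x m` integer matrix of fold labels in `1..N`.
#' @export
make_cv_folds <- function(n, m, N = 10, seed = NULL) {
  if (N < 2) stop("'N' must be at least 2")
  if (N > n * m) stop("more folds than matrix entries")
  if (!is.null(seed)) set.seed(seed)
  for (try in 1:100) {
    lab <- rep_len(seq_len(N), n * m)
    folds <- matrix(lab[sample.int(n * m)], n, m)
    ok <- all(vapply(seq_len(N), function(k) {
      tr <- folds != k
      all(rowSums(tr) > 0) && all(colSums(tr) > 0)
    }, logical(1)))
    if (ok) return(folds)
  }
  stop("could not build folds keeping every row and column in every training set")
}

#' Select the factor-model rank by entry-wise cross-validation
#'
#' For each candidate rank, fits the factor model on the training entries of
#' each fold (warm-started from a full-data fit at that rank) and sums the
#' ZIGP log-likelihood of the held-out entries at the fitted
#' `(F, L, tau, alpha)`.  The selected rank maximizes the summed held-out
#' likelihood; ties break to the smallest rank.
#'
#' @param Y count matrix.
#' @param ranks candidate ranks (default `1:6`).
#' @param N number of folds (default 10).
#' @param seed integer seed driving the fold assignment.
#' @param T relative library sizes (computed from `Y` when `NULL`).
#' @param control see [zigp_control()].
#' @param verbose print progress?
#' @return an object of class `gzigpfa_cv`: a list with `ranks`,
#'   `cv_loglik`, `selected_rank`, `fold_assignment`, `per_fold` (fold x rank
#'   matrix of held-out log-likelihoods), and `seed`.
#' @export
cv_select_rank <- function(Y, ranks = 1:6, N = 10, seed = 1, T = NULL,
                           control = zigp_control(), verbose = FALSE) {
  Y <- .validate_counts(Y)
  if (any(ranks < 1) || any(ranks > min(dim(Y)))) {
    stop("candidate ranks must lie in 1..min(n, m)")
  }
  ranks <- sort(unique(as.integer(ranks)))
  if (is.null(T)) T <- relative_library_size(Y)
  folds <- make_cv_folds(nrow(Y), ncol(Y), N, seed)
  per_fold <- matrix(NA_real_, N, length(ranks),
                     dimnames = list(NULL, paste0("K", ranks)))
  for (r in seq_along(ranks)) {
    K <- ranks[r]
    full <- gzigpfa(Y, K, T = T, control = control)
    for (k in seq_len(N)) {
      train <- folds != k
      fit <- tryCatch(
        gzigpfa(Y, K, T = T, mask = train,
                init = list(F = full$F, L = full$L, tau = full$tau,
                            alpha = full$alpha),
                control = control),
        error = function(e) stop("fold ", k, ", rank ", K, ": ",
                                 conditionMessage(e))
      )
      per_fold[k, r] <- gzigpfa_loglik(fit, Y, mask = !train)
      if (verbose) message(sprintf("rank %d fold %d: held-out loglik %.2f",
                                   K, k, per_fold[k, r]))
    }
  }
  cv <- colSums(per_fold)
  structure(list(ranks = ranks, cv_loglik = unname(cv),
                 selected_rank = ranks[which.max(cv)],
                 fold_assignment = folds, per_fold = per_fold, seed = seed),
            class = "gzigpfa_cv")
}
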