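# Tabular I/O: count tables in and fitted factor matrices out.

#' Read a count table
#'
#' Reads a TSV/CSV count table with row labels in the first column and
#' column labels in the header.  `orientation = "taxa_rows"` transposes the
#' table into the internal samples x taxa orientation.
#'
#' @param path file path; the delimiter is taken from the extension
#'   (`.csv` = comma, otherwise tab).
#' @param orientation `"samples_rows"` (default) or `"taxa_rows"`.
#' @return an integer count matrix with sample and taxon labels.
#' @export
read_count_table <- function(path, orientation = c("samples_rows", "taxa_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, comment.char = "")
  Y <- as.matrix(df)
  if (!is.numeric(Y)) stop("count table contains non-numeric cells")
  bad <- which(Y < 0 | Y != floor(Y), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer or negative count at row '%s', column '%s'",
                 rownames(Y)[bad[1, 1]], colnames(Y)[bad[1, 2]]))
  }
  if (anyDuplicated(rownames(Y)) || anyDuplicated(colnames(Y))) {
    stop("duplicate sample or taxon identifiers")
  }
  if (orientation == "taxa_rows") Y <- t(Y)
  storage.mode(Y) <- "double"
  Y
}

#' Write a count table
#'
#' @param Y count matrix (samples in rows).
#' @param path output path (`.csv` writes comma-separated, otherwise TSV).
#' @export
write_count_table <- function(Y, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (is.null(rownames(Y))) rownames(Y) <- paste0("S", seq_len(nrow(Y)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("T", seq_len(ncol(Y)))
  df <- data.frame(sample_id = rownames(Y), Y, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_labelled_matrix <- function(M, rlab, clab, rname, path) {
  rownames(M) <- if (is.null(rlab)) paste0(substr(rname, 1, 1), seq_len(nrow(M))) else rlab
  colnames(M) <- clab
  df <- data.frame(id = rownames(M), format(M, digits = 17, trim = TRUE),
                   check.names = FALSE)
  names(df)[1] <- rname
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a fitted factor model to a directory
#'
#' Writes `F.tsv` and `L.tsv` (full-precision, labelled), `params.json`
#' (tau, alpha, K, log-likelihood trace, convergence flag, package version),
#' and optionally `cv.tsv` for a cross-validation result.
#'
#' @param fit a `gzigpfa_fit`.
#' @param dir output directory (created if missing).
#' @param cv optional `gzigpfa_cv` result.
#' @return the directory, invisibly.
#' @export
write_gzigpfa_fit <- function(fit, dir, cv = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kn <- paste0("factor", seq_len(fit$K))
  .write_labelled_matrix(fit$F, fit$sample_ids, kn, "sample_id",
                         file.path(dir, "F.tsv"))
  .write_labelled_matrix(fit$L, fit$taxon_ids, kn, "taxon_id",
                         file.path(dir, "L.tsv"))
  params <- list(tau = fit$tau, alpha = fit$alpha, K = fit$K,
                 loglik = fit$loglik,
                 loglik_trace = fit$loglik_trace$loglik,
                 trace_step = fit$loglik_trace$step,
                 n_iters = fit$n_iters, converged = fit$converged,
                 package_version = as.character(utils::packageVersion("gzigpfa")))
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(cv)) {
    utils::write.table(
      data.frame(rank = cv$ranks, cv_loglik = cv$cv_loglik),
      file.path(dir, "cv.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a fitted factor model back from a directory
#'
#' @param dir directory written by [write_gzigpfa_fit()].
#' @return a `gzigpfa_fit`-like list with `F`, `L`, `tau`, `alpha`, `K`.
#' @export
read_gzigpfa_fit <- function(dir) {
  rd <- function(f) {
    df <- utils::read.table(file.path(dir, f), header = TRUE, sep = "\t",
                            row.names = 1, check.names = FALSE)
    as.matrix(df)
  }
  Fm <- rd("F.tsv"); Lm <- rd("L.tsv")
  params <- jsonlite::read_json(file.path(dir, "params.json"),
                                simplifyVector = TRUE)
  structure(list(F = Fm, L = Lm, tau = params$tau, alpha = params$alpha,
                 K = params$K, T = rep(1, nrow(Fm)), loglik = params$loglik,
                 converged = params$converged,
                 sample_ids = rownames(Fm), taxon_ids = rownames(Lm)),
            class = "gzigpfa_fit")
}
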