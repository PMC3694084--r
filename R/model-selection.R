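#' Laplace log model evidence of a fitted model
#'
#' The final free energy of the inversion is the Laplace approximation to the
#' log model evidence used for model comparison.
#'
#' @param posterior an `erpdcm_posterior`
#' @return log evidence (nats); a warning is attached when the inversion had
#'   not converged
#' @export
log_evidence <- function(posterior) {
  ev <- posterior$F_trace[length(posterior$F_trace)]
  if (!isTRUE(posterior$converged)) {
    warning("inversion had not converged; evidence may be unreliable")
    attr(ev, "unconverged") <- TRUE
  }
  ev
}

#' Fixed-effects Bayesian model selection
#'
#' Sums log evidences over subjects for each candidate model (the
#' fixed-effects assumption: one common model generated every subject's data)
#' and converts the sums to posterior model probabilities with a
#' log-sum-exp-stabilized softmax.
#'
#' @param evidence numeric matrix, subjects x models, of log evidences; model
#'   names taken from the column names
#' @return object of class `erpdcm_bms`: `sum_log_evidence`, `probability`
#'   (sums to 1), `best` (winning model label)
#' @export
fixed_effects_bms <- function(evidence) {
  evidence <- as.matrix(evidence)
  if (ncol(evidence) < 2) stop("model comparison needs at least 2 models")
  if (nrow(evidence) < 1) stop("model comparison needs at least 1 subject")
  if (!all(is.finite(evidence))) stop("log evidences must be finite")
  if (is.null(colnames(evidence)))
    colnames(evidence) <- paste0("model", seq_len(ncol(evidence)))
  s <- colSums(evidence)
  z <- s - max(s)                      # log-sum-exp stabilization
  p <- exp(z) / sum(exp(z))
  structure(list(sum_log_evidence = s, probability = p,
                 best = names(which.max(p)), n_subjects = nrow(evidence)),
            class = "erpdcm_bms")
}

#' @export
print.erpdcm_bms <- function(x, ...) {
  cat("Fixed-effects BMS over", x$n_subjects, "subject(s)\n")
  print(data.frame(sum_log_evidence = round(x$sum_log_evidence, 2),
                   probability = signif(x$probability, 4)))
  cat("winning model:", x$best, "\n")
  invisible(x)
}

#' Read / write an evidence table
#'
#' TSV with one row per subject and one labelled column per model.
#'
#' @param path file path
#' @export
read_evidence_table <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              check.names = FALSE))
}

#' @rdname read_evidence_table
#' @param evidence subjects x models matrix
#' @export
write_evidence_table <- function(evidence, path) {
  utils::write.table(evidence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
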