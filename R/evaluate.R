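#' Pearson correlation between true and estimated trajectories
#'
#' The standard decoding accuracy measure: the Pearson correlation
#' coefficient between an actual joint-angle sequence and its estimate,
#' computed on the window-step time base. Returns `NA` (with a warning) when
#' either sequence has zero variance, where the coefficient is undefined —
#' never a silent 0.
#'
#' @param theta numeric sequence (true angles).
#' @param theta_hat numeric sequence of equal length (estimates).
#'
#' @return A scalar in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
pearson_cc <- function(theta, theta_hat) {
  theta <- as.numeric(theta); theta_hat <- as.numeric(theta_hat)
  if (length(theta) != length(theta_hat)) {
    stop(sprintf("sequences have lengths %d and %d", length(theta), length(theta_hat)),
         call. = FALSE)
  }
  if (length(theta) < 2L) stop("need at least 2 points", call. = FALSE)
  if (stats::sd(theta) == 0 || stats::sd(theta_hat) == 0) {
    warning("correlation undefined: a sequence has zero variance", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(theta, theta_hat)
}

#' Evaluate a decoded trace against ground truth
#'
#' Computes the per-DOF Pearson correlation between decoded and true angle
#' trajectories (one value per window step) and aggregates mean and standard
#' deviation over the DOFs where the correlation is defined.
#'
#' @param trace a [run_filter()] trace, or an n x M matrix of estimates.
#' @param truth n x M matrix of true states at window steps (or an
#'   `angle_signal` already sampled at window steps, or a `training_pair`
#'   whose `X` is used).
#' @param metadata optional named list of labels (subject, dataset, ...)
#'   carried into the report.
#'
#' @return An object of class `eval_report`: `cc_per_dof` (named), `mean_cc`,
#'   `sd_cc`, `n_steps`, `n_defined`, `metadata`.
#' @export
evaluate_trace <- function(trace, truth, metadata = list()) {
  X_hat <- if (inherits(trace, "kf_trace")) trace$X_hat else as.matrix(trace)
  Xt <- if (inherits(truth, "training_pair")) {
    truth$X
  } else if (inherits(truth, "angle_signal")) {
    truth$data
  } else {
    as.matrix(truth)
  }
  if (nrow(X_hat) != nrow(Xt)) {
    stop(sprintf("trace has %d DOFs but truth has %d", nrow(X_hat), nrow(Xt)),
         call. = FALSE)
  }
  if (ncol(X_hat) != ncol(Xt)) {
    stop(sprintf("trace has %d steps but truth has %d", ncol(X_hat), ncol(Xt)),
         call. = FALSE)
  }
  n <- nrow(X_hat)
  cc <- vapply(seq_len(n), function(d) {
    if (stats::sd(Xt[d, ]) == 0 || stats::sd(X_hat[d, ]) == 0) NA_real_
    else stats::cor(Xt[d, ], X_hat[d, ])
  }, numeric(1))
  names(cc) <- if (inherits(trace, "kf_trace") && !is.null(trace$dof_names)) {
    trace$dof_names
  } else {
    default_dof_names(n)
  }
  if (anyNA(cc)) {
    warning(sprintf("%d DOF(s) had zero variance; excluded from the aggregate",
                    sum(is.na(cc))), call. = FALSE)
  }
  defined <- cc[!is.na(cc)]
  structure(list(cc_per_dof = cc,
                 mean_cc = if (length(defined)) mean(defined) else NA_real_,
                 sd_cc = if (length(defined) > 1L) stats::sd(defined) else NA_real_,
                 n_steps = ncol(X_hat),
                 n_defined = length(defined),
                 metadata = metadata),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("<eval_report> %d steps, %d/%d DOFs defined\n",
              x$n_steps, x$n_defined, length(x$cc_per_dof)))
  cc <- round(x$cc_per_dof, digits)
  for (i in seq_along(cc)) {
    cat(sprintf("  %-12s CC = %s\n", names(cc)[i],
                ifelse(is.na(cc[i]), "undefined", format(cc[i]))))
  }
  cat(sprintf("  mean CC = %.3f (sd %.3f)\n", x$mean_cc, x$sd_cc))
  invisible(x)
}

#' Flatten an evaluation report to a data frame
#'
#' One row per DOF (subject, dataset and other metadata repeated), suitable
#' for binding across runs and subjects.
#'
#' @param report an [evaluate_trace()] report.
#' @return A data.frame with columns `dof`, `cc`, plus one column per
#'   metadata entry.
#' @export
report_to_df <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  out <- data.frame(dof = names(report$cc_per_dof),
                    cc = as.numeric(report$cc_per_dof),
                    stringsAsFactors = FALSE)
  for (nm in names(report$metadata)) out[[nm]] <- report$metadata[[nm]]
  out
}
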