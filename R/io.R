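# Plain-text serialization: every artifact is a delimited numeric table
# (channels/DOFs x samples) plus a small JSON sidecar carrying rates, names
# and provenance, so sessions, models and traces survive any toolchain.

#' Write a session (EMG + angles) to a directory
#'
#' Writes `emg.tsv` and `angles.tsv` (rows = channels/DOFs, columns =
#' samples, tab-delimited) and `session.json` (fs, channel names, DOF names,
#' and for synthetic sessions the generating truth record).
#'
#' @param session a `synthetic_session`, or any list with `emg`
#'   ([emg_signal()]) and `angles` ([angle_signal()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(is.list(session), inherits(session$emg, "emg_signal"),
            inherits(session$angles, "angle_signal"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(session$emg$data),
                     file.path(dir, "emg.tsv"), sep = "\t", col.names = FALSE)
  data.table::fwrite(data.table::as.data.table(session$angles$data),
                     file.path(dir, "angles.tsv"), sep = "\t", col.names = FALSE)
  side <- list(fs = session$emg$fs,
               channel_names = session$emg$channel_names,
               dof_names = session$angles$dof_names)
  if (!is.null(session$truth)) {
    tr <- session$truth
    side$truth <- list(
      rest_deg = tr$rest_deg, envelope_baseline = tr$envelope_baseline,
      noise_scale = tr$noise_scale, joint_limits = tr$joint_limits,
      seed = tr$seed, gains = tr$gains,
      plan = if (nrow(tr$plan)) list(onset_s = tr$plan$onset_s,
                                     duration_s = tr$plan$duration_s,
                                     peak_deg = tr$plan$peak_deg,
                                     dofs = tr$plan$dofs) else NULL)
  }
  jsonlite::write_json(side, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir session directory.
#' @return List with `emg`, `angles` and (if present) `truth`.
#' @export
read_session <- function(dir) {
  side_path <- file.path(dir, "session.json")
  if (!file.exists(side_path)) {
    stop(sprintf("no session.json in %s", dir), call. = FALSE)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  emg <- as.matrix(data.table::fread(file.path(dir, "emg.tsv"), header = FALSE))
  ang <- as.matrix(data.table::fread(file.path(dir, "angles.tsv"), header = FALSE))
  dimnames(emg) <- NULL; dimnames(ang) <- NULL
  fs <- as.numeric(side$fs)
  list(emg = emg_signal(emg, fs, side$channel_names),
       angles = angle_signal(ang, fs, side$dof_names),
       truth = side$truth)
}

#' Serialize a trained model to JSON
#'
#' All matrices, means, flags and the training window count in one
#' schema-versioned JSON file; numbers are written at full precision so a
#' write/read round trip is exact.
#'
#' @param model a [train_kalman()] model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "kalman_model"))
  obj <- list(schema = "emgkalman-model-1",
              A = model$A, H = model$H, W = model$W, Q = model$Q,
              x_mean = model$x_mean, z_mean = model$z_mean,
              centered = model$centered, P0 = model$P0,
              M_train = model$M_train,
              dof_names = model$dof_names, channel_names = model$channel_names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path model JSON path.
#' @return A `kalman_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != "emgkalman-model-1") {
    stop(sprintf("%s is not an emgkalman model file", path), call. = FALSE)
  }
  structure(
    list(A = as.matrix(obj$A), H = as.matrix(obj$H),
         W = as.matrix(obj$W), Q = as.matrix(obj$Q),
         x_mean = as.numeric(obj$x_mean), z_mean = as.numeric(obj$z_mean),
         centered = isTRUE(obj$centered), P0 = as.matrix(obj$P0),
         M_train = as.integer(obj$M_train),
         dof_names = obj$dof_names, channel_names = obj$channel_names),
    class = "kalman_model")
}

#' Write a decoded trace to text
#'
#' Writes the estimated trajectories as a DOFs x steps tab-delimited table
#' with a JSON sidecar recording the step period and DOF names.
#'
#' @param trace a [run_filter()] trace.
#' @param path output `.tsv` path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param step_ms window step period in milliseconds (default 25).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, step_ms = 25) {
  stopifnot(inherits(trace, "kf_trace"))
  data.table::fwrite(data.table::as.data.table(trace$X_hat), path,
                     sep = "\t", col.names = FALSE)
  jsonlite::write_json(list(schema = "emgkalman-trace-1", step_ms = step_ms,
                            dof_names = trace$dof_names,
                            n_steps = trace$n_steps),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path trace `.tsv` path.
#' @return A `kf_trace` (without covariances/gains).
#' @export
read_trace <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  X_hat <- as.matrix(data.table::fread(path, header = FALSE))
  dimnames(X_hat) <- NULL
  structure(list(X_hat = X_hat, P = NULL, n_steps = ncol(X_hat),
                 dof_names = side$dof_names, gains = NULL,
                 innovations = NULL, covariances = NULL),
            class = "kf_trace")
}
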