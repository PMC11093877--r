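#' Build a movement plan for the synthetic session generator
#'
#' Each row describes one raised-cosine flexion/extension event: which DOFs
#' move together, when the movement starts, how long it lasts and its peak
#' excursion above the resting angle.
#'
#' @param dofs list of integer vectors, one per event, naming the DOF indices
#'   that move together.
#' @param onset_s numeric vector of event onsets (seconds).
#' @param duration_s numeric vector of event durations (seconds).
#' @param peak_deg numeric vector of peak excursions (degrees above rest).
#'
#' @return A `movement_plan` data.frame with a list-column of DOF sets.
#' @export
movement_plan <- function(dofs, onset_s, duration_s, peak_deg) {
  if (!is.list(dofs)) dofs <- as.list(dofs)
  L <- length(dofs)
  stopifnot(length(onset_s) == L, length(duration_s) == L, length(peak_deg) == L)
  if (any(duration_s <= 0)) stop("movement durations must be positive", call. = FALSE)
  out <- data.frame(onset_s = as.numeric(onset_s),
                    duration_s = as.numeric(duration_s),
                    peak_deg = as.numeric(peak_deg))
  out$dofs <- lapply(dofs, as.integer)
  class(out) <- c("movement_plan", class(out))
  out
}

#' Default movement plan: cyclic single-DOF flexions
#'
#' Sequences repeated flexion events over all DOFs (round-robin), emulating a
#' protocol of individual finger movements separated by rest, so every DOF
#' is exercised several times within the session.
#'
#' @param n_dofs number of DOFs.
#' @param duration_s session length in seconds.
#' @param move_s duration of each flexion event (default 2 s).
#' @param rest_s rest gap between consecutive events (default 1 s).
#' @param peak_deg peak excursion of each event (default 60 degrees).
#'
#' @return A `movement_plan`.
#' @export
default_movement_plan <- function(n_dofs, duration_s, move_s = 2, rest_s = 1,
                                  peak_deg = 60) {
  period <- move_s + rest_s
  n_events <- max(0L, floor((duration_s - rest_s) / period))
  if (n_events == 0L) {
    return(movement_plan(list(), numeric(0), numeric(0), numeric(0)))
  }
  onsets <- rest_s + period * (seq_len(n_events) - 1L)
  dofs <- as.list(((seq_len(n_events) - 1L) %% n_dofs) + 1L)
  movement_plan(dofs, onsets, rep(move_s, n_events), rep(peak_deg, n_events))
}

#' Generate a synthetic sEMG + joint-angle recording session
#'
#' Produces synchronized multichannel sEMG and joint-angle trajectories with
#' the statistical structure the decoder assumes: angles follow smooth
#' raised-cosine flexion/extension profiles around a nonzero rest posture,
#' and each EMG channel is band-limited (10-450 Hz) broadband noise whose
#' amplitude envelope is a channel-specific linear mixture of normalized DOF
#' excursions plus a baseline, with additive sensor noise on top. The linear
#' envelope-angle coupling makes the linear observation model true by
#' construction, so downstream fitting and filtering are testable end to end
#' without any recorded data.
#'
#' @param n_channels number of EMG channels (default 16).
#' @param n_dofs number of angle DOFs (default 6).
#' @param duration_s session length in seconds.
#' @param fs sampling rate (samples/s, >= 1000; default 2000).
#' @param plan a [movement_plan()]; defaults to cyclic single-DOF flexions.
#'   Events moving the same DOF must not overlap in time.
#' @param noise_scale standard deviation of the additive sensor noise, in
#'   units of the EMG carrier's baseline amplitude (default 0.05).
#' @param rest_deg resting posture, recycled to `n_dofs` (default 15 deg;
#'   deliberately nonzero so mean-centering in training is exercised).
#' @param joint_limits length-2 vector of admissible angles (degrees).
#' @param seed integer RNG seed; the session is a deterministic function of
#'   its arguments.
#'
#' @return An object of class `synthetic_session`: list with `emg`
#'   ([emg_signal()]), `angles` ([angle_signal()]) and `truth` (generating
#'   parameters: plan, per-channel/DOF envelope gains, rest posture, noise
#'   scale, seed).
#' @export
generate_session <- function(n_channels = 16L, n_dofs = 6L, duration_s = 60,
                             fs = 2000, plan = NULL, noise_scale = 0.05,
                             rest_deg = 15, joint_limits = c(-20, 110),
                             seed = 1L) {
  n_channels <- .stopifnot_scalar_int(n_channels, "n_channels")
  n_dofs <- .stopifnot_scalar_int(n_dofs, "n_dofs")
  if (fs < 1000) stop("fs must be at least 1000 samples/s", call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  if (is.null(plan)) plan <- default_movement_plan(n_dofs, duration_s)
  n_samples <- as.integer(round(duration_s * fs))
  rest <- rep_len(as.numeric(rest_deg), n_dofs)

  .check_plan(plan, n_dofs, duration_s)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  t_s <- (seq_len(n_samples) - 1L) / fs
  angles <- matrix(rest, n_dofs, n_samples)
  excursion <- matrix(0, n_dofs, n_samples)   # normalized [0, 1] activity
  if (nrow(plan) > 0L) {
    for (i in seq_len(nrow(plan))) {
      on <- plan$onset_s[i]; dur <- plan$duration_s[i]; pk <- plan$peak_deg[i]
      idx <- which(t_s >= on & t_s < on + dur)
      if (length(idx) == 0L) next
      # raised cosine: 0 at both endpoints, 1 at mid-movement
      prof <- 0.5 * (1 - cos(2 * pi * (t_s[idx] - on) / dur))
      for (d in plan$dofs[[i]]) {
        angles[d, idx] <- angles[d, idx] + pk * prof
        excursion[d, idx] <- excursion[d, idx] + prof
      }
    }
  }
  if (any(angles < joint_limits[1]) || any(angles > joint_limits[2])) {
    stop("movement plan drives angles outside the declared joint limits",
         call. = FALSE)
  }

  # Envelope gains drawn once per (channel, DOF). Electrodes sit over
  # distinct muscles, so each channel is dominated by one DOF (round-robin
  # assignment) with weak crosstalk from the others; this muscle-selective
  # mixture keeps the observation map well-conditioned, as in real arrays.
  gains <- 0.15 * abs(matrix(stats::rnorm(n_channels * n_dofs),
                             n_channels, n_dofs))
  pref <- ((seq_len(n_channels) - 1L) %% n_dofs) + 1L
  gains[cbind(seq_len(n_channels), pref)] <-
    0.7 + 0.3 * stats::runif(n_channels)
  baseline <- 0.05
  envelope <- baseline + gains %*% excursion

  carrier <- matrix(stats::rnorm(n_channels * n_samples), n_channels, n_samples)
  sensor <- matrix(stats::rnorm(n_channels * n_samples), n_channels, n_samples)
  # band-limit the carrier to the sEMG band before modulating
  bf <- signal::butter(4, c(10, 450) / (fs / 2), type = "pass")
  for (ch in seq_len(n_channels)) {
    carrier[ch, ] <- signal::filter(bf, carrier[ch, ])
  }
  emg <- carrier * envelope + noise_scale * baseline * sensor

  structure(
    list(
      emg = emg_signal(emg, fs),
      angles = angle_signal(angles, fs, default_dof_names(n_dofs)),
      truth = list(plan = plan, gains = gains, rest_deg = rest,
                   envelope_baseline = baseline, noise_scale = noise_scale,
                   joint_limits = joint_limits, seed = as.integer(seed))
    ),
    class = "synthetic_session")
}

# Reject plans where two events drive the same DOF at the same time.
.check_plan <- function(plan, n_dofs, duration_s) {
  if (!inherits(plan, "movement_plan")) {
    stop("plan must be a movement_plan", call. = FALSE)
  }
  if (nrow(plan) == 0L) return(invisible(TRUE))
  all_dofs <- unlist(plan$dofs)
  if (any(all_dofs < 1L | all_dofs > n_dofs)) {
    stop("movement plan references a DOF outside 1..n_dofs", call. = FALSE)
  }
  if (any(plan$onset_s < 0) || any(plan$onset_s + plan$duration_s > duration_s)) {
    stop("movement intervals must lie within [0, duration_s]", call. = FALSE)
  }
  for (d in seq_len(n_dofs)) {
    rows <- which(vapply(plan$dofs, function(s) d %in% s, logical(1)))
    if (length(rows) < 2L) next
    o <- plan$onset_s[rows]; e <- o + plan$duration_s[rows]
    ord <- order(o)
    if (any(e[ord][-length(ord)] > o[ord][-1] + 1e-12)) {
      stop(sprintf("movement plan has overlapping events for DOF %d", d),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %d EMG channels, %d DOFs, %.1f s @ %g Hz, %d movement events\n",
              nrow(x$emg$data), nrow(x$angles$data),
              ncol(x$emg$data) / x$emg$fs, x$emg$fs, nrow(x$truth$plan)))
  invisible(x)
}
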