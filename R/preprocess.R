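#' Sliding-window configuration
#'
#' Defaults follow standard practice for sEMG decoding at 2 kHz: a 150 ms
#' analysis window (300 samples) advanced in 25 ms steps (50 samples). The
#' overlap between the EMG window and the angle sampled at its trailing edge
#' absorbs the electromechanical delay (EMG leads movement by 30-150 ms)
#' without any explicit lag shift.
#'
#' @param window_ms window length in milliseconds (default 150).
#' @param step_ms step length in milliseconds (default 25).
#' @param fs sampling rate in samples/s (default 2000).
#'
#' @return An object of class `windowing_config` with integer sample counts
#'   `window_samples` and `step_samples`.
#' @export
windowing_config <- function(window_ms = 150, step_ms = 25, fs = 2000) {
  ws <- window_ms * fs / 1000
  ss <- step_ms * fs / 1000
  if (abs(ws - round(ws)) > 1e-9 || abs(ss - round(ss)) > 1e-9) {
    stop("window_ms and step_ms must convert to whole sample counts at fs",
         call. = FALSE)
  }
  ws <- as.integer(round(ws)); ss <- as.integer(round(ss))
  if (ws < 1L || ss < 1L) stop("window and step must be at least one sample", call. = FALSE)
  if (ss > ws) stop("step must not exceed the window length", call. = FALSE)
  structure(list(window_ms = window_ms, step_ms = step_ms, fs = fs,
                 window_samples = ws, step_samples = ss),
            class = "windowing_config")
}

#' Butterworth bandpass filter for sEMG
#'
#' Filters each channel independently with a Butterworth bandpass (default
#' 10-450 Hz, order 4). By default the filter is applied forward-backward
#' (zero phase) as is standard for offline analysis; set `zero_phase = FALSE`
#' for a causal forward-only pass matching a streaming implementation.
#'
#' @param x an [emg_signal()].
#' @param low_hz lower cutoff (Hz, default 10).
#' @param high_hz upper cutoff (Hz, default 450).
#' @param order filter order (default 4).
#' @param zero_phase logical; forward-backward filtering (default TRUE).
#'
#' @return An [emg_signal()] of identical dimensions.
#' @export
bandpass_filter <- function(x, low_hz = 10, high_hz = 450, order = 4L,
                            zero_phase = TRUE) {
  stopifnot(inherits(x, "emg_signal"))
  nyq <- x$fs / 2
  if (low_hz <= 0 || low_hz >= high_hz) {
    stop("require 0 < low_hz < high_hz", call. = FALSE)
  }
  if (high_hz >= nyq) {
    stop(sprintf("upper cutoff %g Hz is at or above the Nyquist frequency %g Hz",
                 high_hz, nyq), call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- x$data
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- if (zero_phase) {
      signal::filtfilt(bf, x$data[ch, ])
    } else {
      signal::filter(bf, x$data[ch, ])
    }
  }
  emg_signal(out, x$fs, x$channel_names)
}

#' Enumerate sliding-window boundaries
#'
#' Windows are half-open 0-based sample intervals `[start, end)`: under the
#' defaults `[0, 300)`, `[50, 350)`, ... Every window has exactly
#' `window_samples` samples; an incomplete tail is dropped, never padded.
#'
#' @param n_samples total number of samples available.
#' @param config a [windowing_config()].
#'
#' @return Integer matrix with columns `start` and `end` (0-based, half-open),
#'   one row per window; `floor((n_samples - window)/step) + 1` rows.
#' @export
segment_windows <- function(n_samples, config = windowing_config()) {
  stopifnot(inherits(config, "windowing_config"))
  n_samples <- .stopifnot_scalar_int(n_samples, "n_samples", lower = 0L)
  ws <- config$window_samples; ss <- config$step_samples
  if (n_samples < ws) {
    stop(sprintf("signal has %d samples but the window needs %d", n_samples, ws),
         call. = FALSE)
  }
  starts <- seq.int(0L, n_samples - ws, by = ss)
  cbind(start = starts, end = starts + ws)
}

#' Mean absolute value of a signal window
#'
#' The standard sEMG amplitude feature: the mean of the absolute sample
#' values within the window.
#'
#' @param window nonempty numeric vector.
#' @return Nonnegative scalar.
#' @export
mav <- function(window) {
  if (length(window) == 0L) stop("window must be nonempty", call. = FALSE)
  mean(abs(window))
}

#' Extract aligned feature and state matrices from a session
#'
#' Slides the analysis window over the synchronized EMG and angle signals.
#' Column k of `Z` holds the per-channel MAV of window k; column k of `X`
#' holds every DOF's angle at the last sample of window k (sample index
#' `end - 1` in the 0-based half-open convention). These are the observation
#' and state matrices consumed by [train_kalman()].
#'
#' @param emg an [emg_signal()].
#' @param angles an [angle_signal()] synchronized with `emg` (same fs and
#'   sample count).
#' @param config a [windowing_config()].
#'
#' @return An object of class `training_pair`: list with `Z` (n_channels x M),
#'   `X` (n_dofs x M), `M`, `config`, `channel_names`, `dof_names`.
#' @export
extract_training_pair <- function(emg, angles, config = windowing_config()) {
  stopifnot(inherits(emg, "emg_signal"), inherits(angles, "angle_signal"))
  if (emg$fs != angles$fs) {
    stop(sprintf("EMG fs (%g) and angle fs (%g) differ", emg$fs, angles$fs),
         call. = FALSE)
  }
  ns_e <- ncol(emg$data); ns_a <- ncol(angles$data)
  if (ns_e != ns_a) {
    stop(sprintf("EMG has %d samples but angles have %d; signals must be synchronized",
                 ns_e, ns_a), call. = FALSE)
  }
  win <- segment_windows(ns_e, config)
  M <- nrow(win)
  nch <- nrow(emg$data); ndof <- nrow(angles$data)
  Z <- matrix(0, nch, M)
  for (k in seq_len(M)) {
    seg <- emg$data[, (win[k, "start"] + 1L):win[k, "end"], drop = FALSE]
    Z[, k] <- rowMeans(abs(seg))
  }
  X <- angles$data[, win[, "end"], drop = FALSE]  # 1-based index of sample end-1
  structure(list(Z = Z, X = X, M = M, config = config,
                 channel_names = emg$channel_names,
                 dof_names = angles$dof_names),
            class = "training_pair")
}

#' Concatenate training pairs from several sessions
#'
#' Feature extraction is always done per session (windows never straddle a
#' session boundary); this binds the resulting matrices column-wise for
#' joint training.
#'
#' @param ... `training_pair` objects with identical channel/DOF layout.
#' @return A single `training_pair`.
#' @export
bind_training_pairs <- function(...) {
  pairs <- list(...)
  if (length(pairs) == 1L && is.list(pairs[[1]]) && !inherits(pairs[[1]], "training_pair")) {
    pairs <- pairs[[1]]
  }
  stopifnot(length(pairs) >= 1L, all(vapply(pairs, inherits, logical(1), "training_pair")))
  p1 <- pairs[[1]]
  for (p in pairs[-1]) {
    if (nrow(p$Z) != nrow(p1$Z) || nrow(p$X) != nrow(p1$X)) {
      stop("training pairs have inconsistent channel/DOF dimensions", call. = FALSE)
    }
  }
  structure(list(Z = do.call(cbind, lapply(pairs, `[[`, "Z")),
                 X = do.call(cbind, lapply(pairs, `[[`, "X")),
                 M = sum(vapply(pairs, `[[`, integer(1), "M")),
                 config = p1$config,
                 channel_names = p1$channel_names,
                 dof_names = p1$dof_names),
            class = "training_pair")
}

#' @export
print.training_pair <- function(x, ...) {
  cat(sprintf("<training_pair> Z: %d features x %d windows, X: %d DOFs x %d windows (%g ms window / %g ms step)\n",
              nrow(x$Z), x$M, nrow(x$X), x$M, x$config$window_ms, x$config$step_ms))
  invisible(x)
}
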