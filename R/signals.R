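#' Multichannel sEMG signal container
#'
#' @param data n_channels x n_samples numeric matrix of raw sEMG (arbitrary
#'   amplitude units), one row per electrode channel.
#' @param fs sampling rate in samples per second.
#' @param channel_names optional character vector of channel labels.
#'
#' @return An object of class `emg_signal`.
#' @export
emg_signal <- function(data, fs, channel_names = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("EMG data must be numeric", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (is.null(channel_names)) {
    channel_names <- sprintf("emg%02d", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    stop("channel_names length must match the number of channels", call. = FALSE)
  }
  structure(list(data = data, fs = fs, channel_names = channel_names),
            class = "emg_signal")
}

#' Multichannel joint-angle signal container
#'
#' Degrees throughout; row order follows the degree-of-freedom convention
#' thumb flexion/extension, thumb abduction/adduction, then index, middle,
#' ring and little finger flexion/extension.
#'
#' @param data n_dofs x n_samples numeric matrix of joint angles (degrees).
#' @param fs sampling rate in samples per second.
#' @param dof_names optional character vector of DOF labels.
#'
#' @return An object of class `angle_signal`.
#' @export
angle_signal <- function(data, fs, dof_names = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("angle data must be numeric", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (is.null(dof_names)) {
    dof_names <- default_dof_names(nrow(data))
  }
  if (length(dof_names) != nrow(data)) {
    stop("dof_names length must match the number of DOFs", call. = FALSE)
  }
  structure(list(data = data, fs = fs, dof_names = dof_names),
            class = "angle_signal")
}

#' Default degree-of-freedom labels
#'
#' @param n number of DOFs.
#' @return Character vector of labels; the first six follow the standard
#'   finger-joint order.
#' @export
default_dof_names <- function(n) {
  base <- c("thumb_flex", "thumb_abd", "index_flex",
            "middle_flex", "ring_flex", "little_flex")
  if (n <= length(base)) base[seq_len(n)] else c(base, sprintf("dof%02d", seq.int(7L, n)))
}

#' @export
print.emg_signal <- function(x, ...) {
  cat(sprintf("<emg_signal> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
print.angle_signal <- function(x, ...) {
  cat(sprintf("<angle_signal> %d DOFs x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}
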