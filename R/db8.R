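# Loader for Ninapro DB8 recordings (16-channel sEMG + 18-sensor Cyberglove
# kinematics). The recordings ship as MATLAB containers; this package reads
# them after conversion to its plain-text session dialect (one numeric table
# per signal plus a JSON sidecar) — a converter script is provided in
# inst/scripts/db8_mat_to_text.py for users who have downloaded the data.
# Everything else in the package works without any download.

#' Default Cyberglove-to-DOF channel map
#'
#' Maps the 18 Cyberglove sensors to the six target finger DOFs (thumb
#' flexion, thumb abduction, index, middle, ring, little flexion). Glove
#' channel conventions vary across dataset releases, so the map is data, not
#' code: it ships as `inst/extdata/db8_dof_map.json` and any edited copy can
#' be passed to [load_db8()].
#'
#' @return Named integer vector: DOF name -> glove channel index (1-based).
#' @export
db8_default_dof_map <- function() {
  path <- system.file("extdata", "db8_dof_map.json", package = "emgkalman")
  map <- jsonlite::read_json(path, simplifyVector = TRUE)
  unlist(map$dof_map)
}

#' Load a DB8 recording from the text dialect
#'
#' Reads a recording directory holding `emg.tsv` (channels x samples),
#' `glove.tsv` (18 glove channels x samples) and `record.json` (fs, subject,
#' dataset), reduces the glove channels to the six target DOFs through the
#' channel map, and resamples both streams to 2 kHz when needed (polyphase
#' resampling for the broadband EMG, linear interpolation for the smooth
#' angles).
#'
#' @param dir recording directory in the text dialect.
#' @param dof_map named integer vector mapping DOF names to glove channels;
#'   defaults to [db8_default_dof_map()].
#' @param target_fs output sampling rate (default 2000).
#'
#' @return List with `emg` ([emg_signal()]), `angles` ([angle_signal()]),
#'   `subject_id`, `dataset_index`, `source`.
#' @export
load_db8 <- function(dir, dof_map = db8_default_dof_map(), target_fs = 2000) {
  meta_path <- file.path(dir, "record.json")
  if (!file.exists(meta_path)) {
    stop(sprintf("no record.json in %s (convert the MATLAB container with inst/scripts/db8_mat_to_text.py first)",
                 dir), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (v in c("fs", "subject_id", "dataset_index")) {
    if (is.null(meta[[v]])) stop(sprintf("record.json is missing '%s'", v), call. = FALSE)
  }
  emg <- .read_exact_tsv(file.path(dir, "emg.tsv"))
  glove <- .read_exact_tsv(file.path(dir, "glove.tsv"))
  if (nrow(emg) != 16L) {
    stop(sprintf("expected 16 EMG channels, found %d", nrow(emg)), call. = FALSE)
  }
  if (nrow(glove) != 18L) {
    stop(sprintf("expected 18 glove channels, found %d", nrow(glove)), call. = FALSE)
  }
  if (ncol(emg) != ncol(glove)) {
    stop(sprintf("EMG (%d samples) and glove (%d samples) are not synchronized",
                 ncol(emg), ncol(glove)), call. = FALSE)
  }
  if (any(dof_map < 1L | dof_map > 18L)) {
    stop("dof_map indices must lie in 1..18", call. = FALSE)
  }
  angles <- glove[dof_map, , drop = FALSE]
  fs <- meta$fs
  if (fs != target_fs) {
    p <- target_fs; q <- fs
    g <- .gcd(p, q); p <- p / g; q <- q / g
    n_out <- ceiling(ncol(emg) * p / q)
    emg2 <- matrix(0, nrow(emg), n_out)
    for (ch in seq_len(nrow(emg))) {
      r <- signal::resample(emg[ch, ], p = p, q = q)
      emg2[ch, ] <- r[seq_len(n_out)]
    }
    t_in <- (seq_len(ncol(angles)) - 1) / fs
    t_out <- (seq_len(n_out) - 1) / target_fs
    ang2 <- t(apply(angles, 1L, function(a) {
      stats::approx(t_in, a, xout = t_out, rule = 2)$y
    }))
    emg <- emg2; angles <- ang2; fs <- target_fs
  }
  list(emg = emg_signal(emg, fs),
       angles = angle_signal(angles, fs, names(dof_map)),
       subject_id = as.integer(meta$subject_id),
       dataset_index = as.integer(meta$dataset_index),
       source = meta$source %||% dir)
}

#' Write a recording in the DB8 text dialect
#'
#' Companion writer for [load_db8()]; used for round-trip testing and for
#' building recordings from other sources.
#'
#' @param emg 16 x n_samples matrix.
#' @param glove 18 x n_samples matrix.
#' @param fs sampling rate.
#' @param subject_id subject number (1-12 in the source database).
#' @param dataset_index dataset number (1-3).
#' @param dir output directory.
#' @param source provenance string.
#' @return `dir`, invisibly.
#' @export
write_db8_text <- function(emg, glove, fs, subject_id, dataset_index, dir,
                           source = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_exact_tsv(as.matrix(emg), file.path(dir, "emg.tsv"))
  .write_exact_tsv(as.matrix(glove), file.path(dir, "glove.tsv"))
  jsonlite::write_json(list(fs = fs, subject_id = subject_id,
                            dataset_index = dataset_index, source = source),
                       file.path(dir, "record.json"), auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(dir)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

# Lossless numeric text: 17 significant digits uniquely identify a double,
# and R's own parser (scan) is correctly rounded, so write + read is
# bit-exact. Used for the recording dialect, where exact round trips are
# part of the contract.
.write_exact_tsv <- function(x, path) {
  fmt <- matrix(sprintf("%.17g", x), nrow(x))
  writeLines(apply(fmt, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

.read_exact_tsv <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  vals <- scan(path, what = double(), sep = "\t", quiet = TRUE)
  matrix(vals, ncol = length(first), byrow = TRUE)
}
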