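# Declarative pipeline configuration shared by the CLI subcommands.

.config_defaults <- function() {
  list(
    window_ms = 150, step_ms = 25,
    low_hz = 10, high_hz = 450, filter_order = 4, zero_phase = TRUE,
    center = TRUE, ridge = 1e-8,
    seed = 1L,
    n_channels = 16L, n_dofs = 6L, duration_s = 60, fs = 2000,
    noise_scale = 0.05,
    session_dirs = NULL, model_path = NULL, trace_path = NULL,
    report_path = NULL, out_dir = NULL
  )
}

#' Read and validate a pipeline configuration
#'
#' JSON configuration for the command-line pipeline. Unknown keys are
#' rejected rather than silently ignored, so misspelled options fail loudly.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return Named list of resolved options.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- .config_defaults()
  user <- if (!is.null(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    list()
  }
  for (src in list(user, overrides)) {
    bad <- setdiff(names(src), names(cfg))
    if (length(bad)) {
      stop(sprintf("unknown configuration key(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    for (k in names(src)) if (!is.null(src[[k]])) cfg[[k]] <- src[[k]]
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Write a run manifest
#'
#' Records the resolved configuration, its hash, the package version and a
#' timestamp next to a pipeline artifact, so every output is traceable to
#' the exact parameters that produced it.
#'
#' @param config resolved configuration list.
#' @param path manifest output path (JSON).
#' @param extra optional named list of additional fields (input paths, wall
#'   times, ...).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, extra = list()) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = I(17))
  manifest <- c(list(config = config,
                     config_md5 = unname(tools::md5sum(tmp)),
                     package_version = as.character(utils::packageVersion("emgkalman")),
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Preprocess a session into a training pair under a configuration
#'
#' Convenience wrapper used by the CLI and scripts: bandpass-filters the EMG
#' and extracts the aligned MAV/angle matrices.
#'
#' @param session list with `emg` and `angles` (from [generate_session()],
#'   [read_session()] or [load_db8()]).
#' @param config resolved configuration (see [read_pipeline_config()]).
#' @return A `training_pair`.
#' @export
preprocess_session <- function(session, config = read_pipeline_config()) {
  emg <- bandpass_filter(session$emg, low_hz = config$low_hz,
                         high_hz = config$high_hz,
                         order = config$filter_order,
                         zero_phase = isTRUE(config$zero_phase))
  wc <- windowing_config(config$window_ms, config$step_ms, session$emg$fs)
  extract_training_pair(emg, session$angles, wc)
}
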