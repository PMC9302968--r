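#' Write / read an EEG recording as CSV with a JSON sidecar
#'
#' The sample matrix goes to `<path>.csv` (one column per channel, uV) and
#' the metadata (sampling rate, neighbor map, session layout) to
#' `<path>.json`.  Reading refuses a sampling-rate override rather than
#' silently resampling.
#'
#' @param recording An [eeg_recording()].
#' @param path Base path (without extension).
#' @return `write_eeg` returns `path` invisibly; `read_eeg` returns the
#'   [eeg_recording()].
#' @export
write_eeg <- function(recording, path) {
  utils::write.csv(as.data.frame(recording$data),
                   paste0(path, ".csv"), row.names = FALSE)
  meta <- list(fs = recording$fs, channels = recording$channels,
               neighbors = recording$neighbors,
               session = unclass(recording$session))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_eeg
#' @param expected_fs Optional sampling-rate check; a mismatch is an error,
#'   never a resample.
#' @export
read_eeg <- function(path, expected_fs = NULL) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!is.null(expected_fs) && meta$fs != expected_fs) {
    stop("sampling-rate mismatch: file has ", meta$fs, " Hz, expected ",
         expected_fs, " Hz (resampling refused)", call. = FALSE)
  }
  dat <- as.matrix(utils::read.csv(paste0(path, ".csv"),
                                   check.names = FALSE))
  ses <- meta$session
  spec <- session_spec(ses$kind, ses$n_trials, ses$rest, ses$ready, ses$mi,
                       ses$iti, ses$trigger_window, ses$fallback_window,
                       ses$pulse_split)
  eeg_recording(dat, meta$fs, meta$channels,
                lapply(meta$neighbors, as.character), spec)
}

#' Write / read trigger events as CSV
#'
#' Columns: trial, triggered, t_event_s (from MI onset), pulse_kind,
#' isi_ms, erd_contra_pct, erd_ipsi_pct.
#'
#' @param events Event data frame from [run_session()].
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a calibration profile as JSON
#'
#' Persists the per-hemisphere target bands, the rest/MI percentile tables
#' (0.5-percentile resolution), the feedback axis range and origin.
#'
#' @param profile A `calibration_profile`.
#' @param path JSON path.
#' @export
write_profile <- function(profile, path) {
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (hemi in names(p$erd_dist_rest)) {
    names(p$erd_dist_rest[[hemi]]) <- paste0(seq(0, 100, 0.5), "%")
    names(p$erd_dist_mi[[hemi]]) <- paste0(seq(0, 100, 0.5), "%")
  }
  structure(p, class = "calibration_profile")
}

#' Read / write a run configuration (YAML)
#'
#' A run configuration names the sessions (REST and NoFB first, the three
#' feedback sessions in seeded-random order), the per-stage seeds, the
#' simulation parameters, and QC thresholds.  `load -> save -> load`
#' round-trips identically.
#'
#' @param path YAML path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$seed))
  cfg
}

#' @rdname read_run_config
#' @param config Configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Default run configuration
#'
#' @param seed Master seed; every stochastic stage gets an explicit seed
#'   derived from it.
#' @return Configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  fb <- with_seed(derive_seed(seed, "session-order"),
                  sample(c("HIGH", "MID", "LOW")))
  list(
    seed = as.integer(seed),
    sessions = c("REST", "NoFB", fb),
    seeds = list(
      eeg = derive_seed(seed, "eeg"),
      calibration = derive_seed(seed, "calibration"),
      session = derive_seed(seed, "session"),
      mep = derive_seed(seed, "mep"),
      surrogates = derive_seed(seed, "surrogates")
    ),
    sim = list(mu_freq = 10, erd_contra = 30, erd_ipsi = 30, erd_sd = 10),
    n_trials = 40L, calibration_trials = 20L,
    qc = list(mvc_threshold = 0.05, outlier_sd = 3, reject_uv = 100),
    surrogates = 200L, alpha = 0.05
  )
}
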