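#' MVC as the RMS of the most stable 3 s of EMG
#'
#' Slides a 3 s window over the (at least 5 s) maximal-voluntary-contraction
#' trace, scores each position by the variance of its 250-ms chunk RMS
#' values, and returns the RMS of the most stable (minimum-variance)
#' window — so transient bursts are excluded from the reference.
#'
#' @param emg Numeric EMG trace, mV.
#' @param fs Sampling rate, Hz.
#' @param stable_window Window length in seconds (default 3).
#' @param step Search step in seconds (default 0.1).
#' @return RMS of the stable window, mV.
#' @export
mvc_rms <- function(emg, fs, stable_window = 3, step = 0.1) {
  n_win <- round(stable_window * fs)
  if (length(emg) < max(n_win, round(5 * fs))) {
    stop("MVC trace must cover at least 5 s", call. = FALSE)
  }
  starts <- seq(1L, length(emg) - n_win + 1L, by = max(1L, round(step * fs)))
  n_chunk <- round(0.25 * fs)
  score <- vapply(starts, function(s) {
    w <- emg[s:(s + n_win - 1L)]
    chunks <- split(w, ceiling(seq_along(w) / n_chunk))
    stats::var(vapply(chunks, function(c) sqrt(mean(c^2)), numeric(1)))
  }, numeric(1))
  s <- starts[which.min(score)]
  sqrt(mean(emg[s:(s + n_win - 1L)]^2))
}

#' Causal sliding RMS of filtered EMG
#'
#' Band-passes (5-1000 Hz, second order) and notches (50 Hz) the EMG
#' causally, then returns the RMS over the trailing window at every sample.
#' Samples before one full window are flagged as warm-up.
#'
#' @param emg Numeric EMG trace, mV.
#' @param fs Sampling rate, Hz.
#' @param window Window length in seconds (default 1).
#' @param filter Apply the 5-1000 Hz band-pass + 50 Hz notch first?
#' @return Data frame with `rms` and logical `warmup`.
#' @export
emg_rms_monitor <- function(emg, fs, window = 1, filter = TRUE) {
  if (filter) {
    bp <- signal::butter(2, c(5, min(1000, fs / 2 * 0.99)) / (fs / 2), "pass")
    bs <- signal::butter(2, c(48, 52) / (fs / 2), "stop")
    emg <- as.numeric(signal::filter(bs, as.numeric(signal::filter(bp, emg))))
  }
  n <- round(window * fs)
  ms <- stats::filter(emg^2, rep(1 / n, n), sides = 1)
  csum <- cumsum(emg^2)
  warm <- seq_along(emg) < n
  ms[warm] <- csum[warm] / seq_len(sum(warm))   # partial-window RMS in warm-up
  data.frame(rms = sqrt(as.numeric(ms)), warmup = warm)
}

#' Peak-to-peak MEP amplitude in the 20-45 ms post-pulse window
#'
#' @param trace Numeric EMG trace, mV.
#' @param fs Sampling rate, Hz.
#' @param pulse_index Sample index of the TMS pulse.
#' @param window Post-pulse search window in seconds (default
#'   `c(0.020, 0.045)`).
#' @return Peak-to-peak amplitude, mV. Deflections outside the window are
#'   ignored.
#' @export
peak_to_peak <- function(trace, fs, pulse_index,
                         window = c(0.020, 0.045)) {
  idx <- (pulse_index + round(window[1] * fs)):(pulse_index + round(window[2] * fs))
  idx <- idx[idx >= 1L & idx <= length(trace)]
  if (length(idx) == 0L) stop("search window outside the trace", call. = FALSE)
  max(trace[idx]) - min(trace[idx])
}

#' Quality-control flags for one MEP trial
#'
#' Three rejection rules: (1) coil shift (metadata flag, > 3 mm and/or
#' > 3 degrees); (2) pre-innervation — RMS of the 250 ms before the pulse
#' above 5% of MVC; (3) amplitude outlier — outside mean +/- 3 SD of its
#' session x pulse-kind stratum.  Any flag excludes the trial from the
#' session means.
#'
#' @param amplitude Peak-to-peak amplitude of the trial, mV.
#' @param pre_rms RMS of the 250 ms pre-pulse EMG, mV.
#' @param mvc MVC reference RMS, mV (> 0).
#' @param stratum_amplitudes Amplitudes of all trials in the same
#'   session x pulse-kind stratum (including this one), for the outlier rule.
#' @param coil_shift Metadata: was the coil displaced beyond tolerance?
#' @param mvc_threshold Pre-innervation threshold as a fraction of MVC
#'   (default 0.05).
#' @return A list of logical flags `pre_innervation`, `outlier`,
#'   `coil_shift`, and `rejected` (their union).
#' @export
qc_trial <- function(amplitude, pre_rms, mvc, stratum_amplitudes,
                     coil_shift = FALSE, mvc_threshold = 0.05) {
  stopifnot(mvc > 0)
  pre <- pre_rms > mvc_threshold * mvc
  if (length(stratum_amplitudes) < 2L) {
    warning("empty or singleton stratum: outlier rule skipped")
    out <- FALSE
  } else {
    m <- mean(stratum_amplitudes)
    s <- stats::sd(stratum_amplitudes)
    out <- s > 0 && abs(amplitude - m) > 3 * s
  }
  list(pre_innervation = pre, outlier = out, coil_shift = coil_shift,
       rejected = pre || out || coil_shift)
}

#' Apply QC to a table of MEP trials
#'
#' Vectorized [qc_trial()] over a data frame, with the +/- 3 SD outlier rule
#' evaluated within each session x pulse-kind stratum (one pass, no
#' re-iteration after removal).
#'
#' @param trials Data frame with columns `amplitude`, `pre_rms`,
#'   `pulse_kind`, `session`, and optionally `coil_shift`.
#' @param mvc MVC reference RMS, mV.
#' @param mvc_threshold Pre-innervation threshold fraction (default 0.05).
#' @return `trials` with added logical columns `qc_pre_innervation`,
#'   `qc_outlier`, `qc_coil_shift`, `qc_rejected`.
#' @export
qc_trials <- function(trials, mvc, mvc_threshold = 0.05) {
  if (is.null(trials$coil_shift)) trials$coil_shift <- FALSE
  trials$qc_pre_innervation <- trials$pre_rms > mvc_threshold * mvc
  trials$qc_outlier <- FALSE
  for (str in split(seq_len(nrow(trials)),
                    interaction(trials$session, trials$pulse_kind,
                                drop = TRUE))) {
    a <- trials$amplitude[str]
    if (length(a) >= 2L && stats::sd(a) > 0) {
      trials$qc_outlier[str] <- abs(a - mean(a)) > 3 * stats::sd(a)
    }
  }
  trials$qc_coil_shift <- trials$coil_shift
  trials$qc_rejected <- trials$qc_pre_innervation | trials$qc_outlier |
    trials$qc_coil_shift
  trials
}

#' Interhemispheric inhibition from conditioned and unconditioned MEPs
#'
#' `IHI = mean(conditioned) / mean(unconditioned) * 100` — the ratio of
#' means, not the mean of ratios.  Smaller values mean stronger inhibition.
#'
#' @param conditioned,unconditioned Numeric vectors of QC-accepted
#'   peak-to-peak amplitudes, mV.
#' @param session Optional session label carried into the result.
#' @return An object of class `ihi_result`: `session`, `mean_conditioned`,
#'   `mean_unconditioned`, `ihi` (percent), `n_conditioned`,
#'   `n_unconditioned`.
#' @export
compute_ihi <- function(conditioned, unconditioned, session = NA_character_) {
  if (length(conditioned) == 0L || length(unconditioned) == 0L) {
    stop("undefined-IHI: both pulse kinds need accepted trials",
         call. = FALSE)
  }
  mc <- mean(conditioned)
  mu <- mean(unconditioned)
  structure(
    list(session = session, mean_conditioned = mc, mean_unconditioned = mu,
         ihi = mc / mu * 100,
         n_conditioned = length(conditioned),
         n_unconditioned = length(unconditioned)),
    class = "ihi_result"
  )
}

#' @export
print.ihi_result <- function(x, ...) {
  cat(sprintf("<ihi_result> %s: IHI = %.1f%% (%d cond / %d uncond trials)\n",
              x$session, x$ihi, x$n_conditioned, x$n_unconditioned))
  invisible(x)
}

#' IHI curve over conditioning-stimulus intensities
#'
#' Mean conditioned amplitude per CS intensity, normalized to the mean
#' TS-only amplitude (intensity 0); the normalized value at 0 is 100% by
#' construction.  Monotonicity is not enforced.
#'
#' @param trials Data frame with `cs_intensity` (percent RMT; 0 = TS-only)
#'   and `amplitude` (mV).
#' @param intensities Intensity levels expected on the curve (default
#'   `c(0, 100, 110, 120, 130, 140)`).
#' @return An object of class `ihi_curve`: data frame with `cs_intensity`,
#'   `n`, `mean_amplitude`, `normalized_pct`, plus a `gaps` attribute naming
#'   missing levels.
#' @export
ihi_curve <- function(trials, intensities = c(0, 100, 110, 120, 130, 140)) {
  if (!any(trials$cs_intensity == 0)) {
    stop("TS-only group (cs_intensity = 0) required", call. = FALSE)
  }
  ts_mean <- mean(trials$amplitude[trials$cs_intensity == 0])
  rows <- lapply(intensities, function(ii) {
    a <- trials$amplitude[trials$cs_intensity == ii]
    data.frame(cs_intensity = ii, n = length(a),
               mean_amplitude = if (length(a)) mean(a) else NA_real_,
               normalized_pct = if (length(a)) mean(a) / ts_mean * 100
                                else NA_real_)
  })
  curve <- do.call(rbind, rows)
  gaps <- curve$cs_intensity[curve$n == 0L]
  if (length(gaps)) warning("missing CS intensity levels: ",
                            paste(gaps, collapse = ", "))
  structure(curve, gaps = gaps, class = c("ihi_curve", "data.frame"))
}

#' IHI manipulation range between the HIGH and LOW sessions
#'
#' Signed percentage change `(ihi_low - ihi_high) / ihi_low * 100`
#' (positive when inhibition is stronger — smaller IHI — in HIGH), plus its
#' magnitude.
#'
#' @param ihi_high,ihi_low Session IHI values, percent.
#' @return List with `signed` and `magnitude` (percent).
#' @export
manipulation_range <- function(ihi_high, ihi_low) {
  if (ihi_low == 0) stop("ihi_low must be nonzero", call. = FALSE)
  signed <- (ihi_low - ihi_high) / ihi_low * 100
  list(signed = signed, magnitude = abs(signed))
}

#' Normalize session IHI values to the NoFB baseline
#'
#' Percentage change of each session's IHI relative to baseline:
#' `(ihi - baseline) / baseline * 100`.
#'
#' @param ihi_by_session Named numeric vector of session IHI values.
#' @param baseline Name of the baseline session (default `"NoFB"`).
#' @return Named numeric vector of percent changes.
#' @export
normalize_to_baseline <- function(ihi_by_session, baseline = "NoFB") {
  b <- unname(ihi_by_session[baseline])
  if (length(b) != 1L || is.na(b) || b == 0) {
    stop("baseline session missing or zero", call. = FALSE)
  }
  (ihi_by_session - b) / b * 100
}
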