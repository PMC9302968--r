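#' Causal online preprocessing: band-pass and notch
#'
#' Applies, causally (forward-only, no future samples), a 1-70 Hz
#' second-order Butterworth band-pass followed by a 50 Hz notch
#' (second-order band-stop, 48-52 Hz) to each channel.  Because the filters
#' are causal and start from zero state, the output for any prefix of the
#' data equals the prefix of the output for the full data — the property
#' that lets the offline tests stand in for the streaming path.
#'
#' @param x Numeric vector or samples x channels matrix, uV.
#' @param fs Sampling rate, Hz.
#' @param bandpass Passband edges, Hz (default `c(1, 70)`).
#' @param notch Notch center, Hz (default 50; half-width 2 Hz).
#' @return Filtered data, same shape as `x`.
#' @export
preprocess_online <- function(x, fs, bandpass = c(1, 70), notch = 50) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  if (nrow(xm) < fs) {
    stop("insufficient-data: need at least 1 s of samples for filter warm-up",
         call. = FALSE)
  }
  bp <- signal::butter(2, bandpass / (fs / 2), type = "pass")
  bs <- signal::butter(2, c(notch - 2, notch + 2) / (fs / 2), type = "stop")
  out <- apply(xm, 2, function(col) {
    as.numeric(signal::filter(bs, as.numeric(signal::filter(bp, col))))
  })
  out <- matrix(out, nrow = nrow(xm), dimnames = dimnames(xm))
  if (vec) drop(out) else out
}

#' Large Laplacian spatial filter
#'
#' Center channel minus the mean of its six surrounding channels,
#' sample-wise.  Rejects any signal common to all seven channels.
#'
#' @param x Samples x channels matrix with named columns.
#' @param center Name of the center channel (e.g. `"C3"`).
#' @param neighbors Character vector of exactly six neighbor names.
#' @return Numeric vector, one sample per row of `x`.
#' @export
large_laplacian <- function(x, center, neighbors) {
  if (length(neighbors) != 6L) {
    stop("montage error: large Laplacian needs exactly 6 neighbors",
         call. = FALSE)
  }
  missing <- setdiff(c(center, neighbors), colnames(x))
  if (length(missing) > 0L) {
    stop("montage error: missing channels ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x[, center] - rowMeans(x[, neighbors, drop = FALSE])
}

# One-sided power spectrum of exactly 1 s of signal at 1 Hz resolution.
# Bin k (0-based) holds the power at k Hz: amplitude-A sinusoid -> A^2/2.
power_spectrum_1s <- function(x, fs, fmax = 70) {
  n <- length(x)
  X <- fft(x)
  k <- 0:fmax
  p <- (Mod(X[k + 1]) / n)^2
  p[k > 0] <- 2 * p[k > 0]
  names(p) <- k
  p
}

#' FFT band power of a 1 s window
#'
#' Rectangular-window FFT of exactly one second of signal (1 Hz bins), power
#' as the squared magnitude spectrum, averaged over the inclusive integer-Hz
#' bins of `band`.  Scaled so a unit-amplitude sinusoid carries power 1/2
#' in its bin.
#'
#' @param x Numeric vector of exactly `fs` samples.
#' @param band `c(f_lo, f_hi)` in Hz.
#' @param fs Sampling rate, Hz.
#' @return Band power, uV^2.
#' @export
band_power <- function(x, band, fs) {
  if (length(x) != round(fs)) {
    stop("band_power needs exactly 1 s of signal (", fs, " samples)",
         call. = FALSE)
  }
  if (band[1] < 0 || band[2] > fs / 2) {
    stop("range error: band outside [0, Nyquist]", call. = FALSE)
  }
  bins <- seq(ceiling(band[1]), floor(band[2]))
  p <- power_spectrum_1s(x, fs, fmax = floor(band[2]))
  mean(p[as.character(bins)])
}

#' Time-smooth band power over the last five windows
#'
#' Arithmetic mean of up to the five most recent 100-ms window powers
#' (500 ms of smoothing).  During warm-up, averages however many windows
#' exist rather than stalling, so estimates are available from the first
#' window on.
#'
#' @param history Numeric vector of window powers, oldest first.
#' @return Smoothed power, uV^2.
#' @export
smooth_power <- function(history) {
  if (length(history) == 0L) {
    stop("insufficient-data: empty power history", call. = FALSE)
  }
  mean(utils::tail(history, 5L))
}

#' Event-related desynchronization relative to a resting reference
#'
#' `ERD = (ref_power - power) / ref_power * 100`.  Positive values indicate
#' desynchronization; complete loss of band power gives exactly 100%, and
#' synchronization is unbounded below.
#'
#' @param power Instantaneous band power, uV^2.
#' @param ref_power Resting-epoch reference band power, uV^2 (> 0).
#' @return ERD in percent, in (-Inf, 100].
#' @examples
#' compute_erd(0, 4)    # 100
#' compute_erd(4, 4)    # 0
#' compute_erd(8, 4)    # -100
#' @export
compute_erd <- function(power, ref_power) {
  if (any(ref_power <= 0)) {
    stop("invalid-reference: reference power must be positive", call. = FALSE)
  }
  (ref_power - power) / ref_power * 100
}

#' Select the target alpha band from per-frequency ERD
#'
#' Scans the alpha band with the four 3 Hz-wide candidate bins
#' 8-10, 9-11, 10-12, 11-13 Hz (1 Hz step, i.e. 2 Hz overlap between
#' consecutive bins) and returns the bin with the largest mean ERD; ties go
#' to the lowest-frequency bin.
#'
#' @param erd_by_freq Numeric vector of mean ERD (percent) named by integer
#'   frequency, covering 8..13 Hz.
#' @return `c(f_lo, f_hi)` of the winning bin.
#' @export
select_target_band <- function(erd_by_freq) {
  need <- as.character(8:13)
  if (!all(need %in% names(erd_by_freq))) {
    stop("input error: ERD values for all of 8..13 Hz are required",
         call. = FALSE)
  }
  bins <- lapply(8:11, function(lo) c(lo, lo + 2))
  means <- vapply(bins, function(b) {
    mean(erd_by_freq[as.character(b[1]:b[2])])
  }, numeric(1))
  bins[[which.max(means)]]   # which.max returns the first (lowest) maximum
}

# --- windowed spectra over a recording ------------------------------------

# Per-trial matrices of 1-s window spectra at the 100-ms cadence.
# Window i ends at t = 1.0 + (i-1)*0.1 s from trial start (needs 1 s of
# history, so the first window ends at 1.0 s); rows = windows, cols = 0..fmax Hz.
trial_window_spectra <- function(sig, recording, fmax = 70, step = 0.1) {
  fs <- recording$fs
  session <- recording$session
  tdur <- trial_duration(session)
  ends <- seq(1, tdur, by = step)
  lapply(seq_len(session$n_trials), function(tr) {
    s0 <- trial_start_sample(recording, tr) - 1L
    sp <- t(vapply(ends, function(e) {
      idx <- (s0 + round((e - 1) * fs) + 1L):(s0 + round(e * fs))
      power_spectrum_1s(sig[idx], fs, fmax)
    }, numeric(fmax + 1L)))
    rownames(sp) <- format(ends)
    attr(sp, "t") <- ends
    sp
  })
}

# Running mean of the last <=5 values (matches smooth_power applied online).
running_smooth5 <- function(p) {
  vapply(seq_along(p), function(i) mean(p[max(1L, i - 4L):i]), numeric(1))
}

# Band power trace for one trial's spectra matrix.
spectra_band_power <- function(sp, band) {
  bins <- as.character(seq(ceiling(band[1]), floor(band[2])))
  rowMeans(sp[, bins, drop = FALSE])
}

# ERD trace for one trial: smoothed band power relative to the mean smoothed
# power of the windows lying fully inside the 1-5 s resting epoch.
trial_erd_trace <- function(sp, band, rest_ref_window = c(2, 5),
                            smooth = TRUE) {
  t <- attr(sp, "t")
  p <- spectra_band_power(sp, band)
  if (smooth) p <- running_smooth5(p)
  ref_idx <- t >= rest_ref_window[1] & t <= rest_ref_window[2]
  ref <- mean(p[ref_idx])
  list(t = t, erd = compute_erd(p, ref), power = p, ref = ref)
}

#' Calibrate the online estimator from a calibration recording
#'
#' Runs the full online pipeline over a (nominally 20-trial) calibration
#' recording: selects the per-hemisphere target alpha band by scanning 3 Hz
#' bins for maximal mean ERD during motor imagery, then pools the 100-ms ERD
#' samples of the rest and MI epochs across trials into empirical percentile
#' distributions (0.5-percentile resolution).  The feedback axis range is
#' the [5th, 95th] percentile of the MI distribution and the origin its
#' median, per hemisphere.
#'
#' @param recording An [eeg_recording()] with the 5 s rest / 1 s ready /
#'   6 s MI trial timeline.
#' @param min_trials Hard minimum trial count (error below; warning below
#'   20).
#' @return An object of class `calibration_profile`: per-hemisphere `band`,
#'   percentile tables `erd_dist_rest` / `erd_dist_mi`, `axis_range`,
#'   `origin`.
#' @export
calibrate <- function(recording, min_trials = 5L) {
  n <- recording$session$n_trials
  if (n < min_trials) {
    stop("calibration needs at least ", min_trials, " trials", call. = FALSE)
  }
  if (n < 20L) {
    warning("calibration recording has ", n, " trials (20 recommended)")
  }
  filt <- preprocess_online(recording$data, recording$fs)
  probs <- seq(0, 1, by = 0.005)
  out <- list(bands = list(), erd_dist_rest = list(), erd_dist_mi = list(),
              axis_range = list(), origin = list())
  mi_t <- c(mi_onset(recording$session) + 1, trial_duration(recording$session))
  for (hemi in c("contra", "ipsi")) {
    ctr <- if (hemi == "contra") "C3" else "C4"
    lap <- large_laplacian(filt, ctr, recording$neighbors[[ctr]])
    sp <- trial_window_spectra(lap, recording)
    # per-frequency ERD (1 Hz bins) averaged over MI windows, for band choice
    erd_by_freq <- vapply(8:13, function(f) {
      mean(unlist(lapply(sp, function(m) {
        tr <- trial_erd_trace(m, c(f, f))
        tr$erd[tr$t >= mi_t[1] & tr$t <= mi_t[2]]
      })))
    }, numeric(1))
    names(erd_by_freq) <- 8:13
    band <- select_target_band(erd_by_freq)
    traces <- lapply(sp, trial_erd_trace, band = band)
    pool <- function(win) {
      unlist(lapply(traces, function(tr) tr$erd[tr$t >= win[1] & tr$t <= win[2]]))
    }
    rest_erd <- pool(c(2, 5))
    mi_erd <- pool(mi_t)
    out$bands[[hemi]] <- band
    out$erd_dist_rest[[hemi]] <- stats::quantile(rest_erd, probs, names = TRUE)
    out$erd_dist_mi[[hemi]] <- stats::quantile(mi_erd, probs, names = TRUE)
    out$axis_range[[hemi]] <- unname(stats::quantile(mi_erd, c(0.05, 0.95)))
    out$origin[[hemi]] <- unname(stats::median(mi_erd))
  }
  structure(out, class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat(sprintf(
    "<calibration_profile> bands %d-%d (contra) / %d-%d (ipsi) Hz; origin %.1f / %.1f %%ERD\n",
    x$bands$contra[1], x$bands$contra[2], x$bands$ipsi[1], x$bands$ipsi[2],
    x$origin$contra, x$origin$ipsi))
  invisible(x)
}

#' Percentile of a calibration ERD distribution
#'
#' @param profile A `calibration_profile`.
#' @param hemi `"contra"` or `"ipsi"`.
#' @param p Percentile in [0, 100] (vectorized).
#' @param dist `"mi"` or `"rest"`.
#' @return ERD value(s) in percent.
#' @export
profile_percentile <- function(profile, hemi, p, dist = c("mi", "rest")) {
  dist <- match.arg(dist)
  tab <- if (dist == "mi") profile$erd_dist_mi[[hemi]] else
    profile$erd_dist_rest[[hemi]]
  probs <- seq(0, 100, by = 0.5)
  stats::approx(probs, tab, xout = p, rule = 2)$y
}

#' Run the online ERD estimator over a recording
#'
#' Emits one bilateral ERD sample every 100 ms once one second of history
#' exists (t = 1.0, 1.1, ... s from trial start; a 12 s trial yields 111
#' samples).  Within each trial the reference is the mean smoothed band
#' power over the windows of that trial's 1-5 s resting epoch.  All
#' computations are causal, so streaming and batch execution agree.
#'
#' @param recording An [eeg_recording()].
#' @param profile A `calibration_profile` supplying the per-hemisphere
#'   target bands.
#' @param reference `"per-trial"` (default): each trial's own 1-5 s rest
#'   power; `"pooled"`: the mean rest power across all trials, for
#'   sensitivity analyses of the reference choice.
#' @return Data frame with columns `trial`, `t_s` (from trial start),
#'   `erd_contra_pct`, `erd_ipsi_pct`, `power_contra`, `power_ipsi`.
#' @export
run_realtime <- function(recording, profile,
                         reference = c("per-trial", "pooled")) {
  reference <- match.arg(reference)
  for (hemi in c("contra", "ipsi")) {
    band <- profile$bands[[hemi]]
    if (band[2] > recording$fs / 2) {
      stop("profile band exceeds the recording Nyquist rate", call. = FALSE)
    }
  }
  filt <- preprocess_online(recording$data, recording$fs)
  res <- list()
  for (hemi in c("contra", "ipsi")) {
    ctr <- if (hemi == "contra") "C3" else "C4"
    lap <- large_laplacian(filt, ctr, recording$neighbors[[ctr]])
    sp <- trial_window_spectra(lap, recording)
    traces <- lapply(sp, trial_erd_trace, band = profile$bands[[hemi]])
    if (reference == "pooled") {
      ref <- mean(vapply(traces, `[[`, numeric(1), "ref"))
      traces <- lapply(traces, function(tr) {
        tr$erd <- compute_erd(tr$power, ref)
        tr$ref <- ref
        tr
      })
    }
    res[[hemi]] <- traces
  }
  do.call(rbind, lapply(seq_along(res$contra), function(tr) {
    data.frame(trial = tr,
               t_s = res$contra[[tr]]$t,
               erd_contra_pct = res$contra[[tr]]$erd,
               erd_ipsi_pct = res$ipsi[[tr]]$erd,
               power_contra = res$contra[[tr]]$power,
               power_ipsi = res$ipsi[[tr]]$power)
  }))
}
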