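#' Offline preprocessing: common average reference and channel rejection
#'
#' Re-references every channel to the instantaneous mean across channels
#' (so the channel mean of the output is zero at every sample), then flags,
#' per trial, channels whose re-referenced amplitude exceeds the rejection
#' threshold (default 100 uV).
#'
#' @param recording An [eeg_recording()].
#' @param threshold Rejection threshold, uV (default 100).
#' @return List with `recording` (re-referenced copy), `rejected` (data
#'   frame `trial`, `channel`), and `dropped_trials` (trials with no
#'   surviving channel).
#' @export
offline_preprocess <- function(recording, threshold = 100) {
  x <- recording$data
  if (ncol(x) < 2L) stop("need at least 2 channels", call. = FALSE)
  car <- x - rowMeans(x)
  out <- recording
  out$data <- car
  n_blk <- round(block_duration(recording$session) * recording$fs)
  rej <- list()
  dropped <- integer(0)
  for (tr in seq_len(recording$session$n_trials)) {
    idx <- (trial_start_sample(recording, tr)):(trial_start_sample(recording, tr) + n_blk - 1L)
    idx <- idx[idx <= nrow(car)]
    bad <- colnames(car)[apply(abs(car[idx, , drop = FALSE]) > threshold, 2, any)]
    if (length(bad) == ncol(car)) dropped <- c(dropped, tr)
    if (length(bad)) rej[[length(rej) + 1L]] <- data.frame(trial = tr,
                                                          channel = bad)
  }
  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(trial = integer(0), channel = character(0))
  list(recording = out, rejected = rejected, dropped_trials = dropped)
}

#' Pre-stimulus window of a trial
#'
#' Returns both the full pre-stimulus span (trial start up to the
#' conditioning-stimulus marker) and the final 1 s slice before it; if the
#' stimulus fell less than 1 s into the MI epoch the slice reaches back into
#' the ready epoch and is flagged as padded.
#'
#' @param recording An [eeg_recording()].
#' @param trial Trial index.
#' @param cs_time Stimulus time in seconds from trial start.
#' @return List with `full_idx`, `last1s_idx` (sample indices into the
#'   recording), and logical `padded`.
#' @export
prestimulus_window <- function(recording, trial, cs_time) {
  fs <- recording$fs
  s0 <- trial_start_sample(recording, trial) - 1L
  n_cs <- round(cs_time * fs)
  if (n_cs < 1L) stop("empty pre-stimulus span", call. = FALSE)
  full <- (s0 + 1L):(s0 + n_cs)
  if (n_cs < fs) stop("less than 1 s of pre-stimulus data", call. = FALSE)
  last1 <- (s0 + n_cs - fs + 1L):(s0 + n_cs)
  padded <- (cs_time - 1) < mi_onset(recording$session)
  list(full_idx = full, last1s_idx = last1, padded = padded)
}

#' Segment a signal into overlapping Hanning-tapered windows
#'
#' Windows of `window` seconds starting every `(1 - overlap) * window`
#' seconds, each multiplied by a Hanning taper.  A 4 s epoch at the default
#' 1 s / 90% settings yields 31 segments.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param window Segment length, seconds (default 1).
#' @param overlap Fractional overlap between consecutive segments
#'   (default 0.9).
#' @param taper Apply the Hanning taper (default TRUE).
#' @return Matrix, one segment per row.
#' @export
segment_epoch <- function(x, fs, window = 1, overlap = 0.9, taper = TRUE) {
  n_win <- round(window * fs)
  if (length(x) < n_win) stop("signal shorter than one segment", call. = FALSE)
  step <- round((1 - overlap) * window * fs)
  starts <- seq(1L, length(x) - n_win + 1L, by = step)
  h <- if (taper) signal::hanning(n_win) else rep(1, n_win)
  seg <- t(vapply(starts, function(s) x[s:(s + n_win - 1L)] * h,
                  numeric(n_win)))
  attr(seg, "fs") <- fs
  seg
}

# Band-averaged cross- and auto-spectra over a segment matrix pair.
# Returns the complex coherency C of the band.
band_coherency <- function(xseg, yseg, band, fs) {
  stopifnot(nrow(xseg) == nrow(yseg))
  if (nrow(xseg) < 2L) stop("need at least 2 segments", call. = FALSE)
  n <- ncol(xseg)
  df <- fs / n                       # frequency resolution
  bins <- which((0:(n - 1)) * df >= band[1] & (0:(n - 1)) * df <= band[2])
  X <- t(apply(xseg, 1, fft))
  Y <- t(apply(yseg, 1, fft))
  sxy <- mean(colMeans(X[, bins, drop = FALSE] *
                       Conj(Y[, bins, drop = FALSE])))
  sxx <- mean(colMeans(Mod(X[, bins, drop = FALSE])^2))
  syy <- mean(colMeans(Mod(Y[, bins, drop = FALSE])^2))
  if (sxx <= 0 || syy <= 0) {
    stop("undefined: zero auto-spectrum in band", call. = FALSE)
  }
  sxy / sqrt(sxx * syy)
}

#' Corrected imaginary coherence (ciCOH) of two segmented signals
#'
#' Complex coherency `C(f)` from cross- and auto-spectra averaged over
#' segments and over the band's frequency bins, then
#' `ciCOH = Im(C) / sqrt(1 - Re(C)^2)`, clipped to [-1, 1].  Any
#' zero-lag (instantaneously mixed) pair has purely real coherency and
#' hence ciCOH = 0 — the volume-conduction robustness that motivates the
#' measure.  By default the spectra are band-averaged before the ratio; set
#' `per_bin = TRUE` to average per-bin ciCOH instead.
#'
#' @param xseg,yseg Segment matrices from [segment_epoch()] (equal segment
#'   counts, at least 2).
#' @param band `c(f_lo, f_hi)`, Hz.
#' @param fs Sampling rate, Hz.
#' @param per_bin Average per-bin ciCOH instead of band-averaging spectra
#'   first.
#' @return ciCOH value in [-1, 1].
#' @export
cicoh <- function(xseg, yseg, band, fs = attr(xseg, "fs"), per_bin = FALSE) {
  ci_of <- function(C) {
    den <- sqrt(pmax(1 - Re(C)^2, .Machine$double.eps))
    v <- Im(C) / den
    pmin(1, pmax(-1, v))
  }
  if (!per_bin) {
    ci_of(band_coherency(xseg, yseg, band, fs))
  } else {
    n <- ncol(xseg)
    df <- fs / n
    freqs <- (0:(n - 1)) * df
    bins <- freqs[freqs >= band[1] & freqs <= band[2]]
    mean(vapply(bins, function(f) {
      ci_of(band_coherency(xseg, yseg, c(f, f), fs))
    }, numeric(1)))
  }
}

# Phase-randomized surrogate preserving the amplitude spectrum.
phase_randomize <- function(x) {
  n <- length(x)
  X <- fft(x)
  half <- seq(2L, ceiling(n / 2))
  ph <- stats::runif(length(half), 0, 2 * pi)
  X[half] <- Mod(X[half]) * exp(1i * ph)
  X[n - half + 2L] <- Conj(X[half])
  if (n %% 2 == 0) X[n / 2 + 1] <- Mod(X[n / 2 + 1])
  Re(fft(X, inverse = TRUE)) / n
}

# Circular-shift surrogate: rotate the continuous signal by a random
# offset of at least one window.  Preserves the signal's spectrum and its
# full autocorrelation (hence the dependence between overlapping segments,
# which the null distribution must share with the observed estimator) while
# destroying its temporal alignment with the partner signal.
circular_shift_surrogate <- function(y, fs, window = 1) {
  n <- length(y)
  lo <- round(window * fs)
  off <- sample.int(max(1L, n - 2L * lo), 1L) + lo
  y[((seq_len(n) - 1L + off) %% n) + 1L]
}

#' Surrogate-based significance of a ciCOH value
#'
#' Compares the observed |ciCOH| of a channel pair against the null
#' distribution obtained by circularly time-shifting the second signal by a
#' random offset (at least one window) and re-segmenting.  The shift
#' preserves the signal's spectrum and autocorrelation — including the
#' dependence between overlapping segments, which the null must share with
#' the observed estimator — while destroying its alignment with the
#' partner.  Significant iff the observed value exceeds the (1 - alpha)
#' quantile of the null.  Note the null is degenerate for strictly
#' periodic, noiseless signals (any shift of a pure sinusoid stays
#' coherent); physiological signals have finite coherence times.
#'
#' @param x,y Continuous signals (same length), uV.
#' @param fs Sampling rate, Hz.
#' @param band `c(f_lo, f_hi)`, Hz.
#' @param window,overlap Segmentation settings (default 1 s, 90%).
#' @param n_surrogates Number of surrogates (>= 100; default 200).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed for the phase draws.
#' @return List with `cicoh`, `significant`, `threshold`, and `null` (the
#'   surrogate |ciCOH| values).
#' @export
cicoh_significance <- function(x, y, fs, band, window = 1, overlap = 0.9,
                               n_surrogates = 200L, alpha = 0.05,
                               seed = 1L) {
  if (n_surrogates < 100L) {
    stop("n_surrogates must be at least 100", call. = FALSE)
  }
  xseg <- segment_epoch(x, fs, window, overlap)
  yseg <- segment_epoch(y, fs, window, overlap)
  obs <- cicoh(xseg, yseg, band, fs)
  null <- with_seed(seed, vapply(seq_len(n_surrogates), function(i) {
    ys <- segment_epoch(circular_shift_surrogate(y, fs, window), fs,
                        window, overlap)
    abs(cicoh(xseg, ys, band, fs))
  }, numeric(1)))
  thr <- stats::quantile(null, 1 - alpha, names = FALSE)
  list(cicoh = obs, significant = abs(obs) > thr, threshold = thr,
       null = null)
}

#' Interhemispheric ciCOH matrix with significance mask
#'
#' ciCOH between every channel of the contralateral seed set (C3 and its
#' ring) and every channel of the ipsilateral set (C4 and its ring), with a
#' phase-randomization significance mask.  Surrogates of each ipsilateral
#' channel are shared across its seven contralateral partners.
#'
#' @param sig_contra,sig_ipsi Samples x 7 matrices of continuous signals
#'   (columns named by channel).
#' @param fs Sampling rate, Hz.
#' @param band `c(f_lo, f_hi)`, Hz.
#' @param window,overlap Segmentation settings.
#' @param n_surrogates,alpha Significance settings.
#' @param seed Integer seed.
#' @return An object of class `cicoh_matrix`: `values` and `mask` (7 x 7),
#'   `band`.
#' @export
cicoh_matrix <- function(sig_contra, sig_ipsi, fs, band,
                         window = 1, overlap = 0.9,
                         n_surrogates = 200L, alpha = 0.05, seed = 1L) {
  nc <- ncol(sig_contra); ni <- ncol(sig_ipsi)
  segs_c <- lapply(seq_len(nc), function(j)
    segment_epoch(sig_contra[, j], fs, window, overlap))
  segs_i <- lapply(seq_len(ni), function(j)
    segment_epoch(sig_ipsi[, j], fs, window, overlap))
  values <- matrix(NA_real_, nc, ni,
                   dimnames = list(colnames(sig_contra), colnames(sig_ipsi)))
  mask <- matrix(FALSE, nc, ni, dimnames = dimnames(values))
  for (j in seq_len(ni)) {
    null <- with_seed(derive_seed(seed, paste0("surr", j)), {
      t(vapply(seq_len(n_surrogates), function(s) {
        ys <- segment_epoch(circular_shift_surrogate(sig_ipsi[, j], fs,
                                                     window),
                            fs, window, overlap)
        vapply(segs_c, function(xs) abs(cicoh(xs, ys, band, fs)), numeric(1))
      }, numeric(nc)))
    })
    for (i in seq_len(nc)) {
      values[i, j] <- cicoh(segs_c[[i]], segs_i[[j]], band, fs)
      thr <- stats::quantile(null[, i], 1 - alpha, names = FALSE)
      mask[i, j] <- abs(values[i, j]) > thr
    }
  }
  structure(list(values = values, mask = mask, band = band),
            class = "cicoh_matrix")
}

#' Network intensity: sum of significant interhemispheric ciCOH
#'
#' The scalar coupling summary for one band and epoch: the sum of the
#' ciCOH values over all contralateral x ipsilateral channel pairs whose
#' significance mask is true.
#'
#' @param matrix A `cicoh_matrix`.
#' @return List with `value`, `n_significant`, `band`.
#' @export
network_intensity <- function(matrix) {
  list(value = sum(matrix$values[matrix$mask]),
       n_significant = sum(matrix$mask),
       band = matrix$band)
}

#' Canonical analysis bands
#'
#' Theta 4-7, low-beta 14-20, high-beta 21-30, gamma 31-50 Hz; the alpha
#' band is participant-specific and taken from the calibration profile.
#'
#' @param profile Optional `calibration_profile` supplying the alpha band
#'   (contralateral selection; defaults to 8-13 Hz if absent).
#' @return Named list of `c(f_lo, f_hi)` bands.
#' @export
analysis_bands <- function(profile = NULL) {
  alpha <- if (!is.null(profile)) profile$bands$contra else c(8, 13)
  list(theta = c(4, 7), alpha = alpha, low_beta = c(14, 20),
       high_beta = c(21, 30), gamma = c(31, 50))
}

#' Offline ERD of the pre-stimulus second
#'
#' ERD of the 1 s immediately before stimulation relative to the trial's
#' 1-5 s resting reference, computed per hemisphere on the large-Laplacian
#' signal of the common-average-referenced recording.  Trials with a
#' rejected channel among a hemisphere's 7-channel set are excluded for
#' that hemisphere.
#'
#' @param recording A common-average-referenced [eeg_recording()] (see
#'   [offline_preprocess()]).
#' @param profile A `calibration_profile` (target bands).
#' @param trial Trial index.
#' @param cs_time Stimulus time, seconds from trial start.
#' @param rejected Data frame of per-trial channel rejections (from
#'   [offline_preprocess()]).
#' @param band Optional `c(f_lo, f_hi)` overriding the profile band (e.g. a
#'   control band from [analysis_bands()]).
#' @return Named numeric `c(contra = , ipsi = )` ERD in percent; `NA` where
#'   the hemisphere was excluded.
#' @export
erd_offline <- function(recording, profile, trial, cs_time,
                        rejected = NULL, band = NULL) {
  fs <- recording$fs
  win <- prestimulus_window(recording, trial, cs_time)
  filt <- preprocess_online(recording$data, fs)
  s0 <- trial_start_sample(recording, trial) - 1L
  out <- c(contra = NA_real_, ipsi = NA_real_)
  for (hemi in c("contra", "ipsi")) {
    ctr <- if (hemi == "contra") "C3" else "C4"
    chans <- c(ctr, recording$neighbors[[ctr]])
    if (!is.null(rejected) &&
        any(rejected$trial == trial & rejected$channel %in% chans)) next
    lap <- large_laplacian(filt, ctr, recording$neighbors[[ctr]])
    b <- if (is.null(band)) profile$bands[[hemi]] else band
    # rest reference: mean power of the 1-s windows ending at 2..5 s
    ref <- mean(vapply(seq(2, 5, by = 0.1), function(e) {
      idx <- (s0 + round((e - 1) * fs) + 1L):(s0 + round(e * fs))
      band_power(filt_window <- lap[idx], b, fs)
    }, numeric(1)))
    p <- band_power(lap[win$last1s_idx], b, fs)
    out[hemi] <- compute_erd(p, ref)
  }
  out
}
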