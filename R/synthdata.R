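#' Pink (1/f) noise
#'
#' Gaussian noise with a 1/f amplitude spectrum, scaled to a target standard
#' deviation.  Used as the background EEG on which the mu oscillation rides,
#' so that alpha-band peaks stand out the way they do in real recordings.
#'
#' @param n Number of samples.
#' @param sd Target standard deviation.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, sd = 1) {
  if (n < 2L) return(rnorm(n, sd = sd))
  white <- rnorm(n)
  spec <- fft(white)
  # 1/sqrt(f) amplitude shaping -> 1/f power; DC removed
  f <- c(1, seq_len(n - 1L))
  f <- pmin(f, n - f + 1)        # mirror for the negative frequencies
  shape <- 1 / sqrt(f)
  shape[1] <- 0
  x <- Re(fft(spec * shape, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

# Raised-cosine amplitude envelope for one trial's MI epoch: 1 at rest,
# sqrt(1 - erd/100) during MI, 200 ms half-cosine transitions at the
# epoch boundaries (avoids spectral splatter from hard steps).
mi_envelope <- function(n_block, fs, session, erd_pct, ramp = 0.2) {
  env <- rep(1, n_block)
  lvl <- sqrt(max(0, 1 - erd_pct / 100))
  on <- round(mi_onset(session) * fs) + 1L
  off <- round((mi_onset(session) + session$mi) * fs)
  nr <- round(ramp * fs)
  core <- seq.int(min(on + nr, off), off, by = 1L)
  env[core] <- lvl
  if (nr > 0L && on + nr <= n_block) {
    t <- seq_len(nr) / nr
    env[on:(on + nr - 1L)] <- 1 + (lvl - 1) * (1 - cos(pi * t)) / 2
    fin <- off + seq_len(min(nr, n_block - off))
    env[fin] <- lvl + (1 - lvl) * (1 - cos(pi * seq_along(fin) / nr)) / 2
  }
  env
}

#' Generate a synthetic EEG recording with known ERD ground truth
#'
#' Builds a continuous multichannel recording for one session: pink 1/f
#' background plus white sensor noise on every channel, and a mu-band
#' oscillation over C3 (contralateral to the imagined right hand) and C4
#' (ipsilateral) whose amplitude drops to `sqrt(1 - erd/100)` of its resting
#' value during each motor-imagery epoch, so band power drops by the
#' configured ERD depth.  Per-trial realized depths jitter around the
#' session value (`erd_sd`), and are returned as ground truth.
#'
#' @param cfg A [sim_config()].
#' @param session A [session_spec()].
#' @param seed Integer seed; the same seed regenerates identical arrays.
#' @param neighbors Neighbor map (default [default_neighbors()]).
#' @return A list with `recording` (an [eeg_recording()]) and `truth`, a
#'   data frame with one row per trial: `trial`, `erd_contra_pct`,
#'   `erd_ipsi_pct` (the realized per-trial ERD depths).
#' @examples
#' sim <- generate_eeg(sim_config(), session_spec("MID", n_trials = 2), seed = 1)
#' sim$truth
#' @export
generate_eeg <- function(cfg, session, seed = cfg$seed,
                         neighbors = default_neighbors()) {
  channels <- c("C3", neighbors$C3, "C4", neighbors$C4)
  check_montage(channels, neighbors)
  fs <- cfg$sample_rate_eeg
  n_block <- round(block_duration(session) * fs)
  n_total <- n_block * session$n_trials
  with_seed(seed, {
    erd <- data.frame(
      trial = seq_len(session$n_trials),
      erd_contra_pct = pmin(100, rnorm(session$n_trials,
                                       cfg$erd_depth[["contra"]], cfg$erd_sd)),
      erd_ipsi_pct = pmin(100, rnorm(session$n_trials,
                                     cfg$erd_depth[["ipsi"]], cfg$erd_sd))
    )
    dat <- matrix(0, nrow = n_total, ncol = length(channels),
                  dimnames = list(NULL, channels))
    for (ch in seq_along(channels)) {
      dat[, ch] <- pink_noise(n_total, cfg$background_noise_sd) +
        rnorm(n_total, sd = cfg$white_noise_sd)
    }
    tt <- (seq_len(n_total) - 1) / fs
    for (hemi in c("contra", "ipsi")) {
      ctr <- if (hemi == "contra") "C3" else "C4"
      phase <- runif(1, 0, 2 * pi)
      env <- unlist(lapply(seq_len(session$n_trials), function(i) {
        mi_envelope(n_block, fs, session,
                    erd[[paste0("erd_", hemi, "_pct")]][i])
      }), use.names = FALSE)
      osc <- env * sin(2 * pi * cfg$mu_freq * tt + phase)
      dat[, ctr] <- dat[, ctr] + cfg$osc_amplitude * osc
      for (nb in neighbors[[ctr]]) {
        dat[, nb] <- dat[, nb] + cfg$neighbor_leak * cfg$osc_amplitude * osc
      }
    }
    list(recording = eeg_recording(dat, fs, channels, neighbors, session),
         truth = erd)
  })
}

#' Draw a latent true IHI from the configured ERD coupling
#'
#' true IHI = `ihi_intercept + ihi_slope * erd_ipsi + N(0, ihi_noise_sd)`,
#' clipped at `ihi_floor` (clipped draws flagged).  The linear-with-noise
#' coupling is the simplest model consistent with a correlation analysis
#' between ipsilateral ERD and IHI.
#'
#' @param erd_ipsi Ipsilateral ERD in percent at trigger time (vectorized).
#' @param cfg A [sim_config()].
#' @return Data frame with `true_ihi_pct` and logical `floored`.
#' @export
draw_true_ihi <- function(erd_ipsi, cfg) {
  raw <- cfg$ihi_intercept + cfg$ihi_slope * erd_ipsi +
    rnorm(length(erd_ipsi), sd = cfg$ihi_noise_sd)
  data.frame(true_ihi_pct = pmax(raw, cfg$ihi_floor),
             floored = raw < cfg$ihi_floor)
}

#' Generate a synthetic MEP trial
#'
#' Unconditioned (TS-only) amplitudes are lognormal with median
#' `mep_test_mean` and coefficient of variation `mep_cv`; paired (CS+TS)
#' trials multiply the draw by `true_ihi / 100`.  The returned trace spans
#' [-500, +500] ms around the pulse at the EMG rate, with a biphasic
#' deflection of the drawn peak-to-peak amplitude placed inside the
#' 20-45 ms post-stimulus window.  Pre-innervation contamination can be
#' injected for QC tests.
#'
#' @param pulse_kind `"CS+TS"` or `"TS-only"`.
#' @param erd_ipsi Ipsilateral ERD (percent) at trigger time; drives the
#'   true IHI for CS+TS trials.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param trace If `FALSE`, skip trace synthesis (amplitude only) — used for
#'   large simulated cohorts.
#' @param pre_innervation_pct RMS of injected background EMG in the 250 ms
#'   before the pulse, as a percentage of `mvc`.
#' @param mvc Maximal-voluntary-contraction RMS, mV (reference for
#'   `pre_innervation_pct`).
#' @param noise_sd SD of the baseline trace noise, mV.
#' @return A list of class `mep_trial`: `trace` (or `NULL`), `fs`,
#'   `pulse_index`, `pulse_kind`, `amplitude` (true peak-to-peak, mV),
#'   `true_ihi_pct`, `floored`.
#' @export
generate_mep <- function(pulse_kind, erd_ipsi, cfg, seed,
                         trace = TRUE, pre_innervation_pct = 0, mvc = 1,
                         noise_sd = 0.01) {
  with_seed(seed, {
    sdlog <- sqrt(log(1 + cfg$mep_cv^2))
    uncond <- rlnorm(1, meanlog = log(cfg$mep_test_mean), sdlog = sdlog)
    ihi <- draw_true_ihi(erd_ipsi, cfg)
    amp <- if (pulse_kind == "CS+TS") uncond * ihi$true_ihi_pct / 100 else uncond
    out <- list(pulse_kind = pulse_kind, amplitude = amp,
                true_ihi_pct = ihi$true_ihi_pct, floored = ihi$floored,
                fs = cfg$sample_rate_emg)
    if (trace) {
      fs <- cfg$sample_rate_emg
      n <- round(fs) + 1L                   # [-500, +500] ms
      t_ms <- (seq_len(n) - 1) / fs * 1000 - 500
      pulse_index <- which.min(abs(t_ms))
      w <- exp(-(t_ms - 28)^2 / (2 * 2.5^2)) - exp(-(t_ms - 36)^2 / (2 * 2.5^2))
      w <- w / (max(w) - min(w)) * amp
      tr <- w + rnorm(n, sd = noise_sd)
      if (pre_innervation_pct > 0) {
        pre <- t_ms >= -250 & t_ms < 0
        tr[pre] <- tr[pre] + generate_emg_background(
          duration = sum(pre) / fs, mvc = mvc,
          pre_innervation_pct = pre_innervation_pct, fs = fs,
          seed = derive_seed(seed, "preinnervation"))
      }
      out$trace <- tr
      out$pulse_index <- pulse_index
    }
    structure(out, class = "mep_trial")
  })
}

#' Generate background EMG at a controlled contraction level
#'
#' Band-limited (5-1000 Hz) Gaussian noise whose RMS over any 250 ms window
#' is approximately `pre_innervation_pct * mvc / 100` — the substrate for
#' the pre-innervation QC rule.
#'
#' @param duration Seconds.
#' @param mvc MVC reference RMS, mV.
#' @param pre_innervation_pct Target RMS as percent of MVC (>= 0).
#' @param fs Sampling rate, Hz (default 10000).
#' @param seed Integer seed.
#' @return Numeric vector (mV).
#' @export
generate_emg_background <- function(duration, mvc, pre_innervation_pct,
                                    fs = 10000, seed = 1L) {
  stopifnot(pre_innervation_pct >= 0)
  n <- round(duration * fs)
  if (pre_innervation_pct == 0) return(numeric(n))
  with_seed(seed, {
    x <- rnorm(n)
    bp <- signal::butter(2, c(5, min(1000, fs / 2 * 0.99)) / (fs / 2),
                         type = "pass")
    x <- as.numeric(signal::filter(bp, x))
    target <- pre_innervation_pct * mvc / 100
    x * target / sqrt(mean(x^2))
  })
}
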