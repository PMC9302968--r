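# Shared fixtures, built in code at test time.

# A calibration profile whose ERD percentile tables are the identity map
# (uniform distribution on [0, 100] %ERD): percentile p maps to value p.
uniform_profile <- function() {
  probs <- seq(0, 100, by = 0.5)
  tab <- stats::setNames(probs, paste0(probs, "%"))
  structure(
    list(bands = list(contra = c(9, 11), ipsi = c(9, 11)),
         erd_dist_rest = list(contra = tab, ipsi = tab),
         erd_dist_mi = list(contra = tab, ipsi = tab),
         axis_range = list(contra = c(5, 95), ipsi = c(5, 95)),
         origin = list(contra = 50, ipsi = 50)),
    class = "calibration_profile"
  )
}

# High-SNR simulation config: strong mu oscillation over modest noise so
# small-trial-count recoveries are sharp.
high_snr_config <- function(...) {
  sim_config(osc_amplitude = 40, background_noise_sd = 5, white_noise_sd = 1,
             ...)
}

# Band-limited noise and its Hilbert quadrature partner (90 degree lag):
# the canonical maximally "laggy" pair with |ciCOH| ~ 1 and a finite
# coherence time.
quadrature_pair <- function(n, fs, band = c(8, 13), noise_sd = 0.05) {
  f <- (0:(n - 1)) * fs / n
  X <- fft(rnorm(n))
  keep <- (f >= band[1] & f <= band[2]) |
    (f >= fs - band[2] & f <= fs - band[1])
  X[!keep] <- 0
  pos <- f > 0 & f < fs / 2
  X[!pos] <- 0          # analytic signal: positive frequencies only
  X[pos] <- 2 * X[pos]
  analytic <- fft(X, inverse = TRUE) / n
  a <- Re(analytic); b <- Im(analytic)
  s <- stats::sd(a)
  list(x = a / s + rnorm(n, sd = noise_sd),
       y = b / s + rnorm(n, sd = noise_sd))
}

# Independent offline ERD oracle: raw periodogram band power on the
# generated arrays (plain Laplacian arithmetic + spec.pgram), bypassing the
# online pipeline entirely.
periodogram_erd <- function(recording, truth_hemi = "ipsi", band = c(8, 12)) {
  ctr <- if (truth_hemi == "contra") "C3" else "C4"
  lap <- recording$data[, ctr] -
    rowMeans(recording$data[, recording$neighbors[[ctr]]])
  fs <- recording$fs
  ses <- recording$session
  epoch_power <- function(idx) {
    sp <- stats::spec.pgram(lap[idx], taper = 0, plot = FALSE)
    sel <- sp$freq * fs >= band[1] & sp$freq * fs <= band[2]
    mean(sp$spec[sel])
  }
  vapply(seq_len(ses$n_trials), function(tr) {
    s0 <- round((tr - 1) * block_duration(ses) * fs)
    rest <- (s0 + 1 * fs + 1):(s0 + 5 * fs)
    mi <- (s0 + 7 * fs + 1):(s0 + 12 * fs)
    100 * (1 - epoch_power(mi) / epoch_power(rest))
  }, numeric(1))
}
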