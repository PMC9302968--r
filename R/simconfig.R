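#' Simulation configuration
#'
#' Ground-truth parameters of the synthetic participant: the mu-rhythm
#' frequency, per-hemisphere ERD depths, noise and oscillation amplitudes,
#' and the linear coupling between ipsilateral ERD and interhemispheric
#' inhibition (IHI).  All downstream generators draw from these values.
#'
#' ERD depth is expressed on the same scale as the estimator output:
#' percentage loss of band power during motor imagery relative to rest
#' (100 = complete desynchronization, negative = synchronization).
#'
#' @param mu_freq Mu-rhythm frequency in Hz, within 8-13.
#' @param erd_depth Named numeric `c(contra = , ipsi = )`, percent band-power
#'   loss during MI per hemisphere (each <= 100).
#' @param erd_sd SD of the per-trial Gaussian jitter around `erd_depth`
#'   (percentage points), so percentile target boxes are non-degenerate.
#' @param sample_rate_eeg,sample_rate_emg Sampling rates in Hz.
#' @param background_noise_sd SD of the 1/f (pink) background EEG, uV.
#' @param white_noise_sd SD of the additive white sensor noise, uV.
#' @param osc_amplitude Peak amplitude of the mu oscillation at the center
#'   channel during rest, uV.
#' @param neighbor_leak Fraction of the center-channel oscillation that also
#'   appears on each ring channel (crude volume conduction).
#' @param ihi_intercept IHI in percent at zero ipsilateral ERD.
#' @param ihi_slope Change in IHI (percentage points) per ERD percentage
#'   point; negative couples stronger desynchronization to stronger
#'   inhibition (smaller IHI).
#' @param ihi_noise_sd SD of the trial-level Gaussian noise on true IHI.
#' @param ihi_floor Lower clip for true IHI after noise (clipped trials are
#'   flagged).
#' @param mep_test_mean Median unconditioned MEP amplitude, mV (about 1).
#' @param mep_cv Coefficient of variation of the lognormal MEP draw.
#' @param seed Integer seed recorded with the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(mu_freq = 10,
                       erd_depth = c(contra = 30, ipsi = 30),
                       erd_sd = 10,
                       sample_rate_eeg = 1000,
                       sample_rate_emg = 10000,
                       background_noise_sd = 10,
                       white_noise_sd = 2,
                       osc_amplitude = 20,
                       neighbor_leak = 0.2,
                       ihi_intercept = 100,
                       ihi_slope = -0.8,
                       ihi_noise_sd = 8,
                       ihi_floor = 5,
                       mep_test_mean = 1,
                       mep_cv = 0.3,
                       seed = 1L) {
  if (any(erd_depth > 100)) {
    stop("invalid-config: erd_depth cannot exceed 100%", call. = FALSE)
  }
  if (mu_freq < 8 || mu_freq > 13) {
    stop("invalid-config: mu_freq must lie within [8, 13] Hz", call. = FALSE)
  }
  if (is.null(names(erd_depth))) names(erd_depth) <- c("contra", "ipsi")
  pos <- c(background_noise_sd = background_noise_sd,
           osc_amplitude = osc_amplitude,
           mep_test_mean = mep_test_mean,
           sample_rate_eeg = sample_rate_eeg,
           sample_rate_emg = sample_rate_emg)
  if (any(pos <= 0)) {
    stop("invalid-config: amplitudes, SDs and rates must be positive",
         call. = FALSE)
  }
  structure(
    list(mu_freq = mu_freq, erd_depth = erd_depth, erd_sd = erd_sd,
         sample_rate_eeg = sample_rate_eeg, sample_rate_emg = sample_rate_emg,
         background_noise_sd = background_noise_sd,
         white_noise_sd = white_noise_sd,
         osc_amplitude = osc_amplitude, neighbor_leak = neighbor_leak,
         ihi_intercept = ihi_intercept, ihi_slope = ihi_slope,
         ihi_noise_sd = ihi_noise_sd, ihi_floor = ihi_floor,
         mep_test_mean = mep_test_mean, mep_cv = mep_cv,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> mu %g Hz; ERD contra/ipsi %g/%g%% (sd %g); IHI = %g %+g x ERD_ipsi\n",
    x$mu_freq, x$erd_depth[["contra"]], x$erd_depth[["ipsi"]], x$erd_sd,
    x$ihi_intercept, x$ihi_slope))
  invisible(x)
}

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards.  Keeps the generators reproducible without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a sub-seed for a named stage from a master seed; stays below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435.0 + h) %% 2147483629)
}
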