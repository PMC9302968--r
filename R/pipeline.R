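#' Latent ERD targets per session condition
#'
#' The mean bilateral ERD state the synthetic participant attains in each
#' condition: a constant moderate contralateral ERD during every
#' motor-imagery session, and an ipsilateral ERD that is raised in HIGH,
#' intrinsic in NoFB and MID, and pushed into synchronization (negative
#' ERD) in LOW.  REST carries no ERD on either side.
#'
#' @return Data frame with `kind`, `contra`, `ipsi` (percent ERD).
#' @export
session_erd_targets <- function() {
  data.frame(
    kind = c("REST", "NoFB", "HIGH", "MID", "LOW"),
    contra = c(0, 20, 20, 20, 20),
    ipsi = c(0, 15, 40, 15, -10)
  )
}

#' Simulate a synthetic cohort at the latent level
#'
#' Draws, for every participant x session x trial, the realized bilateral
#' ERD at trigger time (Gaussian around the condition's latent target, with
#' a participant-level offset), the true IHI from the configured linear
#' coupling, and the MEP amplitude (lognormal; conditioned trials scaled by
#' true IHI / 100).  Pulse kinds follow the balanced pre-planned
#' assignment.  This is the fast path used for cohort-level recovery
#' analyses; [generate_eeg()] + [run_session()] exercise the same model
#' through the full signal path.
#'
#' @param n_participants Cohort size (default 22).
#' @param cfg A [sim_config()] (coupling and MEP parameters).
#' @param n_trials Trials per session (default 40).
#' @param kinds Session conditions (default all five).
#' @param seed Integer seed.
#' @param participant_sd SD of the participant-level random offset on IHI
#'   (percentage points, default 8).
#' @return Data frame: `participant`, `session`, `trial`, `pulse_kind`,
#'   `erd_contra_pct`, `erd_ipsi_pct`, `true_ihi_pct`, `amplitude_mv`.
#' @export
simulate_cohort <- function(n_participants = 22L, cfg = sim_config(),
                            n_trials = 40L,
                            kinds = c("REST", "NoFB", "HIGH", "MID", "LOW"),
                            seed = 1L, participant_sd = 8) {
  targets <- session_erd_targets()
  sdlog <- sqrt(log(1 + cfg$mep_cv^2))
  with_seed(seed, {
    rows <- list()
    for (p in seq_len(n_participants)) {
      offset <- rnorm(1, 0, participant_sd)   # random intercept on IHI
      # feedback sessions in randomized order after REST and NoFB
      fb <- sample(intersect(c("HIGH", "MID", "LOW"), kinds))
      order_kinds <- c(intersect(c("REST", "NoFB"), kinds), fb)
      for (kind in order_kinds) {
        tg <- targets[targets$kind == kind, ]
        plan <- sample(c(rep("CS+TS", round(n_trials * 0.5)),
                         rep("TS-only", n_trials - round(n_trials * 0.5))))
        erd_c <- pmin(100, rnorm(n_trials, tg$contra, cfg$erd_sd))
        erd_i <- pmin(100, rnorm(n_trials, tg$ipsi, cfg$erd_sd))
        ihi <- pmax(cfg$ihi_floor,
                    cfg$ihi_intercept + offset + cfg$ihi_slope * erd_i +
                      rnorm(n_trials, sd = cfg$ihi_noise_sd))
        uncond <- rlnorm(n_trials, log(cfg$mep_test_mean), sdlog)
        amp <- ifelse(plan == "CS+TS", uncond * ihi / 100, uncond)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = p, session = kind, trial = seq_len(n_trials),
          pulse_kind = plan, erd_contra_pct = erd_c, erd_ipsi_pct = erd_i,
          true_ihi_pct = ihi, amplitude_mv = amp)
      }
    }
    do.call(rbind, rows)
  })
}

#' Session-level IHI per participant from a simulated cohort
#'
#' @param cohort Data frame from [simulate_cohort()].
#' @return Data frame: `participant`, `session`, `ihi`,
#'   `mean_unconditioned`.
#' @export
cohort_ihi <- function(cohort) {
  out <- lapply(split(cohort, list(cohort$participant, cohort$session),
                      drop = TRUE), function(d) {
    res <- compute_ihi(d$amplitude_mv[d$pulse_kind == "CS+TS"],
                       d$amplitude_mv[d$pulse_kind == "TS-only"],
                       session = d$session[1])
    data.frame(participant = d$participant[1], session = d$session[1],
               ihi = res$ihi, mean_unconditioned = res$mean_unconditioned)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$participant, out$session), ]
}

#' Run the full desk-scale experiment
#'
#' One participant's signal path — synthetic calibration EEG, calibration,
#' then a closed-loop session per condition with triggered/fallback pulses
#' and per-event MEPs — plus a latent-level cohort for the statistical
#' battery: session rmANOVA on IHI, Bonferroni post-hoc contrasts,
#' manipulation range, baseline normalization, repeated-measures
#' correlation between ipsilateral ERD and IHI, and the mixed model.
#'
#' @param seed Master seed.
#' @param cfg A [sim_config()].
#' @param n_trials Trials per closed-loop session (default 40).
#' @param calibration_trials Calibration trials (default 20).
#' @param n_participants Cohort size for the statistical battery
#'   (default 22).
#' @param kinds Signal-path session conditions to run (default HIGH, MID,
#'   LOW).
#' @param out_dir Optional directory; when given, events, the ERD stream,
#'   the IHI table and the stats summary are written there as CSV/JSON.
#' @return List with `profile`, `sessions` (per-kind events + logs),
#'   `mep_trials`, `ihi_signal_path`, `cohort`, `ihi_table`, `stats`.
#' @export
run_experiment <- function(seed = 1L, cfg = sim_config(),
                           n_trials = 40L, calibration_trials = 20L,
                           n_participants = 22L,
                           kinds = c("HIGH", "MID", "LOW"),
                           out_dir = NULL) {
  # --- signal path for one synthetic participant -------------------------
  calib_spec <- session_spec("NoFB", n_trials = calibration_trials)
  calib <- generate_eeg(cfg, calib_spec, seed = derive_seed(seed, "calib"))
  profile <- calibrate(calib$recording,
                       min_trials = min(5L, calibration_trials))
  targets <- session_erd_targets()
  sessions <- list()
  mep <- list()
  for (kind in kinds) {
    tg <- targets[targets$kind == kind, ]
    cfg_k <- cfg
    cfg_k$erd_depth <- c(contra = tg$contra, ipsi = tg$ipsi)
    spec <- session_spec(kind, n_trials = n_trials)
    sim <- generate_eeg(cfg_k, spec, seed = derive_seed(seed, kind))
    ses <- run_session(sim$recording, profile, spec,
                       seed = derive_seed(seed, paste0(kind, "-run")))
    sessions[[kind]] <- ses
    ev <- ses$events
    for (i in seq_len(nrow(ev))) {
      tr <- generate_mep(ev$pulse_kind[i], ev$erd_ipsi_pct[i], cfg,
                         seed = derive_seed(seed,
                                            paste0(kind, "-mep", i)),
                         trace = FALSE)
      mep[[length(mep) + 1L]] <- data.frame(
        session = kind, trial = ev$trial[i], triggered = ev$triggered[i],
        pulse_kind = ev$pulse_kind[i], amplitude = tr$amplitude,
        pre_rms = 0, true_ihi_pct = tr$true_ihi_pct)
    }
  }
  mep <- do.call(rbind, mep)
  mep <- qc_trials(mep, mvc = 1)
  acc <- mep[!mep$qc_rejected, ]
  ihi_signal <- lapply(kinds, function(kind) {
    d <- acc[acc$session == kind, ]
    compute_ihi(d$amplitude[d$pulse_kind == "CS+TS"],
                d$amplitude[d$pulse_kind == "TS-only"], session = kind)
  })
  names(ihi_signal) <- kinds

  # --- cohort-level battery ----------------------------------------------
  cohort <- simulate_cohort(n_participants, cfg, n_trials,
                            seed = derive_seed(seed, "cohort"))
  ihi_tab <- cohort_ihi(cohort)
  anova_dat <- data.frame(participant = ihi_tab$participant,
                          session = ihi_tab$session, value = ihi_tab$ihi)
  aov_res <- rm_anova_oneway(anova_dat)
  posthoc <- paired_t_bonferroni(
    anova_dat, contrasts = list(c("HIGH", "MID"), c("HIGH", "LOW"),
                                c("MID", "LOW")))
  means <- tapply(ihi_tab$ihi, ihi_tab$session, mean)
  manip <- manipulation_range(means[["HIGH"]], means[["LOW"]])
  normed <- normalize_to_baseline(means, baseline = "NoFB")
  nf <- cohort[cohort$session %in% c("HIGH", "MID", "LOW") &
                 cohort$pulse_kind == "CS+TS", ]
  rmc <- rm_corr(nf$erd_ipsi_pct, nf$true_ihi_pct, nf$participant)
  mm <- mixed_model_ihi(nf$true_ihi_pct, nf$erd_contra_pct,
                        nf$erd_ipsi_pct, nf$participant)
  stats_out <- list(rm_anova = aov_res, posthoc = posthoc,
                    session_means = as.list(means),
                    manipulation_range = manip,
                    normalized_to_baseline = as.list(normed),
                    rm_corr = rmc[c("r_rm", "df", "p")],
                    mixed_model = mm$coefficients)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (kind in kinds) {
      write_events(sessions[[kind]]$events,
                   file.path(out_dir, paste0("events_", kind, ".csv")))
    }
    write_profile(profile, file.path(out_dir, "profile.json"))
    utils::write.csv(ihi_tab, file.path(out_dir, "ihi_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(rm_anova = stats_out$rm_anova[c("F", "df", "p", "eta_sq")],
           session_means = stats_out$session_means,
           manipulation_range = manip,
           normalized_to_baseline = stats_out$normalized_to_baseline,
           rm_corr = stats_out$rm_corr),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
  }

  list(profile = profile, sessions = sessions, mep_trials = mep,
       ihi_signal_path = ihi_signal, cohort = cohort, ihi_table = ihi_tab,
       stats = stats_out)
}
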