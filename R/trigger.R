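#' Build the per-session bivariate target box
#'
#' Maps the calibration percentile tables to the ERD target rectangle of a
#' session condition.  The contralateral axis is always the 37.5-62.5th
#' percentile band; the ipsilateral axis selects the excitability state:
#' HIGH 75-95th, MID 37.5-62.5th, LOW 5-25th, NoFB 5-95th — all of the MI
#' distribution.  REST uses the 37.5-62.5th band of the rest distribution
#' on both axes.
#'
#' @param profile A `calibration_profile`.
#' @param kind Session condition.
#' @return An object of class `target_box`: `contra_range`, `ipsi_range`
#'   (ERD percent), `source_percentiles`, `source_distribution`.
#' @export
build_target_boxes <- function(profile,
                               kind = c("REST", "NoFB", "HIGH", "MID", "LOW")) {
  kind <- match.arg(kind)
  mid <- c(37.5, 62.5)
  pct <- switch(kind,
    REST = list(contra = mid, ipsi = mid, dist = "rest"),
    NoFB = list(contra = mid, ipsi = c(5, 95), dist = "mi"),
    HIGH = list(contra = mid, ipsi = c(75, 95), dist = "mi"),
    MID  = list(contra = mid, ipsi = mid, dist = "mi"),
    LOW  = list(contra = mid, ipsi = c(5, 25), dist = "mi")
  )
  contra <- profile_percentile(profile, "contra", pct$contra, pct$dist)
  ipsi <- profile_percentile(profile, "ipsi", pct$ipsi, pct$dist)
  if (diff(contra) <= 0 || diff(ipsi) <= 0) {
    warning("degenerate calibration distribution: zero-width target box")
  }
  structure(
    list(contra_range = contra, ipsi_range = ipsi,
         source_percentiles = list(contra = pct$contra, ipsi = pct$ipsi),
         source_distribution = pct$dist, kind = kind),
    class = "target_box"
  )
}

#' @export
print.target_box <- function(x, ...) {
  cat(sprintf("<target_box> %s: contra [%.1f, %.1f] x ipsi [%.1f, %.1f] %%ERD (%s dist)\n",
              x$kind, x$contra_range[1], x$contra_range[2],
              x$ipsi_range[1], x$ipsi_range[2], x$source_distribution))
  invisible(x)
}

#' Trigger decision for one ERD sample
#'
#' Fires iff both ERD components lie inside their (closed) target ranges,
#' the time from MI onset lies inside the trigger window, and no trigger
#' has fired yet this trial.
#'
#' @param erd_contra,erd_ipsi Instantaneous ERD, percent.
#' @param box A `target_box`.
#' @param t_mi Time from MI onset, seconds.
#' @param already_fired Has this trial already triggered?
#' @param trigger_window Eligible window, seconds from MI onset.
#' @return Logical.
#' @export
evaluate_trigger <- function(erd_contra, erd_ipsi, box, t_mi,
                             already_fired = FALSE,
                             trigger_window = c(0.5, 5.5)) {
  !already_fired &&
    t_mi >= trigger_window[1] && t_mi <= trigger_window[2] &&
    erd_contra >= box$contra_range[1] && erd_contra <= box$contra_range[2] &&
    erd_ipsi >= box$ipsi_range[1] && erd_ipsi <= box$ipsi_range[2]
}

#' Pre-plan the pulse-kind assignment for a session
#'
#' Exactly balanced assignment of paired (CS+TS) versus unconditioned
#' (TS-only) pulses — round(n * split) CS+TS trials — in a seeded random
#' order.  Planned ahead of the session, independent of the EEG, so the
#' pulse composition cannot be confounded with brain state.
#'
#' @param n_trials Number of trials (> 0).
#' @param split Fraction of CS+TS trials (default 0.5).
#' @param seed Integer seed.
#' @return Character vector of `"CS+TS"` / `"TS-only"`, one per trial.
#' @export
plan_pulse_assignment <- function(n_trials, split = 0.5, seed = 1L) {
  if (n_trials < 1L) stop("n_trials must be positive", call. = FALSE)
  stopifnot(split > 0, split < 1)
  n_cs <- round(n_trials * split)
  kinds <- c(rep("CS+TS", n_cs), rep("TS-only", n_trials - n_cs))
  with_seed(seed, sample(kinds))
}

#' Fallback timing for a non-triggered trial
#'
#' When the ERD never reaches the target box by 5.5 s, the pulse is
#' delivered anyway at a uniformly random time in the 5.5-6.0 s fallback
#' window, irrespective of the instantaneous ERD.
#'
#' @param n Number of draws.
#' @param window Fallback window, seconds from MI onset.
#' @return Numeric vector of event times (s from MI onset).
#' @export
fallback_nontriggered <- function(n = 1L, window = c(5.5, 6.0)) {
  stats::runif(n, window[1], window[2])
}

#' Run one closed-loop session
#'
#' Streams the online ERD estimate through the trigger state machine:
#' builds the session's target box from the calibration profile, walks the
#' 100-ms ERD samples of each trial, fires on the first sample inside the
#' box within the trigger window, and otherwise delivers the fallback pulse
#' in the 5.5-6.0 s window.  Pulse kinds follow the pre-planned balanced
#' assignment; CS+TS events schedule the test stimulus 10 ms after the
#' conditioning stimulus.
#'
#' @param recording An [eeg_recording()] covering the whole session.
#' @param profile A `calibration_profile`.
#' @param spec A [session_spec()].
#' @param seed Integer seed (pulse plan and fallback timing).
#' @return A list with `events` — data frame of one row per trial: `trial`,
#'   `triggered`, `t_event_s` (from MI onset), `pulse_kind`, `isi_ms`,
#'   `erd_contra_pct`, `erd_ipsi_pct` — and `log`, the per-session summary
#'   (success count, mean waiting time from MI onset and from the earliest
#'   eligible trigger time).
#' @export
run_session <- function(recording, profile, spec = recording$session,
                        seed = 1L) {
  needed <- session_duration(spec) * recording$fs
  if (nrow(recording$data) < needed) {
    stop("truncation error: recording shorter than the session", call. = FALSE)
  }
  box <- build_target_boxes(profile, spec$kind)
  plan <- plan_pulse_assignment(spec$n_trials, spec$pulse_split,
                                derive_seed(seed, "pulse-plan"))
  stream <- run_realtime(recording, profile)
  onset <- mi_onset(spec)
  fb <- with_seed(derive_seed(seed, "fallback"),
                  fallback_nontriggered(spec$n_trials, spec$fallback_window))
  events <- lapply(seq_len(spec$n_trials), function(tr) {
    st <- stream[stream$trial == tr, ]
    t_mi <- st$t_s - onset
    inside <- vapply(seq_len(nrow(st)), function(i) {
      evaluate_trigger(st$erd_contra_pct[i], st$erd_ipsi_pct[i], box,
                       t_mi[i], FALSE, spec$trigger_window)
    }, logical(1))
    if (any(inside)) {
      i <- which(inside)[1]
      data.frame(trial = tr, triggered = TRUE, t_event_s = t_mi[i],
                 pulse_kind = plan[tr],
                 isi_ms = if (plan[tr] == "CS+TS") 10 else NA_real_,
                 erd_contra_pct = st$erd_contra_pct[i],
                 erd_ipsi_pct = st$erd_ipsi_pct[i])
    } else {
      # ERD at the fallback moment: last emitted sample before the event
      i <- max(which(t_mi <= fb[tr]))
      data.frame(trial = tr, triggered = FALSE, t_event_s = fb[tr],
                 pulse_kind = plan[tr],
                 isi_ms = if (plan[tr] == "CS+TS") 10 else NA_real_,
                 erd_contra_pct = st$erd_contra_pct[i],
                 erd_ipsi_pct = st$erd_ipsi_pct[i])
    }
  })
  events <- do.call(rbind, events)
  trg <- events$t_event_s[events$triggered]
  log <- list(
    kind = spec$kind,
    n_trials = spec$n_trials,
    n_triggered = sum(events$triggered),
    mean_wait_from_mi_onset_s = if (length(trg)) mean(trg) else NA_real_,
    # same statistic measured from the earliest eligible trigger time
    # (0.5 s after MI onset), the "task onset" convention
    mean_wait_from_task_onset_s = if (length(trg))
      mean(trg - spec$trigger_window[1]) else NA_real_
  )
  list(events = events, log = log, box = box)
}
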