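#' Session specification
#'
#' Describes one experimental session: its condition, trial count and the
#' within-trial timeline (5 s rest, 1 s ready, 6 s motor imagery, 3 s
#' inter-trial interval), the EEG-triggered stimulation window and the
#' non-triggered fallback window, and the planned fraction of paired
#' (CS+TS) pulses.
#'
#' @param kind Session condition: one of `"REST"`, `"NoFB"`, `"HIGH"`,
#'   `"MID"`, `"LOW"`.
#' @param n_trials Number of trials (default 40).
#' @param rest,ready,mi,iti Epoch durations in seconds (defaults 5, 1, 6, 3).
#' @param trigger_window Eligible trigger times in seconds from MI onset
#'   (default `c(0.5, 5.5)`).
#' @param fallback_window Window for the non-triggered fallback pulse,
#'   seconds from MI onset (default `c(5.5, 6.0)`).
#' @param pulse_split Fraction of trials receiving the paired CS+TS pulse
#'   (default 0.5; the rest receive the unconditioned test pulse alone).
#' @return An object of class `session_spec`.
#' @examples
#' sp <- session_spec("HIGH")
#' trial_duration(sp)    # 12 s
#' session_duration(sp)  # 600 s = 10 min
#' @export
session_spec <- function(kind = c("REST", "NoFB", "HIGH", "MID", "LOW"),
                         n_trials = 40L,
                         rest = 5, ready = 1, mi = 6, iti = 3,
                         trigger_window = c(0.5, 5.5),
                         fallback_window = c(5.5, 6.0),
                         pulse_split = 0.5) {
  kind <- match.arg(kind)
  stopifnot(n_trials >= 1L, rest > 0, ready >= 0, mi > 0, iti >= 0,
            pulse_split > 0, pulse_split < 1)
  if (trigger_window[1] < 0 || trigger_window[2] > mi) {
    stop("trigger_window must lie within the MI epoch", call. = FALSE)
  }
  if (fallback_window[1] < trigger_window[2]) {
    stop("fallback_window must follow the trigger window", call. = FALSE)
  }
  structure(
    list(kind = kind, n_trials = as.integer(n_trials),
         rest = rest, ready = ready, mi = mi, iti = iti,
         trigger_window = trigger_window,
         fallback_window = fallback_window,
         pulse_split = pulse_split),
    class = "session_spec"
  )
}

#' @rdname session_spec
#' @param spec A `session_spec`.
#' @export
trial_duration <- function(spec) spec$rest + spec$ready + spec$mi

#' @rdname session_spec
#' @export
block_duration <- function(spec) trial_duration(spec) + spec$iti

#' @rdname session_spec
#' @export
session_duration <- function(spec) spec$n_trials * block_duration(spec)

#' @rdname session_spec
#' @export
mi_onset <- function(spec) spec$rest + spec$ready

#' @export
print.session_spec <- function(x, ...) {
  cat(sprintf("<session_spec> %s: %d trials of %g s (+%g s ITI), %g s total\n",
              x$kind, x$n_trials, trial_duration(x), x$iti,
              session_duration(x)))
  invisible(x)
}
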