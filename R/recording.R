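#' EEG recording container
#'
#' A multichannel EEG recording: a samples x channels matrix in microvolts
#' at a fixed sampling rate, with channel names, the neighbor map used by
#' the large Laplacian, and the session layout that produced it (trials are
#' contiguous blocks of `block_duration(session)` seconds).
#'
#' @param data Numeric matrix, samples in rows, channels in columns.
#' @param fs Sampling rate, Hz.
#' @param channels Character vector of channel names (length = ncol).
#' @param neighbors Named list mapping center channels to their 6 neighbors.
#' @param session The `session_spec` describing the trial layout.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels, neighbors, session) {
  data <- as.matrix(data)
  stopifnot(ncol(data) == length(channels), fs > 0)
  colnames(data) <- channels
  check_montage(channels, neighbors)
  structure(
    list(data = data, fs = fs, channels = channels,
         neighbors = neighbors, session = session),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s x %d trials\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs,
              x$session$kind, x$session$n_trials))
  invisible(x)
}

# Sample index of the first sample of trial i (1-based).
trial_start_sample <- function(recording, trial) {
  blk <- block_duration(recording$session)
  as.integer(round((trial - 1) * blk * recording$fs)) + 1L
}
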