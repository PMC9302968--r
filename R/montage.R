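#' Default bilateral sensorimotor montage
#'
#' Fourteen channels: C3 and C4 plus the six surrounding channels each, as
#' used by the large Laplacian spatial filter (center minus the mean of its
#' ring).  Channel names follow the extended 10-20 system.
#'
#' @return A named list with elements `C3` and `C4`, each a character vector
#'   of six neighbor channel names.
#' @examples
#' default_neighbors()
#' @export
default_neighbors <- function() {
  list(
    C3 = c("FC5", "FC1", "C5", "C1", "CP5", "CP1"),
    C4 = c("FC2", "FC6", "C2", "C6", "CP2", "CP6")
  )
}

#' All channel names of the default montage
#' @return Character vector of 14 channel names (C3, C4 and their rings).
#' @export
default_montage <- function() {
  nb <- default_neighbors()
  c("C3", nb$C3, "C4", nb$C4)
}

check_montage <- function(channels, neighbors) {
  for (ctr in c("C3", "C4")) {
    if (!ctr %in% channels) {
      stop("montage error: missing center channel ", ctr, call. = FALSE)
    }
    nb <- neighbors[[ctr]]
    if (is.null(nb) || length(nb) != 6L) {
      stop("montage error: ", ctr, " must have exactly 6 neighbors",
           call. = FALSE)
    }
    missing <- setdiff(nb, channels)
    if (length(missing) > 0L) {
      stop("montage error: missing neighbor channels ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}
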