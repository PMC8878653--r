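#' Gesture labels understood by the toolkit
#'
#' Three gestures occur in a recording: `rest` (no activation, between
#' activation bouts), and the two classifier classes `open` and `grasp`.
#'
#' @return Character vector `c("rest", "open", "grasp")`.
#' @export
gesture_levels <- function() c("rest", "open", "grasp")

as_gesture <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), gesture_levels())
  if (length(bad) > 0)
    abort_invalid(sprintf("unknown gesture label(s): %s", paste(bad, collapse = ", ")))
  factor(x, levels = gesture_levels())
}

#' Multi-channel sEMG recording
#'
#' Container for a multi-channel surface-EMG time series in millivolts with
#' its sampling rate, optional per-sample gesture annotation and an optional
#' subject identifier.
#'
#' @param samples Numeric matrix, channels x time, in mV. Row names are taken
#'   as channel names; defaults are `ch1`, `ch2`, ...
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param labels Optional per-sample gesture labels (length = number of time
#'   samples); coerced with [gesture_levels()] ordering.
#' @param subject_id Optional subject identifier string.
#'
#' @return An object of class `signal_recording`.
#' @export
signal_recording <- function(samples, sampling_rate, labels = NULL,
                             subject_id = NA_character_) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    abort_invalid("`samples` must be a numeric channels x time matrix")
  stopifnot_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  if (!is.null(labels)) {
    labels <- as_gesture(labels)
    if (length(labels) != ncol(samples))
      abort_invalid("`labels` must have one entry per time sample")
  }
  if (is.null(rownames(samples)))
    rownames(samples) <- paste0("ch", seq_len(nrow(samples)))
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         labels = labels, subject_id = subject_id),
    class = "signal_recording")
}

#' @export
print.signal_recording <- function(x, ...) {
  cat(sprintf("<signal_recording> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              n_channels(x), n_samples(x), x$sampling_rate,
              n_samples(x) / x$sampling_rate))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  invisible(x)
}

#' @rdname signal_recording
#' @param rec A `signal_recording`.
#' @export
n_channels <- function(rec) nrow(rec$samples)

#' @rdname signal_recording
#' @export
n_samples <- function(rec) ncol(rec$samples)
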