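#' Sliding-window specification
#'
#' Overlapped sliding-window segmentation: 250 ms analysis windows advanced
#' in 100 ms steps by default, the standard low-latency compromise for
#' real-time myoelectric control.
#'
#' @param window_ms Window length in ms (default 250).
#' @param step_ms Window increment in ms (default 100); `0 < step_ms <=
#'   window_ms`. Both must convert to whole sample counts at the
#'   recording's sampling rate.
#'
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(window_ms = 250, step_ms = 100) {
  stopifnot_scalar_number(window_ms, "window_ms", positive = TRUE)
  stopifnot_scalar_number(step_ms, "step_ms", positive = TRUE)
  if (step_ms > window_ms) abort_invalid("`step_ms` must not exceed `window_ms`")
  structure(list(window_ms = window_ms, step_ms = step_ms), class = "window_spec")
}

ms_to_samples <- function(ms, sampling_rate, name) {
  n <- ms * sampling_rate / 1000
  if (abs(n - round(n)) > 1e-9)
    abort_invalid(sprintf("`%s` (%g ms) is not a whole number of samples at %g Hz",
                          name, ms, sampling_rate))
  as.integer(round(n))
}

# Majority label of a window; ties broken toward the gesture that starts
# earliest within the window.
window_label <- function(labels) {
  tab <- table(labels)
  tab <- tab[tab > 0]
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) return(winners)
  first_occurrence <- vapply(winners, function(g) match(g, labels), 0L)
  winners[which.min(first_occurrence)]
}

#' Segment a recording into sliding-window frames
#'
#' Produces `floor((N - W) / S) + 1` left-aligned frames of `W` samples
#' advanced by `S` samples. Each frame carries the majority per-sample
#' gesture label (ties toward the earlier-starting gesture), or `NA` for
#' unlabeled recordings.
#'
#' @param rec A [signal_recording()] at least one window long.
#' @param spec A [window_spec()].
#'
#' @return An object of class `window_frames`: a list of frames (each with
#'   `start_index`, `samples` (channels x W), `label`), with the sampling
#'   rate and window geometry attached as attributes.
#' @export
segment <- function(rec, spec = window_spec()) {
  if (!inherits(rec, "signal_recording")) abort_invalid("`rec` must be a signal_recording")
  W <- ms_to_samples(spec$window_ms, rec$sampling_rate, "window_ms")
  S <- ms_to_samples(spec$step_ms, rec$sampling_rate, "step_ms")
  N <- n_samples(rec)
  if (N < W)
    abort_windowing(sprintf("recording (%d samples) is shorter than one window (%d samples)",
                            N, W))
  starts <- seq.int(1L, N - W + 1L, by = S)
  frames <- lapply(starts, function(s) {
    idx <- s:(s + W - 1L)
    list(start_index = s,
         samples = rec$samples[, idx, drop = FALSE],
         label = if (is.null(rec$labels)) NA_character_
                 else window_label(as.character(rec$labels[idx])))
  })
  structure(frames, class = "window_frames",
            sampling_rate = rec$sampling_rate, window = W, step = S)
}

#' @export
print.window_frames <- function(x, ...) {
  cat(sprintf("<window_frames> %d frames of %d samples (step %d) @ %g Hz\n",
              length(x), attr(x, "window"), attr(x, "step"),
              attr(x, "sampling_rate")))
  invisible(x)
}

check_window <- function(x, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len)
    abort_invalid(sprintf("window must contain at least %d sample(s)", min_len))
  invisible(x)
}

#' Time-domain window features
#'
#' The six per-channel window statistics used for gesture recognition.
#' `x` is one channel of a window (numeric vector, mV).
#'
#' * `feature_iemg(x, dt)` — integrated EMG, `sum(|x|) * dt` (mV s); the
#'   discretisation of the rectified-signal integral over the window, with
#'   `dt = 1/sampling_rate`.
#' * `feature_rms(x)` — root mean square, `sqrt(mean(x^2))` (mV).
#' * `feature_mav(x)` — mean absolute value, `mean(|x|)` (mV).
#' * `feature_zc(x, threshold)` — zero crossings: count of consecutive
#'   sample pairs with a sign change (`x[n] * x[n-1] < 0`) whose amplitude
#'   difference is at least `threshold` (a crude frequency proxy, robust to
#'   baseline noise). `literal = TRUE` instead applies the literal printed
#'   textbook-variant rule that counts non-crossing pairs
#'   (`sgn(x[n] * x[n-1]) == 1` with `sgn(v) = 1` iff `v >= threshold`);
#'   it is provided for auditability only.
#' * `feature_var(x)` — sample variance with the `n - 1` denominator (mV^2).
#' * `feature_min(x)` — minimum raw sample value (mV).
#'
#' @param x Numeric vector: one channel of one window.
#' @param dt Sample period in seconds.
#' @param threshold Amplitude-difference threshold in mV (default 0.01).
#' @param literal Use the literal printed non-crossing rule (default FALSE).
#'
#' @return A single number (a count for `feature_zc`).
#' @name window_features
NULL

#' @rdname window_features
#' @export
feature_iemg <- function(x, dt) {
  check_window(x)
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  sum(abs(x)) * dt
}

#' @rdname window_features
#' @export
feature_rms <- function(x) {
  check_window(x)
  sqrt(mean(x^2))
}

#' @rdname window_features
#' @export
feature_mav <- function(x) {
  check_window(x)
  mean(abs(x))
}

#' @rdname window_features
#' @export
feature_zc <- function(x, threshold = 0.01, literal = FALSE) {
  check_window(x, min_len = 2L)
  if (threshold < 0) abort_invalid("`threshold` must be >= 0")
  prod_pairs <- x[-1] * x[-length(x)]
  big_jump <- abs(diff(x)) >= threshold
  if (literal) sum(prod_pairs >= threshold & big_jump)
  else sum(prod_pairs < 0 & big_jump)
}

#' @rdname window_features
#' @export
feature_var <- function(x) {
  check_window(x, min_len = 2L)
  stats::var(x)
}

#' @rdname window_features
#' @export
feature_min <- function(x) {
  check_window(x)
  min(x)
}

FEATURE_NAMES <- c("iEMG", "RMS", "MAV", "ZC", "VAR", "MIN")

feature_fun <- function(name, dt, zc_threshold) {
  switch(name,
    iEMG = function(x) feature_iemg(x, dt),
    RMS = feature_rms,
    MAV = feature_mav,
    ZC = function(x) feature_zc(x, zc_threshold),
    VAR = feature_var,
    MIN = feature_min)
}

#' Labeled per-window feature set
#'
#' @param matrix Numeric n_windows x d feature matrix (no missing values).
#' @param labels Gesture label per window.
#' @param feature_names Column names, length d.
#'
#' @return An object of class `labeled_feature_set`.
#' @export
labeled_feature_set <- function(matrix, labels, feature_names = colnames(matrix)) {
  matrix <- as.matrix(matrix)
  if (anyNA(matrix) || !is.numeric(matrix))
    abort_invalid("feature matrix must be numeric with no missing values")
  labels <- as_gesture(labels)
  if (length(labels) != nrow(matrix))
    abort_invalid("one label per feature row required")
  if (is.null(feature_names) || length(feature_names) != ncol(matrix))
    abort_invalid("`feature_names` must name every column")
  colnames(matrix) <- feature_names
  structure(list(matrix = matrix, labels = labels, feature_names = feature_names),
            class = "labeled_feature_set")
}

#' @export
print.labeled_feature_set <- function(x, ...) {
  cat(sprintf("<labeled_feature_set> %d windows x %d features\n",
              nrow(x$matrix), ncol(x$matrix)))
  tab <- table(droplevels(x$labels))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' Extract per-window features
#'
#' One row per frame; columns are channel-major, feature-minor
#' (`ch1_VAR, ch1_RMS, ch1_MIN, ch2_VAR, ...` for the default selection),
#' in the order the features are requested.
#'
#' @param frames A `window_frames` object from [segment()].
#' @param features Subset of `iEMG`, `RMS`, `MAV`, `ZC`, `VAR`, `MIN`;
#'   the default `c("VAR", "RMS", "MIN")` is the selection used for
#'   grasp/open recognition.
#' @param zc_threshold Threshold passed to [feature_zc()] (default 0.01 mV).
#'
#' @return A [labeled_feature_set()].
#' @export
extract_features <- function(frames, features = c("VAR", "RMS", "MIN"),
                             zc_threshold = 0.01) {
  if (!inherits(frames, "window_frames")) abort_invalid("`frames` must come from segment()")
  if (length(frames) == 0) abort_invalid("`frames` must be non-empty")
  unknown <- setdiff(features, FEATURE_NAMES)
  if (length(unknown) > 0)
    abort_invalid(sprintf("unknown feature name(s): %s", paste(unknown, collapse = ", ")))
  dt <- 1 / attr(frames, "sampling_rate")
  n_ch <- nrow(frames[[1]]$samples)
  funs <- lapply(features, feature_fun, dt = dt, zc_threshold = zc_threshold)
  names <- as.vector(t(outer(paste0("ch", seq_len(n_ch)), features, paste, sep = "_")))
  mat <- t(vapply(frames, function(fr) {
    unlist(lapply(seq_len(n_ch), function(ch) {
      x <- fr$samples[ch, ]
      vapply(funs, function(f) f(x), 0)
    }))
  }, numeric(n_ch * length(features))))
  labels <- vapply(frames, function(fr) fr$label, "")
  labeled_feature_set(mat, labels, names)
}
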