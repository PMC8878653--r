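#' Parameters of the synthetic sEMG generator
#'
#' The generator emulates two-channel surface EMG as observed on a forearm:
#' band-limited Gaussian "interference-pattern" noise whose amplitude is
#' modulated by a gesture-dependent activation envelope, plus additive
#' baseline sensor noise and an optional 50 Hz powerline tone. Peak signal
#' amplitude is kept inside the 0-6 mV physiological envelope by a
#' saturating front end, and spectral content stays inside the configured
#' 20-450 Hz band (within the stated 0-500 Hz content at the default
#' 1000 Hz sampling rate).
#'
#' The default activation gains give the two channels complementary roles:
#' channel 1 (flexor-side electrode) responds mainly to `grasp`, channel 2
#' (extensor-side electrode) mainly to `open`, so downstream classifiers
#' have a learnable two-muscle structure.
#'
#' @param sampling_rate Sampling rate in Hz (default 1000).
#' @param n_channels Number of electrode channels (default 2).
#' @param baseline_noise_sd Standard deviation of additive white baseline
#'   noise, mV (default 0.02).
#' @param activation_gain Channels x gestures matrix of activation RMS
#'   scales in mV; columns ordered as [gesture_levels()]. All entries >= 0.
#' @param envelope_rise_ms Time constant of the first-order activation
#'   envelope smoothing, ms (default 50).
#' @param powerline_amp Amplitude of the powerline tone, mV (default 0.05).
#' @param powerline_freq Powerline frequency, Hz (default 50).
#' @param bandwidth Two-element band (Hz) for the shaped activity noise,
#'   default `c(20, 450)`.
#' @param seed Default integer seed used by the generator functions.
#'
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(sampling_rate = 1000, n_channels = 2,
                         baseline_noise_sd = 0.02,
                         activation_gain = NULL,
                         envelope_rise_ms = 50,
                         powerline_amp = 0.05, powerline_freq = 50,
                         bandwidth = c(20, 450), seed = 1L) {
  stopifnot_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar_number(n_channels, "n_channels", positive = TRUE)
  if (is.null(activation_gain)) {
    activation_gain <- matrix(0, n_channels, 3,
                              dimnames = list(paste0("ch", seq_len(n_channels)),
                                              gesture_levels()))
    # complementary flexor/extensor pattern on the first two channels
    activation_gain[1, "grasp"] <- 1.0
    activation_gain[1, "open"] <- 0.25
    if (n_channels >= 2) {
      activation_gain[2, "open"] <- 1.0
      activation_gain[2, "grasp"] <- 0.25
    }
  }
  activation_gain <- as.matrix(activation_gain)
  if (nrow(activation_gain) != n_channels || ncol(activation_gain) != 3)
    abort_invalid("`activation_gain` must be an n_channels x 3 matrix (rest, open, grasp)")
  if (any(activation_gain < 0)) abort_invalid("activation gains must be >= 0")
  if (is.null(colnames(activation_gain))) colnames(activation_gain) <- gesture_levels()
  if (baseline_noise_sd < 0) abort_invalid("`baseline_noise_sd` must be >= 0")
  if (powerline_amp < 0) abort_invalid("`powerline_amp` must be >= 0")
  if (length(bandwidth) != 2 || bandwidth[1] <= 0 || bandwidth[2] <= bandwidth[1])
    abort_invalid("`bandwidth` must be an increasing positive Hz pair")
  if (bandwidth[2] >= sampling_rate / 2)
    abort_invalid("upper band edge must be below the Nyquist frequency")
  structure(list(sampling_rate = sampling_rate, n_channels = n_channels,
                 baseline_noise_sd = baseline_noise_sd,
                 activation_gain = activation_gain,
                 envelope_rise_ms = envelope_rise_ms,
                 powerline_amp = powerline_amp, powerline_freq = powerline_freq,
                 bandwidth = bandwidth, seed = as.integer(seed)),
            class = "synth_params")
}

# Saturating front end: keeps samples inside the 0-6 mV peak envelope.
SEMG_PEAK_MV <- 6

# Band-limited unit-variance Gaussian carrier. A 256-tap FIR keeps
# out-of-band leakage far below the spectral-content invariant.
shaped_noise <- function(n, bandwidth, sampling_rate) {
  nyq <- sampling_rate / 2
  b <- signal::fir1(256, bandwidth / nyq, type = "pass")
  x <- Re(signal::fftfilt(b, stats::rnorm(n)))
  x / stats::sd(x)
}

# First-order low-pass of the rectangular gesture gate (neuromuscular drive
# does not switch discontinuously).
smooth_gate <- function(gate, rise_ms, sampling_rate) {
  if (rise_ms <= 0) return(gate)
  a <- exp(-1000 / (rise_ms * sampling_rate))
  as.numeric(stats::filter((1 - a) * gate, a, method = "recursive"))
}

#' Generate a synthetic sEMG recording following a gesture schedule
#'
#' Each channel is unit-variance band-limited Gaussian noise multiplied by a
#' smoothed gesture-dependent activation envelope (per-gesture RMS gains
#' from `params$activation_gain`), plus white baseline noise and an optional
#' powerline tone, finally saturated at the 6 mV peak envelope. All
#' randomness flows from `seed`; identical inputs give bit-identical output.
#'
#' @param schedule Data frame with columns `gesture` (values from
#'   [gesture_levels()]) and `duration_s` (> 0), executed in order.
#' @param params A [synth_params()] object.
#' @param seed Integer seed (defaults to `params$seed`).
#' @param subject_id Optional subject identifier stored in the recording.
#'
#' @return A [signal_recording()] with per-sample labels.
#' @export
#' @examples
#' rec <- generate_recording(
#'   data.frame(gesture = c("grasp", "open"), duration_s = c(5, 5)),
#'   synth_params(), seed = 7)
#' rec
generate_recording <- function(schedule, params = synth_params(),
                               seed = params$seed, subject_id = NA_character_) {
  schedule <- as.data.frame(schedule)
  if (nrow(schedule) == 0) abort_invalid("`schedule` must be non-empty")
  if (!all(c("gesture", "duration_s") %in% names(schedule)))
    abort_invalid("`schedule` needs columns `gesture` and `duration_s`")
  if (any(!is.finite(schedule$duration_s)) || any(schedule$duration_s <= 0))
    abort_invalid("schedule durations must be > 0")
  gest <- as_gesture(schedule$gesture)
  if (anyNA(gest)) abort_invalid("schedule gestures must not be missing")
  fs <- params$sampling_rate
  n_per <- round(schedule$duration_s * fs)
  if (any(n_per < 1)) abort_invalid("each schedule entry must span at least one sample")
  labels <- rep(as.character(gest), n_per)
  n <- length(labels)
  gains <- params$activation_gain
  withr::with_seed(as.integer(seed), {
    samples <- matrix(0, params$n_channels, n)
    t <- (seq_len(n) - 1) / fs
    for (ch in seq_len(params$n_channels)) {
      gate <- gains[ch, labels]
      env <- smooth_gate(gate, params$envelope_rise_ms, fs)
      x <- env * shaped_noise(n, params$bandwidth, fs)
      if (params$baseline_noise_sd > 0)
        x <- x + stats::rnorm(n, sd = params$baseline_noise_sd)
      if (params$powerline_amp > 0)
        x <- x + params$powerline_amp *
          sin(2 * pi * params$powerline_freq * t + stats::runif(1, 0, 2 * pi))
      samples[ch, ] <- pmin(pmax(x, -SEMG_PEAK_MV), SEMG_PEAK_MV)
    }
    rownames(samples) <- rownames(gains)
    signal_recording(samples, fs, labels = labels, subject_id = subject_id)
  })
}

#' Generate a full per-subject acquisition session
#'
#' Emulates the acquisition protocol used for training data: alternating
#' `grasp` and `open` activation bouts (`n_reps` of each, held `hold_s`
#' seconds) separated by rest, with a rest lead-in. The resulting recording
#' feeds the windowing/feature pipeline that produces the 128-window
#' training protocol.
#'
#' @param params A [synth_params()] object.
#' @param n_reps Repetitions of each gesture (default 10).
#' @param hold_s Hold duration per bout in seconds (default 5).
#' @param rest_s Rest duration between bouts in seconds (default 2).
#' @param lead_in_s Initial rest duration in seconds (default 1).
#' @inheritParams generate_recording
#'
#' @return A labeled [signal_recording()].
#' @export
make_subject_dataset <- function(params = synth_params(), n_reps = 10,
                                 hold_s = 5, rest_s = 2, lead_in_s = 1,
                                 seed = params$seed,
                                 subject_id = NA_character_) {
  if (!is.numeric(n_reps) || n_reps < 1) abort_invalid("`n_reps` must be >= 1")
  gestures <- c("rest", rep(c("grasp", "rest", "open", "rest"), n_reps))
  durations <- c(lead_in_s, rep(c(hold_s, rest_s, hold_s, rest_s), n_reps))
  generate_recording(data.frame(gesture = gestures, duration_s = durations),
                     params, seed = seed, subject_id = subject_id)
}

# "grasp:5,open:5" -> schedule data frame (CLI surface)
parse_schedule <- function(text) {
  parts <- strsplit(trimws(text), ",", fixed = TRUE)[[1]]
  if (length(parts) == 0) abort_invalid("empty schedule")
  kv <- strsplit(parts, ":", fixed = TRUE)
  if (any(lengths(kv) != 2)) abort_invalid("schedule entries must be gesture:seconds")
  data.frame(gesture = vapply(kv, `[`, "", 1),
             duration_s = as.numeric(vapply(kv, `[`, "", 2)))
}
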