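#' Signal conditioning specification
#'
#' Describes the software equivalent of the acquisition front end: a gain
#' stage, a Butterworth band-pass and a powerline notch. Both filters are
#' applied forward-backward (zero phase), so gesture labels stay aligned
#' with the underlying activity.
#'
#' `bandpass_order` is the overall band-pass order (must be even; the
#' underlying low/high prototype has half that order). The notch is a
#' second-order-section Butterworth band-stop of width `notch_freq /
#' notch_q`.
#'
#' @param bandpass Two-element passband in Hz (default `c(20, 450)`).
#' @param bandpass_order Overall band-pass filter order, even (default 4).
#' @param notch_freq Notch centre frequency in Hz (default 50; set 60 where
#'   60 Hz mains applies, or `NA` to disable).
#' @param notch_q Notch quality factor (default 30).
#' @param gain Dimensionless gain applied before filtering (default 1;
#'   amplification is a hardware concern, software units stay in mV).
#'
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(bandpass = c(20, 450), bandpass_order = 4,
                        notch_freq = 50, notch_q = 30, gain = 1) {
  if (length(bandpass) != 2 || any(bandpass <= 0) || bandpass[1] >= bandpass[2])
    abort_invalid("`bandpass` must be an increasing positive Hz pair")
  if (bandpass_order < 2 || bandpass_order %% 2 != 0)
    abort_invalid("`bandpass_order` must be a positive even integer")
  if (!is.na(notch_freq) && notch_freq <= 0) abort_invalid("`notch_freq` must be > 0")
  stopifnot_scalar_number(notch_q, "notch_q", positive = TRUE)
  stopifnot_scalar_number(gain, "gain", positive = TRUE)
  structure(list(bandpass = bandpass, bandpass_order = bandpass_order,
                 notch_freq = notch_freq, notch_q = notch_q, gain = gain),
            class = "filter_spec")
}

validate_spec_rate <- function(spec, sampling_rate) {
  nyq <- sampling_rate / 2
  if (spec$bandpass[2] >= nyq)
    abort_invalid(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)",
                          spec$bandpass[2], nyq))
  if (!is.na(spec$notch_freq) && spec$notch_freq >= nyq)
    abort_invalid("notch frequency is at or above Nyquist")
  invisible(spec)
}

spec_filters <- function(spec, sampling_rate) {
  nyq <- sampling_rate / 2
  filts <- list(signal::butter(spec$bandpass_order / 2, spec$bandpass / nyq,
                               type = "pass"))
  if (!is.na(spec$notch_freq)) {
    bw <- spec$notch_freq / spec$notch_q
    filts <- c(filts, list(signal::butter(2, c(spec$notch_freq - bw / 2,
                                               spec$notch_freq + bw / 2) / nyq,
                                          type = "stop")))
  }
  filts
}

#' Condition a recording (gain, band-pass, notch)
#'
#' Applies `spec$gain`, then the band-pass and the notch, each zero-phase
#' (forward-backward), channel by channel. Output has identical shape,
#' labels and sampling rate; conditioning is linear.
#'
#' @param rec A [signal_recording()].
#' @param spec A [filter_spec()].
#'
#' @return A conditioned [signal_recording()].
#' @export
condition_signal <- function(rec, spec = filter_spec()) {
  if (!inherits(rec, "signal_recording")) abort_invalid("`rec` must be a signal_recording")
  validate_spec_rate(spec, rec$sampling_rate)
  if (n_samples(rec) <= 3 * spec$bandpass_order)
    abort_invalid("recording too short for the requested filter order")
  filts <- spec_filters(spec, rec$sampling_rate)
  out <- rec$samples * spec$gain
  for (ch in seq_len(nrow(out))) {
    x <- out[ch, ]
    for (f in filts) x <- signal::filtfilt(f, x)
    out[ch, ] <- x
  }
  signal_recording(out, rec$sampling_rate, labels = rec$labels,
                   subject_id = rec$subject_id)
}

# H(z) on the unit circle for one ARMA filter
eval_tf <- function(filt, freqs, sampling_rate) {
  z <- exp(-2i * pi * freqs / sampling_rate)
  num <- vapply(z, function(zz) sum(filt$b * zz^(seq_along(filt$b) - 1)), 0i)
  den <- vapply(z, function(zz) sum(filt$a * zz^(seq_along(filt$a) - 1)), 0i)
  num / den
}

#' Magnitude response of the conditioning chain
#'
#' Returns the gain in dB of [condition_signal()]'s whole chain as applied:
#' the zero-phase (forward-backward) application squares each filter's
#' magnitude response, which is reflected here.
#'
#' @inheritParams condition_signal
#' @param sampling_rate Sampling rate in Hz the chain is evaluated against.
#' @param freqs Frequencies (Hz) in (0, Nyquist) to evaluate.
#'
#' @return Numeric vector of gains in dB, one per frequency.
#' @export
filter_response <- function(spec, sampling_rate, freqs) {
  if (length(freqs) == 0) abort_invalid("`freqs` must be non-empty")
  if (any(freqs <= 0 | freqs >= sampling_rate / 2))
    abort_invalid("`freqs` must lie strictly inside (0, Nyquist)")
  validate_spec_rate(spec, sampling_rate)
  db <- rep(20 * log10(spec$gain), length(freqs))
  for (f in spec_filters(spec, sampling_rate)) {
    # 40 = 2 passes x 20 dB/decade convention
    db <- db + 40 * log10(Mod(eval_tf(f, freqs, sampling_rate)))
  }
  db
}
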