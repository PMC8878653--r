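#' Read and write sEMG recordings as delimited text
#'
#' Recordings are stored as CSV with columns `t_s, ch1_mV, ch2_mV, ...[,
#' label]` preceded by `#`-prefixed metadata lines carrying the sampling
#' rate (required) and subject id. Numeric values are written with 17
#' significant digits so the round trip is lossless.
#'
#' @param rec A [signal_recording()].
#' @param path File path.
#'
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a [signal_recording()].
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "signal_recording")) abort_invalid("`rec` must be a signal_recording")
  n <- n_samples(rec)
  cols <- c(list(t_s = (seq_len(n) - 1) / rec$sampling_rate),
            stats::setNames(lapply(seq_len(n_channels(rec)),
                                   function(ch) rec$samples[ch, ]),
                            paste0("ch", seq_len(n_channels(rec)), "_mV")))
  body <- do.call(cbind, lapply(cols, function(v) sprintf("%.17g", v)))
  colnames(body) <- names(cols)
  if (!is.null(rec$labels)) body <- cbind(body, label = as.character(rec$labels))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz: %.17g", rec$sampling_rate), con)
  if (!is.na(rec$subject_id))
    writeLines(sprintf("# subject_id: %s", rec$subject_id), con)
  writeLines(paste(colnames(body), collapse = ","), con)
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

read_metadata <- function(path) {
  lines <- readLines(path, n = 20L)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  meta
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  meta <- read_metadata(path)
  if (is.null(meta$sampling_rate_hz))
    abort_format("missing `sampling_rate_hz` metadata line")
  nf <- utils::count.fields(path, sep = ",", comment.char = "#")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1)
    abort_format(sprintf("ragged rows: first mismatch at data line %d",
                         which(nf != nf[1])[1]))
  df <- utils::read.csv(path, comment.char = "#")
  ch_cols <- grep("^ch[0-9]+_mV$", names(df), value = TRUE)
  if (length(ch_cols) == 0) abort_format("no channel columns (chN_mV) found")
  ch_cols <- ch_cols[order(as.integer(sub("^ch([0-9]+)_mV$", "\\1", ch_cols)))]
  samples <- t(as.matrix(df[, ch_cols, drop = FALSE]))
  rownames(samples) <- sub("_mV$", "", ch_cols)
  signal_recording(samples, as.numeric(meta$sampling_rate_hz),
                   labels = if ("label" %in% names(df)) df$label else NULL,
                   subject_id = meta$subject_id %||% NA_character_)
}

#' Read and write labeled feature sets as CSV
#'
#' Plain CSV with a `label` column followed by one column per feature
#' (`ch1_VAR`, ...), full numeric precision.
#'
#' @param fs A [labeled_feature_set()].
#' @param path File path.
#' @return `write_feature_set` returns `path` invisibly; `read_feature_set`
#'   a [labeled_feature_set()].
#' @export
write_feature_set <- function(fs, path) {
  body <- cbind(label = as.character(fs$labels),
                vapply(seq_len(ncol(fs$matrix)),
                       function(j) sprintf("%.17g", fs$matrix[, j]),
                       character(nrow(fs$matrix))))
  colnames(body) <- c("label", fs$feature_names)
  utils::write.table(body, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  df <- utils::read.csv(path)
  if (!"label" %in% names(df)) abort_format("missing `label` column")
  feats <- setdiff(names(df), "label")
  if (length(feats) == 0) abort_format("no feature columns found")
  labeled_feature_set(as.matrix(df[, feats, drop = FALSE]), df$label, feats)
}

#' Default run configuration
#'
#' All defaults follow the acquisition and recognition protocol the
#' toolkit models: 1000 Hz sampling, 250/100 ms windows, `VAR`/`RMS`/`MIN`
#' features and a 64/64 train/test split.
#'
#' @return Nested list of configuration sections.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    synth = list(sampling_rate = 1000, n_channels = 2, baseline_noise_sd = 0.02,
                 envelope_rise_ms = 50, powerline_amp = 0.05, powerline_freq = 50,
                 bandwidth = c(20, 450)),
    filter = list(bandpass = c(20, 450), bandpass_order = 4,
                  notch_freq = 50, notch_q = 30, gain = 1),
    window = list(window_ms = 250, step_ms = 100),
    features = list(names = c("VAR", "RMS", "MIN"), zc_threshold = 0.01),
    lda = list(ridge_eps = NULL),
    eval = list(n_train = 64, n_test = 64, n_per_class = 64, knn_k = 5,
                dt_max_depth = 4),
    controller = list(stroke = 10, current_limit = 1, position_rate = 1,
                      smooth_m = 3, gate = 0.5))
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    keypath <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      abort_config(sprintf("unknown configuration key `%s`", keypath))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        abort_config(sprintf("`%s` must be a section", keypath))
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  chk <- function(ok, key) if (!ok) abort_config(sprintf("`%s` out of range", key))
  chk(cfg$synth$sampling_rate > 0, "synth.sampling_rate")
  chk(cfg$window$window_ms > 0, "window.window_ms")
  chk(cfg$window$step_ms > 0 && cfg$window$step_ms <= cfg$window$window_ms,
      "window.step_ms")
  chk(all(cfg$features$names %in% FEATURE_NAMES), "features.names")
  chk(cfg$eval$n_train >= 1 && cfg$eval$n_test >= 1, "eval.n_train/n_test")
  chk(cfg$controller$smooth_m >= 1 && cfg$controller$smooth_m %% 2 == 1,
      "controller.smooth_m")
  cfg
}

#' Load a run configuration from YAML
#'
#' Unspecified keys fall back to [default_config()]; unknown keys are
#' rejected with the offending key path named.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- tryCatch(yaml::read_yaml(path),
                     error = function(e) abort_config(conditionMessage(e)))
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
}
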