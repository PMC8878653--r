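# Classed conditions so callers (and the CLI) can distinguish usage errors,
# data-format errors and numerical failures.

myo_abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "myograsp_error")))
}

abort_invalid <- function(msg, ...) myo_abort(msg, "myograsp_invalid_argument", ...)
abort_windowing <- function(msg, ...) myo_abort(msg, "myograsp_windowing_error", ...)
abort_degenerate_class <- function(msg, ...) myo_abort(msg, "myograsp_degenerate_class", ...)
abort_format <- function(msg, ...) myo_abort(msg, "myograsp_format_error", ...)
abort_config <- function(msg, ...) myo_abort(msg, "myograsp_config_error", ...)
abort_no_solution <- function(msg, ...) myo_abort(msg, "myograsp_no_solution", ...)
abort_singular <- function(msg, ...) myo_abort(msg, "myograsp_singular_configuration", ...)

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_invalid(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    abort_invalid(sprintf("`%s` must be > 0", name))
  invisible(x)
}
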