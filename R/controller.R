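#' Grasp controller state
#'
#' State of the simulated dual-loop actuation layer. The position loop
#' advances the motor toward the stroke limit while closing; the current
#' loop monitors simulated motor current (the contact-force proxy) and
#' freezes the grip the moment it reaches `current_limit`, holding the
#' current exactly at the limit.
#'
#' @param stroke Maximum linear stroke in mm (default 10).
#' @param current_limit Current limit in A (default 1).
#' @param position_rate Position advance per controller tick in mm
#'   (default 1; one tick = one frame step).
#'
#' @return An object of class `control_state` with `mode` (one of `idle`,
#'   `closing`, `opening`, `holding`, `fault`), `position` (mm) and
#'   `current` (A).
#' @export
control_state <- function(stroke = 10, current_limit = 1, position_rate = 1) {
  stopifnot_scalar_number(stroke, "stroke", positive = TRUE)
  stopifnot_scalar_number(current_limit, "current_limit", positive = TRUE)
  stopifnot_scalar_number(position_rate, "position_rate", positive = TRUE)
  structure(list(mode = "idle", position = 0, current = 0, stroke = stroke,
                 current_limit = current_limit, position_rate = position_rate),
            class = "control_state")
}

#' Simulated grasped object
#'
#' Linear-stiffness stand-in for objects of different shapes and sizes:
#' below `contact_position` the fingers move freely; past it, simulated
#' motor current grows as `stiffness * compression`.
#'
#' @param contact_position Contact position along the stroke, mm.
#' @param stiffness Current per unit compression, A/mm (>= 0).
#' @param stroke Stroke the object must fit within, mm (default 10).
#'
#' @return An object of class `object_model`.
#' @export
object_model <- function(contact_position, stiffness, stroke = 10) {
  stopifnot_scalar_number(contact_position, "contact_position")
  if (contact_position < 0 || contact_position > stroke)
    abort_invalid("`contact_position` must lie within [0, stroke]")
  if (stiffness < 0) abort_invalid("`stiffness` must be >= 0")
  structure(list(contact_position = contact_position, stiffness = stiffness),
            class = "object_model")
}

object_current <- function(object, position) {
  if (is.null(object)) return(0)
  object$stiffness * max(0, position - object$contact_position)
}

#' Majority-vote smoothing of a decision stream
#'
#' Replaces each frame decision by the majority over the last `m` raw
#' decisions (odd `m`, default used by the controller is 3: rejects
#' single-frame flickers at the cost of `(m - 1)` steps of latency).
#' Before `m` frames have accumulated the most recent raw decision is
#' passed through; three-way ties resolve to the most recent raw decision.
#'
#' @param stream Character vector (or factor) of gesture decisions.
#' @param m Odd vote length, >= 1.
#'
#' @return Character vector of smoothed decisions, same length.
#' @export
smooth_decisions <- function(stream, m = 3) {
  if (m < 1 || m %% 2 == 0) abort_invalid("`m` must be odd and >= 1")
  stream <- as.character(stream)
  n <- length(stream)
  out <- character(n)
  for (i in seq_len(n)) {
    if (i < m) { out[i] <- stream[i]; next }
    window <- stream[(i - m + 1):i]
    tab <- table(window)
    winners <- names(tab)[tab == max(tab)]
    out[i] <- if (length(winners) == 1) winners else stream[i]
  }
  out
}

#' Advance the grasp controller by one tick
#'
#' Implements the two closed loops. On a `grasp` command the motor
#' advances by `position_rate` (position loop) and the simulated current
#' is monitored: the moment it would reach `current_limit`, the position
#' is pulled back onto the limit isocline (`contact + limit/stiffness`)
#' and the mode latches to `holding` (current loop); with no object the
#' motor holds at the stroke limit. An `open` command retracts toward 0,
#' reaching mode `idle`. `rest` leaves the state untouched.
#'
#' @param state A [control_state()].
#' @param command A gesture label (`grasp`, `open` or `rest`).
#' @param object An [object_model()] or `NULL` for free closing.
#'
#' @return The updated `control_state`.
#' @export
step_controller <- function(state, command, object = NULL) {
  if (!inherits(state, "control_state")) abort_invalid("`state` must be a control_state")
  command <- as.character(command)
  if (!command %in% gesture_levels()) abort_invalid("unknown command")
  if (!is.null(object) && object$contact_position > state$stroke)
    abort_invalid("object contact lies beyond the stroke")
  if (command == "grasp") {
    if (state$mode == "holding") return(state)
    pos <- min(state$position + state$position_rate, state$stroke)
    cur <- object_current(object, pos)
    if (cur >= state$current_limit && !is.null(object) && object$stiffness > 0) {
      pos <- object$contact_position + state$current_limit / object$stiffness
      state$mode <- "holding"
      cur <- object_current(object, pos)
    } else if (pos >= state$stroke) {
      state$mode <- "holding"
    } else {
      state$mode <- "closing"
    }
    state$position <- pos
    state$current <- cur
  } else if (command == "open") {
    pos <- max(state$position - state$position_rate, 0)
    state$position <- pos
    state$current <- object_current(object, pos)
    state$mode <- if (pos <= 0) "idle" else "opening"
  }
  state
}

# projected-space confidence margin gate: suppress commands whose nearest/
# second-nearest projected-mean distance gap is below `gate` times the
# smallest inter-mean distance (rest and boundary windows must not actuate)
gate_commands <- function(model, features, raw, gate) {
  if (gate <= 0) return(raw)
  proj <- project(model, features)
  pm <- model$projected_means
  d2 <- outer(rowSums(proj^2), rowSums(pm^2), "+") - 2 * proj %*% t(pm)
  d <- sqrt(pmax(d2, 0))
  inter <- min(stats::dist(pm))
  margin <- apply(d, 1, function(row) {
    s <- sort(row)
    if (length(s) < 2) Inf else s[2] - s[1]
  })
  ifelse(margin >= gate * inter, raw, "rest")
}

#' Replay a recording through the full control pipeline
#'
#' End-to-end simulation: condition the signal, segment it, extract the
#' model's features, classify every frame, gate low-confidence frames to
#' `rest`, smooth with an `m`-frame majority vote, and step the grasp
#' controller once per frame.
#'
#' @param rec A [signal_recording()].
#' @param model A fitted [fit_lda()] model whose features match
#'   `features`.
#' @param filter A [filter_spec()].
#' @param window A [window_spec()].
#' @param features Feature selection used when training the model.
#' @param m Majority-vote length (odd, default 3).
#' @param gate Confidence-gate fraction of the inter-mean projected
#'   distance (default 0.5; 0 disables gating).
#' @param state Initial [control_state()].
#' @param object An [object_model()] or `NULL`.
#'
#' @return A data frame of class `grasp_session` with one row per frame:
#'   `frame`, `time_s` (frame end time), `decision` (raw), `smoothed`
#'   (gated + majority-voted command), `mode`, `position_mm`, `current_A`.
#' @export
run_session <- function(rec, model, filter = filter_spec(),
                        window = window_spec(),
                        features = c("VAR", "RMS", "MIN"),
                        m = 3, gate = 0.5,
                        state = control_state(), object = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      myo_abort(sprintf("[%s] %s", name, conditionMessage(e)),
                class(e)[1], parent = e)
    })
  }
  cond <- stage("preprocess", condition_signal(rec, filter))
  frames <- stage("segment", segment(cond, window))
  fs <- stage("features", extract_features(frames, features))
  raw <- stage("predict", as.character(predict(model, fs$matrix)))
  cmd <- stage("gate", gate_commands(model, fs$matrix, raw, gate))
  smoothed <- smooth_decisions(cmd, m)
  n <- length(smoothed)
  W <- attr(frames, "window")
  log <- data.frame(frame = seq_len(n),
                    time_s = (vapply(frames, `[[`, 0L, "start_index") - 1 + W) /
                      rec$sampling_rate,
                    decision = raw, smoothed = smoothed,
                    mode = character(n), position_mm = numeric(n),
                    current_A = numeric(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    state <- step_controller(state, smoothed[i], object)
    log$mode[i] <- state$mode
    log$position_mm[i] <- state$position
    log$current_A[i] <- state$current
  }
  class(log) <- c("grasp_session", "data.frame")
  log
}
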