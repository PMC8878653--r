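#' Finger linkage geometry
#'
#' Geometry of the underactuated finger mechanism, described by two closed
#' vector loops over eight link vectors `r1..r8`. Under the package's
#' convention (x rightward, y upward, all angles counter-clockwise from
#' +x), each vector `ri` has direction angle: `r1 -> theta2` (the actuator
#' crank), `r2 -> theta4`, `r3 -> theta1` (proximal phalanx), `r4 ->
#' theta4 + delta`, `r5 -> theta3` (distal phalanx), `r6 -> theta5`,
#' `r7 -> theta5 + beta`, `r8 -> theta7` (fixed frame offset). `delta` and
#' `beta` are rigid angular offsets: `r2`/`r4` lie on one ternary coupler
#' body, `r6`/`r7` on another.
#'
#' The two loops are `r4 + r6 = r3 + r5` and `r1 + r2 + r7 = r3 + r5 +
#' r8`; their four XY scalar components are the closure residuals
#' evaluated by [loop_residual()].
#'
#' @param lengths Named numeric vector of the eight link lengths
#'   `r1..r8`, mm, all > 0.
#' @param delta,beta Rigid angular offsets, rad.
#' @param theta7 Fixed frame-link angle, rad.
#' @param crank Actuator slider-crank mapping: list with `radius` (mm),
#'   `s_ref` (mm) and `theta_ref` (rad); [stroke_to_crank()] maps actuator
#'   stroke to the driven angle.
#' @param driven Name of the driven coordinate (default `"theta2"`, the
#'   crank; any one of `theta1..theta5` may be driven instead).
#' @param proximal_limit,distal_limit Design joint-excursion limits in
#'   degrees (defaults 84.5 and 135); configuration constants, not solved
#'   outputs.
#'
#' @return An object of class `linkage_geometry`.
#' @export
linkage_geometry <- function(lengths, delta, beta, theta7,
                             crank = list(radius = 12, s_ref = 0, theta_ref = 0),
                             driven = "theta2",
                             proximal_limit = 84.5, distal_limit = 135) {
  need <- paste0("r", 1:8)
  if (!all(need %in% names(lengths)))
    abort_invalid("`lengths` must name r1..r8")
  lengths <- lengths[need]
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    abort_invalid("all link lengths must be finite and > 0")
  if (proximal_limit <= 0 || proximal_limit >= 180 ||
      distal_limit <= 0 || distal_limit >= 180)
    abort_invalid("joint limits must lie in (0, 180) degrees")
  if (!driven %in% paste0("theta", 1:5))
    abort_invalid("`driven` must be one of theta1..theta5")
  structure(list(lengths = lengths, delta = delta, beta = beta,
                 theta7 = theta7, crank = crank, driven = driven,
                 proximal_limit = proximal_limit, distal_limit = distal_limit),
            class = "linkage_geometry")
}

ALL_ANGLES <- c("theta1", "theta2", "theta3", "theta4", "theta5")

pose_theta <- function(pose) {
  if (inherits(pose, "finger_pose")) pose$theta else pose
}

#' Loop-closure residual of a candidate pose
#'
#' Evaluates the four XY scalar components of the two vector-loop
#' equations at the supplied angles; a pose satisfies both loops exactly
#' when all four components vanish.
#'
#' @param geom A [linkage_geometry()].
#' @param pose A `finger_pose` or a named angle vector containing
#'   `theta1..theta5` (rad); `theta7` comes from the geometry.
#'
#' @return Numeric 4-vector `(Ax, Ay, Bx, By)` in mm.
#' @export
loop_residual <- function(geom, pose) {
  th <- pose_theta(pose)
  if (any(!is.finite(th[ALL_ANGLES]))) abort_invalid("pose angles must be finite")
  r <- geom$lengths
  t1 <- th[["theta1"]]; t2 <- th[["theta2"]]; t3 <- th[["theta3"]]
  t4 <- th[["theta4"]]; t5 <- th[["theta5"]]
  t4a <- t4 + geom$delta; t5a <- t5 + geom$beta; t7 <- geom$theta7
  c(Ax = r[["r4"]] * cos(t4a) + r[["r6"]] * cos(t5) -
        r[["r3"]] * cos(t1) - r[["r5"]] * cos(t3),
    Ay = r[["r4"]] * sin(t4a) + r[["r6"]] * sin(t5) -
        r[["r3"]] * sin(t1) - r[["r5"]] * sin(t3),
    Bx = r[["r1"]] * cos(t2) + r[["r2"]] * cos(t4) + r[["r7"]] * cos(t5a) -
        r[["r3"]] * cos(t1) - r[["r5"]] * cos(t3) - r[["r8"]] * cos(t7),
    By = r[["r1"]] * sin(t2) + r[["r2"]] * sin(t4) + r[["r7"]] * sin(t5a) -
        r[["r3"]] * sin(t1) - r[["r5"]] * sin(t3) - r[["r8"]] * sin(t7))
}

# analytic Jacobian of the residual wrt the four free angles
loop_jacobian <- function(geom, th, unknowns) {
  r <- geom$lengths
  t1 <- th[["theta1"]]; t2 <- th[["theta2"]]; t3 <- th[["theta3"]]
  t4 <- th[["theta4"]]; t5 <- th[["theta5"]]
  t4a <- t4 + geom$delta; t5a <- t5 + geom$beta
  cols <- list(
    theta1 = c( r[["r3"]] * sin(t1), -r[["r3"]] * cos(t1),
                r[["r3"]] * sin(t1), -r[["r3"]] * cos(t1)),
    theta2 = c(0, 0, -r[["r1"]] * sin(t2), r[["r1"]] * cos(t2)),
    theta3 = c( r[["r5"]] * sin(t3), -r[["r5"]] * cos(t3),
                r[["r5"]] * sin(t3), -r[["r5"]] * cos(t3)),
    theta4 = c(-r[["r4"]] * sin(t4a), r[["r4"]] * cos(t4a),
               -r[["r2"]] * sin(t4),  r[["r2"]] * cos(t4)),
    theta5 = c(-r[["r6"]] * sin(t5),  r[["r6"]] * cos(t5),
               -r[["r7"]] * sin(t5a), r[["r7"]] * cos(t5a)))
  do.call(cbind, cols[unknowns])
}

#' Fingertip position of a pose
#'
#' Forward chaining along the two phalanges: the tip sits at
#' `r3 (cos t1, sin t1) + r5 (cos t3, sin t3)` from the knuckle origin.
#'
#' @inheritParams loop_residual
#' @return Numeric `(x, y)` in mm.
#' @export
fingertip_position <- function(geom, pose) {
  th <- pose_theta(pose)
  r <- geom$lengths
  c(x = r[["r3"]] * cos(th[["theta1"]]) + r[["r5"]] * cos(th[["theta3"]]),
    y = r[["r3"]] * sin(th[["theta1"]]) + r[["r5"]] * sin(th[["theta3"]]))
}

new_pose <- function(geom, th) {
  structure(list(theta = th[ALL_ANGLES], driven = geom$driven,
                 fingertip = fingertip_position(geom, th),
                 residual = sqrt(sum(loop_residual(geom, th)^2))),
            class = "finger_pose")
}

#' @export
print.finger_pose <- function(x, ...) {
  cat("<finger_pose>", paste(sprintf("%s=%.4f", names(x$theta), x$theta),
                             collapse = " "), "\n")
  cat(sprintf("  tip (%.2f, %.2f) mm, residual %.2e mm\n",
              x$fingertip[1], x$fingertip[2], x$residual))
  invisible(x)
}

#' Solve the loop-closure equations for a pose
#'
#' Newton iteration on the four scalar closure equations for the four
#' non-driven angles, starting from `guess` (which selects the assembly
#' branch). Converges to a residual norm below `tol`.
#'
#' @param geom A [linkage_geometry()].
#' @param driven_value Value of the driven coordinate (rad).
#' @param guess Starting pose (a `finger_pose` or named angle vector) on
#'   the desired assembly branch.
#' @param tol Residual norm tolerance, mm (default 1e-12).
#' @param max_iter Maximum Newton iterations (default 100).
#'
#' @return A `finger_pose`; errors with class
#'   `myograsp_singular_configuration` at a mechanism dead point and
#'   `myograsp_no_solution` on non-convergence.
#' @export
solve_pose <- function(geom, driven_value, guess, tol = 1e-12, max_iter = 100) {
  th <- pose_theta(guess)[ALL_ANGLES]
  if (anyNA(th)) abort_invalid("`guess` must supply theta1..theta5")
  th[[geom$driven]] <- driven_value
  unknowns <- setdiff(ALL_ANGLES, geom$driven)
  for (it in seq_len(max_iter)) {
    res <- loop_residual(geom, th)
    if (sqrt(sum(res^2)) < tol) return(new_pose(geom, th))
    J <- loop_jacobian(geom, th, unknowns)
    if (rcond(J) < 1e-12)
      abort_singular("Jacobian is singular: mechanism dead point")
    th[unknowns] <- th[unknowns] - solve(J, res)
  }
  abort_no_solution(sprintf("Newton did not converge in %d iterations", max_iter))
}

#' Sweep the driven coordinate and trace the finger trajectory
#'
#' Solves a pose for every driven value by continuation (each solution
#' seeds the next guess), which keeps the sweep on one assembly branch.
#' If a point is unassemblable the partial trajectory is returned with a
#' warning naming the failing driven value.
#'
#' @param geom A [linkage_geometry()].
#' @param driven_values Sequence of driven-coordinate values (rad).
#' @param guess Starting pose for the first value.
#' @param tol,max_iter Passed to [solve_pose()].
#'
#' @return A data frame of class `finger_trajectory` with columns
#'   `driven`, `theta1_deg` .. `theta5_deg`, `tip_x_mm`, `tip_y_mm`,
#'   `residual`; the solved poses are attached as attribute `poses`.
#' @export
sweep_trajectory <- function(geom, driven_values, guess, tol = 1e-12,
                             max_iter = 100) {
  poses <- vector("list", length(driven_values))
  cur <- guess
  n_ok <- 0L
  for (i in seq_along(driven_values)) {
    p <- tryCatch(solve_pose(geom, driven_values[i], cur, tol, max_iter),
                  error = function(e) e)
    if (inherits(p, "error")) {
      warning(sprintf("sweep stopped at driven value %g (%s)",
                      driven_values[i], conditionMessage(p)), call. = FALSE)
      break
    }
    poses[[i]] <- p
    cur <- p
    n_ok <- i
  }
  poses <- poses[seq_len(n_ok)]
  df <- data.frame(driven = driven_values[seq_len(n_ok)])
  for (a in ALL_ANGLES)
    df[[paste0(a, "_deg")]] <- vapply(poses, function(p) p$theta[[a]], 0) * 180 / pi
  df$tip_x_mm <- vapply(poses, function(p) p$fingertip[[1]], 0)
  df$tip_y_mm <- vapply(poses, function(p) p$fingertip[[2]], 0)
  df$residual <- vapply(poses, function(p) p$residual, 0)
  attr(df, "poses") <- poses
  class(df) <- c("finger_trajectory", "data.frame")
  df
}

#' Map actuator stroke to the driven crank angle
#'
#' Slider-crank relation `theta2(s) = theta_ref + asin((s - s_ref) /
#' radius)` for the linear actuator pushing a pin at `radius` mm on the
#' crank.
#'
#' @param geom A [linkage_geometry()].
#' @param s_mm Actuator stroke position(s), mm.
#'
#' @return Driven angle(s), rad.
#' @export
stroke_to_crank <- function(geom, s_mm) {
  ratio <- (s_mm - geom$crank$s_ref) / geom$crank$radius
  if (any(abs(ratio) > 1))
    abort_invalid("stroke outside the crank's reachable range")
  geom$crank$theta_ref + asin(ratio)
}

#' @rdname sweep_trajectory
#' @param stroke_mm Actuator stroke positions (mm) mapped through
#'   [stroke_to_crank()].
#' @export
sweep_stroke <- function(geom, stroke_mm, guess = reference_pose(), tol = 1e-12,
                         max_iter = 100) {
  df <- sweep_trajectory(geom, stroke_to_crank(geom, stroke_mm), guess,
                         tol, max_iter)
  df$stroke_mm <- stroke_mm[seq_len(nrow(df))]
  df
}

# Frozen illustrative geometry: the published mechanism's link dimensions
# are not available, so this synthetic stand-in was constructed once (a
# consistent pose forward-placed, then the crank radius calibrated so the
# 10 mm stroke sweeps the proximal joint through its 84.5 deg design
# limit) and is shipped as the package's reference configuration.
REFERENCE_LENGTHS <- c(r1 = 22.036264087073505, r2 = 62.33318146636274548,
                       r3 = 40, r4 = 28.316366059705615, r5 = 25,
                       r6 = 36.37382713681481050, r7 = 19.477148687466979,
                       r8 = 9.2117981053888798)
REFERENCE_ANGLES <- c(theta1 = 1.36111791942029847, theta2 = 3.46942732596646186,
                      theta3 = 0.85827889153548620, theta4 = 1.11726512671623479,
                      theta5 = 0.97128517408677595)
REFERENCE_DELTA <- 0.30659279294617503
REFERENCE_BETA <- -0.97231193188711262
REFERENCE_THETA7 <- -1.43402717783372102
REFERENCE_CRANK_RADIUS <- 10.467700406920363

#' Reference finger geometry and pose
#'
#' An illustrative, synthetic finger-linkage configuration shipped with
#' the package (the physical hand's link dimensions are unpublished).
#' Sweeping the full 10 mm actuator stroke from [reference_pose()] flexes
#' the proximal joint through approximately its configured 84.5-degree
#' limit.
#'
#' @return `reference_geometry()`: a [linkage_geometry()];
#'   `reference_pose()`: the matching extended-finger `finger_pose` at
#'   stroke 0, which selects the assembly branch.
#' @export
reference_geometry <- function() {
  linkage_geometry(REFERENCE_LENGTHS,
                   delta = REFERENCE_DELTA, beta = REFERENCE_BETA,
                   theta7 = REFERENCE_THETA7,
                   crank = list(radius = REFERENCE_CRANK_RADIUS, s_ref = 0,
                                theta_ref = REFERENCE_ANGLES[["theta2"]]))
}

#' @rdname reference_geometry
#' @export
reference_pose <- function() {
  new_pose(reference_geometry(), REFERENCE_ANGLES)
}

#' Read a linkage geometry from a YAML file
#'
#' Expects keys `lengths_mm` (r1..r8), `delta_deg`, `beta_deg`,
#' `theta7_deg`, optional `crank` (`radius_mm`, `s_ref_mm`,
#' `theta_ref_deg`), `driven`, `proximal_limit_deg`, `distal_limit_deg`.
#' Angles are degrees in the file, radians in the object.
#'
#' @param path YAML file path.
#' @return A [linkage_geometry()].
#' @export
read_geometry <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort_format(conditionMessage(e)))
  need <- c("lengths_mm", "delta_deg", "beta_deg", "theta7_deg")
  missing <- setdiff(need, names(doc))
  if (length(missing) > 0)
    abort_format(sprintf("geometry file lacks field(s): %s",
                         paste(missing, collapse = ", ")))
  d2r <- pi / 180
  crank <- if (is.null(doc$crank)) list(radius = 12, s_ref = 0, theta_ref = 0)
           else list(radius = doc$crank$radius_mm, s_ref = doc$crank$s_ref_mm,
                     theta_ref = doc$crank$theta_ref_deg * d2r)
  geom <- linkage_geometry(unlist(doc$lengths_mm),
                           delta = doc$delta_deg * d2r, beta = doc$beta_deg * d2r,
                           theta7 = doc$theta7_deg * d2r, crank = crank,
                           driven = doc$driven %||% "theta2",
                           proximal_limit = doc$proximal_limit_deg %||% 84.5,
                           distal_limit = doc$distal_limit_deg %||% 135)
  if (!is.null(doc$guess_deg))
    attr(geom, "guess") <- unlist(doc$guess_deg) * d2r
  geom
}

`%||%` <- function(a, b) if (is.null(a)) b else a
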