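# Independent kinematics oracles (no Newton): a forward construction of
# consistent geometry+pose pairs, and a progressive grid search.

# Forward-place a consistent pose: choose phalanx/crank/frame angles and
# most lengths, then close both loops by construction (loop B fixes the
# coupler vector r2/theta4; a fixed-point pass aligns theta5 with the
# residual vector r6 of loop A).
construct_linkage <- function(theta1, theta3, theta2, theta7,
                              r1, r3, r4, r5, r7, r8, delta, beta,
                              theta5_init = 1) {
  tip <- c(r3 * cos(theta1) + r5 * cos(theta3),
           r3 * sin(theta1) + r5 * sin(theta3))
  E <- tip + r8 * c(cos(theta7), sin(theta7))
  A1 <- r1 * c(cos(theta2), sin(theta2))
  theta5 <- theta5_init
  for (i in 1:2000) {
    A2 <- E - r7 * c(cos(theta5 + beta), sin(theta5 + beta))
    v2 <- A2 - A1
    theta4 <- atan2(v2[2], v2[1])
    r2 <- sqrt(sum(v2^2))
    v6 <- tip - r4 * c(cos(theta4 + delta), sin(theta4 + delta))
    t5 <- atan2(v6[2], v6[1])
    r6 <- sqrt(sum(v6^2))
    if (abs(t5 - theta5) < 1e-15) break
    theta5 <- t5
  }
  geom <- linkage_geometry(c(r1 = r1, r2 = r2, r3 = r3, r4 = r4, r5 = r5,
                             r6 = r6, r7 = r7, r8 = r8),
                           delta = delta, beta = beta, theta7 = theta7)
  list(geom = geom,
       theta = c(theta1 = theta1, theta2 = theta2, theta3 = theta3,
                 theta4 = theta4, theta5 = theta5))
}

# Progressive grid search over (theta1, theta3); for each grid point the
# first loop is closed exactly by two-link trigonometry (both elbow
# branches) and the second loop's residual is minimized. Independent of
# the package's Newton solver.
grid_solve_oracle <- function(geom, driven_theta2, guess,
                              half_width = 0.7, n_grid = 41, levels = 4) {
  th <- if (inherits(guess, "finger_pose")) guess$theta else guess
  r <- geom$lengths
  center <- c(th[["theta1"]], th[["theta3"]])
  width <- half_width
  best <- NULL
  for (lev in seq_len(levels)) {
    t1s <- seq(center[1] - width, center[1] + width, length.out = n_grid)
    t3s <- seq(center[2] - width, center[2] + width, length.out = n_grid)
    g <- expand.grid(t1 = t1s, t3 = t3s)
    Tx <- r[["r3"]] * cos(g$t1) + r[["r5"]] * cos(g$t3)
    Ty <- r[["r3"]] * sin(g$t1) + r[["r5"]] * sin(g$t3)
    D2 <- Tx^2 + Ty^2
    ca <- (r[["r4"]]^2 + D2 - r[["r6"]]^2) / (2 * r[["r4"]] * sqrt(D2))
    reachable <- abs(ca) <= 1
    phi <- atan2(Ty, Tx)
    best_val <- Inf
    for (elbow in c(1, -1)) {
      t4a <- phi + elbow * acos(pmin(pmax(ca, -1), 1))
      t4 <- t4a - geom$delta
      ux <- Tx - r[["r4"]] * cos(t4a)
      uy <- Ty - r[["r4"]] * sin(t4a)
      t5 <- atan2(uy, ux)
      Bx <- r[["r1"]] * cos(driven_theta2) + r[["r2"]] * cos(t4) +
        r[["r7"]] * cos(t5 + geom$beta) - Tx - r[["r8"]] * cos(geom$theta7)
      By <- r[["r1"]] * sin(driven_theta2) + r[["r2"]] * sin(t4) +
        r[["r7"]] * sin(t5 + geom$beta) - Ty - r[["r8"]] * sin(geom$theta7)
      val <- Bx^2 + By^2
      val[!reachable] <- Inf
      i <- which.min(val)
      if (val[i] < best_val) {
        best_val <- val[i]
        best <- c(theta1 = g$t1[i], theta2 = driven_theta2,
                  theta3 = g$t3[i], theta4 = t4[i], theta5 = t5[i])
      }
    }
    center <- c(best[["theta1"]], best[["theta3"]])
    width <- 4 * (2 * width / (n_grid - 1))
  }
  best
}
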