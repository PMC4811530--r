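# Independent oracles and shared fixtures for the test suite.

# --- quaternion oracle for angular velocity ----------------------------------
# A rotation vector r (magnitude tan(theta/2)) corresponds to the unit
# quaternion q = (1, r) / sqrt(1 + |r|^2). The angular velocity is
# omega = 2 * qdot * q^-1 (vector part), with qdot estimated by the same
# finite-difference stencils as the implementation under test. This path never
# touches the package's rotation-vector velocity formula.
quat_from_rotvec <- function(r) {
  q <- c(1, r) / sqrt(1 + sum(r^2))
  q
}

quat_mult <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] + cross3_oracle(a[2:4], b[2:4]))
}

quat_conj <- function(q) c(q[1], -q[2:4])

cross3_oracle <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

omega_quaternion_oracle <- function(t, r) {
  n <- nrow(r)
  dt <- mean(diff(t))
  Q <- t(apply(r, 1, quat_from_rotvec))
  Qd <- Q
  Qd[2:(n - 1), ] <- (Q[3:n, ] - Q[1:(n - 2), ]) / (2 * dt)
  Qd[1, ] <- (Q[2, ] - Q[1, ]) / dt
  Qd[n, ] <- (Q[n, ] - Q[n - 1, ]) / dt
  w <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    p <- quat_mult(Qd[i, ], quat_conj(Q[i, ]))
    w[i, ] <- 2 * p[2:4]           # rad/s
  }
  w * 180 / pi
}

# --- brute-force minimizer for the rotation-center objective ------------------
# Exhaustive search of sum_i d(point, line_i)^2 on a square lattice.
brute_force_center <- function(lines, center_guess, half_width = 2,
                               step = 0.01) {
  ys <- seq(center_guess[1] - half_width, center_guess[1] + half_width,
            by = step)
  zs <- seq(center_guess[2] - half_width, center_guess[2] + half_width,
            by = step)
  obj <- function(pt) {
    s <- 0
    for (ln in lines) {
      v <- pt - ln$point
      perp <- v - sum(v * ln$direction) * ln$direction
      s <- s + sum(perp^2)
    }
    s
  }
  best <- c(NA, NA); best_val <- Inf
  for (yv in ys) for (zv in zs) {
    v <- obj(c(yv, zv))
    if (v < best_val) { best_val <- v; best <- c(yv, zv) }
  }
  best
}

# --- shared synthetic fixtures -------------------------------------------------

default_model <- function() eye_model()

render_model <- function() {
  # geometry sized for the 240x160 render canvas: 60/48 px ellipse scale
  eye_model(center = c(120, 80), R = 55, pupil_radius = 30,
            freckle_offset = 40, freckle_radius_px = 4)
}

render_cfg <- function() {
  # pupil thresholds at the midpoint of the local edge ramp: with the default
  # 140->200 background gradient the left pupil edge sits near gray 162 and
  # the right near 177, against pupil gray 25
  detection_config(threshold_left = 94, threshold_right = 101,
                   threshold_freckle = 100, threshold_marker = 128)
}

pupil_rois <- function(pr, pad = 8) {
  half <- pr$major_len / 2
  cy <- pr$pupil[1]; cz <- pr$pupil[2]
  list(left = roi_rect(cy - half - pad, cz - half - pad, cy - 2, cz + half + pad),
       right = roi_rect(cy + 2, cz - half - pad, cy + half + pad, cz + half + pad))
}

expect_vog_error <- function(expr, class) {
  expect_error(expr, class = class)
}
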