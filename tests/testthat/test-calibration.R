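# Center-of-rotation estimation, rotation radii (pupil and freckle), and
# reference-frame selection.

test_that("minor-axis line runs perpendicular to the major axis", {
  e <- pupil_ellipse(10, 10, major_len = 20, minor_len = 12,
                     orientation_deg = 0)
  ln <- minor_axis_line(e)
  expect_equal(ln$point, c(10, 10))
  expect_equal(abs(ln$direction), c(0, 1), tolerance = 1e-12)

  circ <- pupil_ellipse(10, 10, major_len = 20, minor_len = 20,
                        orientation_deg = 0)
  expect_vog_error(minor_axis_line(circ), "vog3d_degeneracy_error")
})

test_that("two perpendicular lines intersect at the rotation center", {
  lines <- list(list(point = c(5, 0), direction = c(0, 1)),
                list(point = c(0, 7), direction = c(1, 0)))
  expect_equal(estimate_rotation_center(lines), c(5, 7), tolerance = 1e-12)
})

test_that("near-parallel line bundles are rejected", {
  lines <- list(list(point = c(0, 0), direction = c(1, 0)),
                list(point = c(0, 1), direction = c(1, 1e-9)))
  expect_vog_error(estimate_rotation_center(lines), "vog3d_degeneracy_error")
})

test_that("minor axes of a noise-free swirl pass through the true center", {
  model <- default_model()
  traj <- generate_trajectory(model, motion_swirl(tilt_deg = 15, turns = 1,
                                                  n_frames = 6))
  lines <- lapply(seq_len(6), function(i) {
    e <- pupil_ellipse(traj$frames$yp[i], traj$frames$zp[i],
                       traj$frames$major_len[i], traj$frames$minor_len[i],
                       traj$frames$orientation[i])
    minor_axis_line(e)
  })
  # each line contains the projected rotation center
  for (ln in lines) {
    v <- model$center - ln$point
    perp <- v - sum(v * ln$direction) * ln$direction
    expect_lt(sqrt(sum(perp^2)), 1e-9)
  }
  expect_equal(estimate_rotation_center(lines), model$center,
               tolerance = 1e-9)
})

test_that("least-squares center matches a brute-force grid minimizer", {
  set.seed(21)
  true_center <- c(50, 40)
  lines <- lapply(1:50, function(i) {
    th <- runif(1, 0, pi)
    d <- c(cos(th), sin(th))
    # line through the center, then perturbed in angle
    th_n <- th + rnorm(1, 0, 0.05)
    list(point = true_center + runif(1, -15, 15) * d,
         direction = c(cos(th_n), sin(th_n)))
  })
  est <- estimate_rotation_center(lines)
  bf <- brute_force_center(lines, est, half_width = 0.5, step = 0.01)
  expect_lt(max(abs(est - bf)), 0.011)
})

test_that("pupil radius follows the sine/cosine elimination", {
  # 3-4-5: image offset 3 px, minor/major = 4/5 -> R = 5
  e <- pupil_ellipse(3, 0, major_len = 10, minor_len = 8, orientation_deg = 90)
  expect_equal(compute_pupil_radius(e, c(0, 0)), 5, tolerance = 1e-12)
  # frontal gaze is excluded, not extrapolated
  circ <- pupil_ellipse(0, 0, major_len = 10, minor_len = 10,
                        orientation_deg = 0)
  expect_true(is.na(compute_pupil_radius(circ, c(0, 0))))
})

test_that("radius aggregation averages retained frames", {
  expect_equal(aggregate_radius(5), 5)
  expect_equal(aggregate_radius(c(4, 6)), 5)
  expect_equal(aggregate_radius(c(4, NA, 6)), 5)
  expect_vog_error(aggregate_radius(c(NA_real_, NA_real_)),
                   "vog3d_calibration_error")
})

test_that("per-frame radii on a noise-free swirl equal the true R exactly", {
  model <- default_model()
  traj <- generate_trajectory(model, motion_swirl(tilt_deg = 18, turns = 2,
                                                  n_frames = 100))
  Rs <- vapply(seq_len(100), function(i) {
    e <- pupil_ellipse(traj$frames$yp[i], traj$frames$zp[i],
                       traj$frames$major_len[i], traj$frames$minor_len[i],
                       traj$frames$orientation[i])
    compute_pupil_radius(e, model$center)
  }, numeric(1))
  expect_lt(max(abs(Rs - model$R)), 1e-9)
  expect_equal(aggregate_radius(Rs), model$R, tolerance = 1e-9)
})

test_that("freckle radius combines R with the in-plane offset", {
  # circle of radius 3, freckle on the edge (a = b), R = 4 -> R' = 5
  circ <- pupil_ellipse(0, 0, major_len = 6, minor_len = 6 - 1e-9,
                        orientation_deg = 0)
  expect_equal(compute_freckle_radius(circ, c(3, 0), R = 4), 5,
               tolerance = 1e-6)
  # algebraic identity: a = b and major/2 = b gives R' = sqrt(R^2 + b^2)
  e <- pupil_ellipse(0, 0, major_len = 14, minor_len = 14 - 1e-9,
                     orientation_deg = 0)
  expect_equal(compute_freckle_radius(e, c(7, 0), R = 10), sqrt(100 + 49),
               tolerance = 1e-6)
  # freckle strictly inside the pupil is a geometry error
  expect_vog_error(compute_freckle_radius(e, c(2, 0), R = 10),
                   "vog3d_geometry_error")
})

test_that("freckle radius is recovered exactly on noise-free frames", {
  model <- default_model()
  true_Rp <- sqrt(model$R^2 + model$freckle_offset^2)
  traj <- generate_trajectory(model, motion_swirl(tilt_deg = 18, turns = 2,
                                                  n_frames = 60))
  Rps <- vapply(seq_len(60), function(i) {
    e <- pupil_ellipse(traj$frames$yp[i], traj$frames$zp[i],
                       traj$frames$major_len[i], traj$frames$minor_len[i],
                       traj$frames$orientation[i])
    compute_freckle_radius(e, c(traj$frames$yi[i], traj$frames$zi[i]),
                           R = model$R)
  }, numeric(1))
  expect_lt(max(abs(Rps - true_Rp)), 1e-9)
  expect_true(all(Rps >= model$R))
})

test_that("reference frame is the pupil position nearest the center", {
  frames <- data.frame(yp = c(3, 1, 2), zp = c(0, 0, 0))
  expect_equal(select_reference_frame(frames, c(0, 0)), 2)
  expect_equal(select_reference_frame(data.frame(yp = 5, zp = 5), c(0, 0)), 1)
  # equidistant frames resolve to the earlier index
  tie <- data.frame(yp = c(2, -2, 0), zp = c(0, 0, 9))
  expect_equal(select_reference_frame(tie, c(0, 0)), 1)
})

test_that("full calibration recovers the generating model", {
  model <- default_model()
  traj <- generate_trajectory(model, motion_swirl())
  # append a frontal-gaze frame: excluded from center/radius estimation by
  # the eccentricity rule, but the nearest to the center and thus the
  # reference position
  frontal <- generate_trajectory(model, motion_angles(c(0, 0, 1), 0))$frames
  cal <- calibrate(rbind(traj$frames, frontal))
  expect_equal(cal$center, model$center, tolerance = 1e-9)
  expect_equal(cal$R, model$R, tolerance = 1e-9)
  expect_equal(cal$R_prime, sqrt(model$R^2 + model$freckle_offset^2),
               tolerance = 1e-9)
  expect_gte(cal$R_prime, cal$R)
  expect_equal(cal$ref_pupil_3d, model$ref_pupil_3d, tolerance = 1e-6)
})

test_that("calibration is invariant to frame order", {
  model <- default_model()
  traj <- generate_trajectory(model, motion_swirl(n_frames = 120))
  cal1 <- calibrate(traj$frames)
  set.seed(5)
  perm <- sample(nrow(traj$frames))
  cal2 <- calibrate(traj$frames[perm, ])
  expect_equal(cal1$center, cal2$center, tolerance = 1e-9)
  expect_equal(cal1$R, cal2$R, tolerance = 1e-9)
  expect_equal(cal1$R_prime, cal2$R_prime, tolerance = 1e-9)
})

test_that("calibration fails without enough usable frames", {
  # all frames near-frontal: excluded by the eccentricity rule
  frames <- data.frame(t = 0:4 / 240, yp = 120, zp = 80, major_len = 30,
                       minor_len = 29.99, orientation = 0, yi = 140, zi = 80)
  expect_vog_error(calibrate(frames), "vog3d_calibration_error")
})
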