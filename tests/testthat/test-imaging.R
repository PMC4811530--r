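# Image-based landmark extraction: contrast, pupil ellipse, freckle, turntable.

test_that("contrast stretch maps the percentile range onto full scale", {
  const <- matrix(77, 10, 10)
  expect_equal(enhance_contrast(const), const)
  two <- matrix(rep(c(50, 100), each = 200), 20, 20)
  out <- enhance_contrast(two)
  expect_equal(sort(unique(as.numeric(out))), c(0, 255))
})

test_that("contrast stretch is invariant to affine intensity changes", {
  set.seed(3)
  img <- matrix(runif(400, 30, 220), 20, 20)
  expect_equal(enhance_contrast(0.5 * img + 20), enhance_contrast(img),
               tolerance = 1e-10)
  # idempotent up to the clamped tails
  once <- enhance_contrast(img)
  expect_lt(max(abs(enhance_contrast(once) - once)), 3)
})

test_that("direct least-squares fit recovers an exact ellipse", {
  th <- seq(0, 2 * pi, length.out = 40)[-40]
  phi <- 25 * pi / 180
  A <- 31; B <- 24
  y <- 120 + A * cos(th) * cos(phi) - B * sin(th) * sin(phi)
  z <- 80 + A * cos(th) * sin(phi) + B * sin(th) * cos(phi)
  e <- fit_ellipse(y, z)
  expect_equal(e$center, c(120, 80), tolerance = 1e-8)
  expect_equal(e$major_len, 2 * A, tolerance = 1e-8)
  expect_equal(e$minor_len, 2 * B, tolerance = 1e-8)
  expect_equal(e$orientation, 25, tolerance = 1e-6)
  expect_vog_error(fit_ellipse(c(1, 2, 3), c(1, 2, 3)),
                   "vog3d_detection_error")
})

test_that("pupil detection recovers the rendered ellipse", {
  model <- render_model()
  M <- rodrigues_matrix(c(0, 1, 0), -20)
  img <- render_eye_frame(model, M)
  pr <- project_eye(model, M)
  rois <- pupil_rois(pr)
  e <- detect_pupil(img, render_cfg(), rois$left, rois$right)
  expect_lt(sqrt(sum((e$center - pr$pupil)^2)), 0.5)
  expect_lt(abs(e$major_len - pr$major_len) / pr$major_len, 0.01)
  expect_lt(abs(e$minor_len - pr$minor_len) / pr$minor_len, 0.01)
})

test_that("a uniform bright image yields a detection failure", {
  img <- matrix(200, 160, 240)
  expect_vog_error(
    detect_pupil(img, render_cfg(), roi_rect(80, 50, 118, 110),
                 roi_rect(122, 50, 160, 110)),
    "vog3d_detection_error")
})

test_that("per-side thresholds beat a single shared threshold under a gradient", {
  model <- render_model()
  M <- rodrigues_matrix(c(0, 1, 0), -18)
  # strong illumination gradient: the left pupil edge ramps toward gray ~155,
  # the right toward ~185, so the per-side ramp midpoints differ
  img <- render_eye_frame(model, M, bg_left = 110, bg_right = 230,
                          softness = 4)
  pr <- project_eye(model, M)
  rois <- pupil_rois(pr)
  cfg_split <- detection_config(threshold_left = 90, threshold_right = 105,
                                threshold_freckle = 100)
  cfg_shared <- detection_config(threshold_left = 90, threshold_right = 90,
                                 threshold_freckle = 100)
  e_split <- detect_pupil(img, cfg_split, rois$left, rois$right)
  e_shared <- detect_pupil(img, cfg_shared, rois$left, rois$right)
  err <- function(e) sqrt(sum((e$center - pr$pupil)^2))
  expect_lt(err(e_split), 0.5)
  expect_gt(err(e_shared), err(e_split))
})

test_that("ellipse recovery holds over random poses", {
  model <- render_model()
  cfg <- render_cfg()
  set.seed(17)
  for (i in 1:100) {
    ax <- c(0, rnorm(2)); ax <- ax / sqrt(sum(ax^2))
    M <- rodrigues_matrix(ax, runif(1, 8, 24) * sample(c(-1, 1), 1))
    pr <- project_eye(model, M)
    img <- render_eye_frame(model, M)
    rois <- pupil_rois(pr)
    e <- detect_pupil(img, cfg, rois$left, rois$right)
    expect_lt(sqrt(sum((e$center - pr$pupil)^2)), 0.5)
    expect_lt(abs(e$major_len - pr$major_len) / pr$major_len, 0.01)
    expect_lt(abs(e$minor_len - pr$minor_len) / pr$minor_len, 0.01)
    dor <- abs(e$orientation - pr$orientation) %% 180
    expect_lt(min(dor, 180 - dor), 1)
  }
})

test_that("freckle centroid is recovered from the annular ROI", {
  model <- render_model()
  M <- rodrigues_matrix(c(0, 1, 0), -15)
  img <- render_eye_frame(model, M)
  pr <- project_eye(model, M)
  rois <- pupil_rois(pr)
  e <- detect_pupil(img, render_cfg(), rois$left, rois$right)
  fk <- detect_freckle(img, e, render_cfg(), roi_annulus(2, 20))
  expect_lt(sqrt(sum((fk - pr$freckle)^2)), 0.3)
})

test_that("absent freckle produces a gap, and the area filter selects blobs", {
  model <- render_model()
  M <- rodrigues_matrix(c(0, 1, 0), -15)
  img <- render_eye_frame(model, M, freckle = FALSE)
  pr <- project_eye(model, M)
  rois <- pupil_rois(pr)
  e <- detect_pupil(img, render_cfg(), rois$left, rois$right)
  expect_null(detect_freckle(img, e, render_cfg(), roi_annulus(2, 20)))

  # two dark blobs in the annulus: area 400 exceeds max_area 200, the ~40 px^2
  # blob is chosen
  img2 <- matrix(200, 160, 240)
  e2 <- pupil_ellipse(120, 80, 60, 60 - 1e-9, 0)
  paint_disk <- function(img, cy, cz, rad, val) {
    yy <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
    zz <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
    img[(yy - cy)^2 + (zz - cz)^2 <= rad^2] <- val
    img
  }
  img2 <- paint_disk(img2, 160, 80, 3.5, 50)    # ~38 px^2, ~10 px beyond edge
  img2 <- paint_disk(img2, 120, 122, 11.2, 50)  # ~394 px^2
  cfg <- detection_config(80, 80, 100, min_area = 4, max_area = 200)
  fk <- detect_freckle(img2, e2, cfg, roi_annulus(2, 25))
  expect_lt(sqrt(sum((fk - c(160, 80))^2)), 0.5)
})

test_that("marker line angles follow the atan2 convention modulo 180", {
  expect_equal(marker_line_angle(c(0, 0), c(10, 0)), 0)
  expect_equal(marker_line_angle(c(0, 0), c(0, 10)), 90)
  expect_equal(marker_line_angle(c(0, 10), c(0, 0)), 90)
})

test_that("turntable tracking recovers a sinusoidal rotation", {
  t <- seq(0, 2, by = 1 / 60)
  true_angle <- 20 * sin(2 * pi * 0.5 * t)
  frames <- render_table_frames(true_angle)
  tr <- track_turntable(frames, render_cfg(), frame_rate = 60)
  expect_lt(max(abs(tr$angle - (true_angle - true_angle[1]))), 0.1)
})

test_that("turntable tracking is linear for uniform rotation and unwraps sweeps", {
  angles <- seq(0, 360, by = 4)   # a full turn: crosses the 180-degree ambiguity
  frames <- render_table_frames(angles)
  tr <- track_turntable(frames, render_cfg(), frame_rate = 60)
  expect_true(all(diff(tr$angle) > 0))
  slope <- coef(lm(tr$angle ~ tr$t))[2]
  expect_lt(abs(slope - 4 * 60) / (4 * 60), 0.001)
  # constant angle stays constant
  frames_const <- render_table_frames(rep(30, 5))
  trc <- track_turntable(frames_const, render_cfg(), frame_rate = 60)
  expect_lt(max(abs(trc$angle)), 1e-6)
})

test_that("major axis stays constant while the minor axis tracks gaze", {
  model <- render_model()
  cfg <- render_cfg()
  angles <- seq(-22, 22, by = 4)
  majors <- minors <- numeric(length(angles))
  for (i in seq_along(angles)) {
    M <- rodrigues_matrix(c(0, 0, 1), angles[i])
    pr <- project_eye(model, M)
    img <- render_eye_frame(model, M)
    rois <- pupil_rois(pr)
    e <- detect_pupil(img, cfg, rois$left, rois$right)
    majors[i] <- e$major_len
    minors[i] <- e$minor_len
  }
  expect_lt((max(majors) - min(majors)) / mean(majors), 0.01)
  expect_gt((max(minors) - min(minors)) / mean(minors), 0.05)
})
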