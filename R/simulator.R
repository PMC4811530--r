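# Forward model: ground-truth synthetic eye trajectories and rendered eye /
# turntable images.
#
# The model implements the four geometric assumptions behind the
# reconstruction: (1) the eye rotates about a fixed point; (2) the pupil edge
# is a circle and the edge and iris freckle lie in one plane; (3) the distance
# from the rotation center to the pupil circle is constant; (4) the camera is
# orthographic (projection onto a plane perpendicular to the camera axis, unit
# magnification: pixels are model units).

#' Synthetic eye model
#'
#' Geometry of the simulated eye. The pupil center sits at distance `R` from
#' the center of eye rotation along the gaze direction; the pupil edge is a
#' circle of radius `pupil_radius` in the plane through the pupil center
#' perpendicular to gaze; the freckle lies in that same plane at in-plane
#' distance `freckle_offset` from the pupil center (so its rotation radius is
#' \eqn{\sqrt{R^2 + d^2}}), at polar angle `freckle_angle_deg` within the
#' plane.
#'
#' @param center projected rotation center (yc, zc) in pixels.
#' @param R rotation radius of the pupil center, pixels.
#' @param pupil_radius radius of the pupil circle, pixels
#'   (0 < pupil_radius < R).
#' @param freckle_offset in-plane distance of the freckle from the pupil
#'   center, pixels (> pupil_radius: the freckle is on the iris, outside the
#'   pupil).
#' @param freckle_angle_deg polar angle of the freckle within the pupil plane.
#' @param reference_gaze unit gaze direction at the reference position
#'   (default: the camera axis +X).
#' @param freckle_radius_px rendered freckle disk radius (rendering only).
#' @return object of class `eye_model`.
#' @export
eye_model <- function(center = c(120, 80), R = 40, pupil_radius = 15,
                      freckle_offset = 22, freckle_angle_deg = 0,
                      reference_gaze = c(1, 0, 0), freckle_radius_px = 4) {
  if (!(R > pupil_radius && pupil_radius > 0))
    stop_vog("need R > pupil_radius > 0", "vog3d_input_error")
  if (!(freckle_offset > pupil_radius))
    stop_vog("freckle must lie outside the pupil (freckle_offset > pupil_radius)",
             "vog3d_input_error")
  g <- reference_gaze / sqrt(sum(reference_gaze^2))
  # in-plane orthonormal basis of the pupil plane at the reference position
  up <- if (abs(g[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e2 <- cross3(up, g); e2 <- e2 / sqrt(sum(e2^2))
  e3 <- cross3(g, e2)
  a <- deg2rad(freckle_angle_deg)
  structure(list(center = center, R = R, pupil_radius = pupil_radius,
                 freckle_offset = freckle_offset,
                 freckle_angle_deg = freckle_angle_deg,
                 reference_gaze = g,
                 freckle_radius_px = freckle_radius_px,
                 ref_pupil_3d = R * g,
                 ref_freckle_3d = R * g +
                   freckle_offset * (cos(a) * e2 + sin(a) * e3),
                 R_prime = sqrt(R^2 + freckle_offset^2)),
            class = "eye_model")
}

#' Motion specifications
#'
#' Rotation sequences consumed by [generate_trajectory()]:
#' `motion_angles` rotates about one fixed unit axis through an explicit list
#' of angles; `motion_sinusoid` oscillates about a fixed axis with
#' `angle(t) = amplitude_deg * sin(2 pi f t + phase)`; `motion_swirl` sweeps
#' the gaze on a cone of half-angle `tilt_deg` around the reference direction
#' (the circular eye movement used for calibration).
#'
#' @param axis unit rotation axis.
#' @param angles_deg rotation angles in degrees, one per frame.
#' @param rate sampling rate in Hz.
#' @param amplitude_deg,freq_hz,phase,duration sinusoid parameters (peak angle
#'   in degrees, Hz, radians, seconds).
#' @param tilt_deg,turns,n_frames swirl parameters: cone half-angle, number of
#'   sweeps, number of frames.
#' @return object of class `vog3d_motion`.
#' @export
motion_angles <- function(axis, angles_deg, rate = 240) {
  axis <- axis / sqrt(sum(axis^2))
  structure(list(type = "angles", axis = axis, angles = angles_deg,
                 rate = rate), class = "vog3d_motion")
}

#' @rdname motion_angles
#' @export
motion_sinusoid <- function(amplitude_deg, freq_hz, phase = 0, duration = 10,
                            rate = 240, axis = c(0, 0, 1)) {
  if (rate <= 2 * freq_hz)
    stop_vog("sample rate must exceed twice the stimulus frequency",
             "vog3d_input_error")
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  motion_angles(axis, amplitude_deg * sin(2 * pi * freq_hz * t + phase), rate)
}

#' @rdname motion_angles
#' @export
motion_swirl <- function(tilt_deg = 15, turns = 3, n_frames = 720,
                         rate = 240) {
  psi <- 2 * pi * turns * (seq_len(n_frames) - 1) / n_frames
  structure(list(type = "swirl", tilt = tilt_deg, psi = psi, rate = rate),
            class = "vog3d_motion")
}

# list of per-frame rotation matrices + time stamps
motion_matrices <- function(motion) {
  stopifnot(inherits(motion, "vog3d_motion"))
  if (motion$type == "angles") {
    mats <- lapply(motion$angles, function(a) rodrigues_matrix(motion$axis, a))
    n <- length(mats)
  } else {
    mats <- mapply(function(ps, tl) rodrigues_matrix(c(0, cos(ps), sin(ps)), tl),
                   motion$psi, MoreArgs = list(tl = motion$tilt),
                   SIMPLIFY = FALSE)
    n <- length(mats)
  }
  list(mats = mats, t = (seq_len(n) - 1) / motion$rate)
}

#' Orthographic projection of the eye model under a pose
#'
#' Rotates the reference landmark geometry by the pose matrix and drops the X
#' coordinate (orthographic camera). The pupil ellipse has constant major axis
#' 2 * pupil_radius and minor axis 2 * pupil_radius * cos(theta), where theta
#' is the angle between the rotated gaze and the camera axis; the minor axis
#' is aligned with the projected gaze-tilt direction, so its extension passes
#' through the projected rotation center.
#'
#' @param model an [eye_model()].
#' @param pose 3x3 rotation matrix (eye pose relative to the reference
#'   position).
#' @return list with `pupil` (y, z), `freckle` (y, z), `major_len`,
#'   `minor_len`, `orientation` (degrees), `gaze` (rotated unit gaze).
#' @export
project_eye <- function(model, pose) {
  stopifnot(inherits(model, "eye_model"))
  g <- as.numeric(pose %*% model$reference_gaze)
  if (g[1] <= 0)
    stop_vog("gaze beyond 90 degrees from the camera axis: eye occluded",
             "vog3d_occlusion_error")
  p3 <- as.numeric(pose %*% model$ref_pupil_3d)
  f3 <- as.numeric(pose %*% model$ref_freckle_3d)
  costh <- g[1]
  tilt2 <- sqrt(g[2]^2 + g[3]^2)
  orient <- if (tilt2 < 1e-12) 0 else
    (atan2(g[3], g[2]) * 180 / pi + 90) %% 180
  list(pupil = model$center + p3[2:3],
       freckle = model$center + f3[2:3],
       major_len = 2 * model$pupil_radius,
       minor_len = 2 * model$pupil_radius * costh,
       orientation = orient,
       gaze = g)
}

#' Generate a ground-truth landmark trajectory
#'
#' Projects the eye model through a motion sequence, producing the per-frame
#' landmark table (as emitted by the imaging stage) together with the true
#' rotation vectors. Optional zero-mean Gaussian pixel noise is added to the
#' landmark coordinates (seeded, reproducible).
#'
#' @param model an [eye_model()].
#' @param motion a motion spec (see [motion_angles()]).
#' @param noise_sd landmark noise standard deviation in pixels.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return list with `frames` (data.frame `t`, `yp`, `zp`, `major_len`,
#'   `minor_len`, `orientation`, `yi`, `zi`), `truth` (data.frame `t`, `rx`,
#'   `ry`, `rz`), `poses` (list of rotation matrices), and `model`.
#' @export
generate_trajectory <- function(model, motion, noise_sd = 0, seed = NULL) {
  mm <- motion_matrices(motion)
  n <- length(mm$mats)
  pr <- lapply(mm$mats, function(M) project_eye(model, M))
  frames <- data.frame(
    t = mm$t,
    yp = vapply(pr, function(x) x$pupil[1], numeric(1)),
    zp = vapply(pr, function(x) x$pupil[2], numeric(1)),
    major_len = vapply(pr, function(x) x$major_len, numeric(1)),
    minor_len = vapply(pr, function(x) x$minor_len, numeric(1)),
    orientation = vapply(pr, function(x) x$orientation, numeric(1)),
    yi = vapply(pr, function(x) x$freckle[1], numeric(1)),
    zi = vapply(pr, function(x) x$freckle[2], numeric(1)))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    frames$yp <- frames$yp + stats::rnorm(n, 0, noise_sd)
    frames$zp <- frames$zp + stats::rnorm(n, 0, noise_sd)
    frames$yi <- frames$yi + stats::rnorm(n, 0, noise_sd)
    frames$zi <- frames$zi + stats::rnorm(n, 0, noise_sd)
  }
  rv <- t(vapply(mm$mats, rotation_vector_from_matrix, numeric(3)))
  truth <- data.frame(t = mm$t, rx = rv[, 1], ry = rv[, 2], rz = rv[, 3])
  list(frames = frames, truth = truth, poses = mm$mats, model = model)
}

#' Simulate a sinusoidal VOR recording
#'
#' Produces synchronized turntable and eye streams for a sinusoidal rotation:
#' the table rotates with peak angular velocity `peak_velocity` at frequency
#' `freq`; the eye counter-rotates about the Z axis with amplitude ratio
#' `gain` and phase lead `phase_lead_deg` relative to the ideal compensatory
#' response. Landmark noise is optional and seeded.
#'
#' @param model an [eye_model()].
#' @param peak_velocity table peak angular velocity, degrees/second.
#' @param freq stimulus frequency, Hz.
#' @param gain true VOR gain (eye/table velocity amplitude ratio).
#' @param phase_lead_deg true phase lead of the eye in degrees.
#' @param duration recording length in seconds.
#' @param rate frame rate in Hz.
#' @param noise_sd,seed landmark noise (pixels) and RNG seed.
#' @return list with `table` (data.frame `t`, `angle` in degrees), `frames`
#'   (landmark table), `truth` (true rotation vectors), `gain`, `phase_deg`.
#' @export
simulate_vor <- function(model, peak_velocity = 20, freq = 0.5, gain = 0.6,
                         phase_lead_deg = 0, duration = 10, rate = 240,
                         noise_sd = 0, seed = NULL) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  table_angle <- peak_velocity / (2 * pi * freq) * sin(2 * pi * freq * t)
  phi <- deg2rad(phase_lead_deg)
  eye_angle <- -(gain * peak_velocity) / (2 * pi * freq) *
    sin(2 * pi * freq * t + phi)
  traj <- generate_trajectory(model, motion_angles(c(0, 0, 1), eye_angle, rate),
                              noise_sd = noise_sd, seed = seed)
  list(table = data.frame(t = t, angle = table_angle),
       frames = traj$frames, truth = traj$truth,
       gain = gain, phase_deg = phase_lead_deg)
}

# signed distance helpers for anti-aliased rendering: coverage ramps linearly
# from 1 to 0 across `softness` pixels around the shape boundary
.coverage <- function(signed_dist, softness) {
  pmin(pmax(0.5 - signed_dist / softness, 0), 1)
}

#' Render a synthetic eye frame
#'
#' Draws the projected pupil ellipse (dark) and freckle disk (intermediate
#' gray) on a bright iris/sclera background with a linear left-right
#' illumination gradient, with anti-aliased (linearly ramped) edges. The
#' gradient emulates the brightness asymmetry produced by an off-axis infrared
#' light source, which is why the left and right pupil edges are thresholded
#' separately during detection.
#'
#' @param model an [eye_model()].
#' @param pose 3x3 rotation matrix.
#' @param width,height canvas size in pixels.
#' @param bg_left,bg_right background gray levels at the left/right image edge.
#' @param pupil_gray,freckle_gray shape gray levels.
#' @param freckle draw the freckle disk (default TRUE).
#' @param softness edge ramp width in pixels.
#' @param noise_sd optional Gaussian pixel-intensity noise (gray levels).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return gray image matrix (z-up), values in [0, 255].
#' @export
render_eye_frame <- function(model, pose, width = 240, height = 160,
                             bg_left = 140, bg_right = 200, pupil_gray = 25,
                             freckle_gray = 60, freckle = TRUE, softness = 1.5,
                             noise_sd = 0, seed = NULL) {
  pr <- project_eye(model, pose)
  A <- pr$major_len / 2; B <- pr$minor_len / 2
  margin <- A + 2
  if (pr$pupil[1] - margin < 1 || pr$pupil[1] + margin > width ||
      pr$pupil[2] - margin < 1 || pr$pupil[2] + margin > height)
    stop_vog("eye geometry outside the canvas", "vog3d_input_error")
  yy <- matrix(seq_len(width), height, width, byrow = TRUE)
  zz <- matrix(seq_len(height), height, width)
  img <- bg_left + (bg_right - bg_left) * (yy - 1) / (width - 1)

  dy <- yy - pr$pupil[1]; dz <- zz - pr$pupil[2]
  phi <- deg2rad(pr$orientation)
  u1 <- cos(phi) * dy + sin(phi) * dz
  u2 <- -sin(phi) * dy + cos(phi) * dz
  m <- sqrt((u1 / A)^2 + (u2 / B)^2)
  d0 <- sqrt(dy^2 + dz^2)
  sd_pupil <- ifelse(d0 < 1e-9, -B, d0 * (1 - 1 / pmax(m, 1e-12)))
  cov <- .coverage(sd_pupil, softness)
  img <- img * (1 - cov) + pupil_gray * cov

  if (freckle) {
    if (pr$freckle[1] < 1 || pr$freckle[1] > width ||
        pr$freckle[2] < 1 || pr$freckle[2] > height)
      stop_vog("freckle outside the canvas", "vog3d_input_error")
    df <- sqrt((yy - pr$freckle[1])^2 + (zz - pr$freckle[2])^2) -
      model$freckle_radius_px
    covf <- .coverage(df, softness)
    img <- img * (1 - covf) + freckle_gray * covf
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                        nrow(img), ncol(img))
  }
  img[img < 0] <- 0
  img[img > 255] <- 255
  img
}

#' Render turntable marker frames
#'
#' Draws two bright anti-aliased disks at a fixed radius from the image center,
#' diametrically opposed, rotated by each angle of the series — the fixture
#' geometry for [track_turntable()].
#'
#' @param angles_deg table angle per frame, degrees.
#' @param width,height canvas size.
#' @param arm marker distance from the image center, pixels.
#' @param marker_radius disk radius, pixels.
#' @param bg,marker_gray background and marker gray levels.
#' @param softness edge ramp width in pixels.
#' @return list of gray image matrices.
#' @export
render_table_frames <- function(angles_deg, width = 220, height = 220,
                                arm = 80, marker_radius = 6, bg = 20,
                                marker_gray = 230, softness = 1.5) {
  cy <- (width + 1) / 2; cz <- (height + 1) / 2
  if (arm + marker_radius + 2 > min(cy, cz))
    stop_vog("markers outside the canvas", "vog3d_input_error")
  yy <- matrix(seq_len(width), height, width, byrow = TRUE)
  zz <- matrix(seq_len(height), height, width)
  lapply(angles_deg, function(a) {
    th <- deg2rad(a)
    img <- matrix(bg, height, width)
    for (sgn in c(1, -1)) {
      my <- cy + sgn * arm * cos(th)
      mz <- cz + sgn * arm * sin(th)
      d <- sqrt((yy - my)^2 + (zz - mz)^2) - marker_radius
      cov <- .coverage(d, softness)
      img <- img * (1 - cov) + marker_gray * cov
    }
    img
  })
}
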