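# Lift 2D landmarks onto their rotation spheres and convert per-frame landmark
# pairs into rotation vectors relative to the reference position.

#' Lift a 2D landmark onto its rotation sphere
#'
#' Under orthographic projection along the camera axis (+X), a landmark that
#' moves on a sphere of the given radius about the center of eye rotation has
#' 3D coordinates
#' \deqn{(\sqrt{\rho^2 - (y-y_c)^2 - (z-z_c)^2},\; y-y_c,\; z-z_c)}
#' with the positive root: the imaged hemisphere faces the camera. Radicands
#' slightly negative from measurement noise (within `tol * radius^2`) are
#' clamped to zero; larger violations raise an error rather than silently
#' hiding calibration drift.
#'
#' @param p landmark (y, z) in pixels.
#' @param center rotation center (yc, zc) in pixels.
#' @param radius rotation radius in pixels.
#' @param tol relative tolerance on out-of-sphere violations.
#' @return numeric length-3 vector (X toward camera, Y right, Z up), measured
#'   from the center of eye rotation.
#' @export
lift_to_sphere <- function(p, center, radius, tol = 1e-6) {
  dy <- p[1] - center[1]
  dz <- p[2] - center[2]
  d2 <- dy^2 + dz^2
  r2 <- radius^2
  if (d2 > r2 * (1 + tol))
    stop_vog(sprintf("landmark outside its rotation sphere (offset %.6g px > radius %.6g px)",
                     sqrt(d2), radius), "vog3d_reconstruction_error")
  c(sqrt(max(r2 - d2, 0)), dy, dz)
}

# vectorized lift: ys, zs vectors -> n x 3 matrix (NA rows preserved)
lift_many <- function(ys, zs, center, radius, tol = 1e-6) {
  dy <- ys - center[1]
  dz <- zs - center[2]
  d2 <- dy^2 + dz^2
  bad <- which(d2 > radius^2 * (1 + tol))
  if (length(bad) > 0)
    stop_vog(sprintf("landmark outside its rotation sphere at frame %d",
                     bad[1]), "vog3d_reconstruction_error")
  cbind(sqrt(pmax(radius^2 - d2, 0)), dy, dz)
}

#' Reconstruct per-frame rotation vectors from 2D landmark tracks
#'
#' For each frame, the pupil center and freckle are lifted onto spheres of
#' radius R and R' about the calibrated rotation center; the pose matrix is
#' formed against the reference triad (pupil, freckle, and their cross
#' product) and converted to a rotation vector. The reference frame itself maps
#' to r = (0,0,0). Frames with missing landmarks are emitted as gaps (NA rows),
#' never interpolated; downstream velocity estimation splits at gaps.
#'
#' @param frames data.frame with columns `t`, `yp`, `zp`, `yi`, `zi` (seconds
#'   and pixels; NA marks a detection gap).
#' @param cal a `vog3d_calibration`.
#' @param trace_eps passed to the rotation-vector conversion.
#' @param tol lift tolerance, see [lift_to_sphere()].
#' @return data.frame with columns `t`, `rx`, `ry`, `rz` (rotation vector,
#'   unitless) and `px`, `py`, `pz`, `fx`, `fy`, `fz` (lifted 3D landmarks).
#' @export
reconstruct_poses <- function(frames, cal, trace_eps = 1e-8, tol = 1e-6) {
  stopifnot(inherits(cal, "vog3d_calibration"))
  need <- c("t", "yp", "zp", "yi", "zi")
  if (!all(need %in% names(frames)))
    stop_vog(paste("frames must have columns:", paste(need, collapse = ", ")),
             "vog3d_input_error")
  n <- nrow(frames)
  ok <- is.finite(frames$yp) & is.finite(frames$zp) &
    is.finite(frames$yi) & is.finite(frames$zi)

  rp <- cal$ref_pupil_3d
  rf <- cal$ref_freckle_3d
  A_ref <- cbind(rp, rf, cross3(rp, rf), deparse.level = 0)
  sv <- svd(A_ref, nu = 0, nv = 0)$d
  if (sv[3] <= 0 || sv[1] / sv[3] > 1e8)
    stop_vog("reference landmark triad is degenerate", "vog3d_degeneracy_error")
  invA <- solve(A_ref)

  P <- matrix(NA_real_, n, 3)
  F3 <- matrix(NA_real_, n, 3)
  r <- matrix(NA_real_, n, 3)
  if (any(ok)) {
    P[ok, ] <- lift_many(frames$yp[ok], frames$zp[ok], cal$center, cal$R, tol)
    F3[ok, ] <- lift_many(frames$yi[ok], frames$zi[ok], cal$center,
                          cal$R_prime, tol)
    C3 <- cbind(P[, 2] * F3[, 3] - P[, 3] * F3[, 2],
                P[, 3] * F3[, 1] - P[, 1] * F3[, 3],
                P[, 1] * F3[, 2] - P[, 2] * F3[, 1])
    degen <- ok & sqrt(rowSums(C3^2)) <=
      1e-8 * sqrt(rowSums(P^2)) * sqrt(rowSums(F3^2))
    if (any(degen))
      stop_vog(sprintf("pupil and freckle directions degenerate at frame %d",
                       which(degen)[1]), "vog3d_degeneracy_error")
    # M = A_cur %*% invA with A_cur = [P | F | P x F]; assemble entrywise so
    # all frames are processed at once
    Mel <- function(i, j)
      P[, i] * invA[1, j] + F3[, i] * invA[2, j] + C3[, i] * invA[3, j]
    M11 <- Mel(1, 1); M22 <- Mel(2, 2); M33 <- Mel(3, 3)
    den <- 1 + M11 + M22 + M33
    low <- ok & den <= trace_eps
    if (any(low))
      stop_vog(sprintf("rotation near 180 degrees at frame %d", which(low)[1]),
               "vog3d_range_error")
    r <- cbind(Mel(3, 2) - Mel(2, 3),
               Mel(1, 3) - Mel(3, 1),
               Mel(2, 1) - Mel(1, 2)) / den
    r[!ok, ] <- NA_real_
  }
  data.frame(t = frames$t, rx = r[, 1], ry = r[, 2], rz = r[, 3],
             px = P[, 1], py = P[, 2], pz = P[, 3],
             fx = F3[, 1], fy = F3[, 2], fz = F3[, 3])
}

#' Reconstruct rotation vectors from a pupil/freckle trajectory-file pair
#'
#' Consumes the two-file trajectory dialect (see [read_trajectory()]): each
#' file carries the rotation radius on its first line, the landmark coordinate
#' at the reference position on its second line, and per-frame 2D coordinates
#' relative to the rotation center on the remaining lines. Returns the
#' rotation-vector series of the eye relative to the reference position.
#'
#' @param pupil,freckle trajectory objects from [read_trajectory()] (or paths
#'   to such files).
#' @param frame_rate sampling rate in Hz used to assign timestamps.
#' @return data.frame with columns `t`, `rx`, `ry`, `rz`.
#' @export
reconstruct_from_trajectories <- function(pupil, freckle, frame_rate = 240) {
  if (is.character(pupil)) pupil <- read_trajectory(pupil)
  if (is.character(freckle)) freckle <- read_trajectory(freckle)
  if (nrow(pupil$coords) != nrow(freckle$coords))
    stop_vog("pupil and freckle trajectories differ in length",
             "vog3d_input_error")
  n <- nrow(pupil$coords)
  cal <- structure(list(
    center = c(0, 0), R = pupil$radius, R_prime = freckle$radius,
    reference_index = NA_integer_,
    ref_pupil_3d = lift_to_sphere(pupil$reference, c(0, 0), pupil$radius),
    ref_freckle_3d = lift_to_sphere(freckle$reference, c(0, 0), freckle$radius),
    frames_used = n), class = "vog3d_calibration")
  frames <- data.frame(t = (seq_len(n) - 1) / frame_rate,
                       yp = pupil$coords[, 1], zp = pupil$coords[, 2],
                       yi = freckle$coords[, 1], zi = freckle$coords[, 2])
  reconstruct_poses(frames, cal)[, c("t", "rx", "ry", "rz")]
}
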