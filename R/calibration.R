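# Geometric calibration: center of eye rotation from pupil-ellipse minor axes,
# rotation radius of the pupil center (R) and of an iris freckle (R').
#
# Image coordinates are (y, z) in pixels with z up; the camera axis is +X.

#' Pupil ellipse
#'
#' Fitted ellipse of the pupil edge in one image.
#'
#' @param center_y,center_z ellipse center in pixels (y right, z up).
#' @param major_len,minor_len full axis lengths in pixels
#'   (major_len >= minor_len > 0).
#' @param orientation_deg direction of the major axis in the image plane,
#'   degrees counterclockwise from +y.
#' @return object of class `pupil_ellipse`.
#' @export
pupil_ellipse <- function(center_y, center_z, major_len, minor_len,
                          orientation_deg) {
  if (!is.finite(major_len) || !is.finite(minor_len) ||
      minor_len <= 0 || major_len < minor_len)
    stop_vog("ellipse axes must satisfy major_len >= minor_len > 0",
             "vog3d_input_error")
  structure(list(center = c(center_y, center_z),
                 major_len = major_len, minor_len = minor_len,
                 orientation = orientation_deg %% 180),
            class = "pupil_ellipse")
}

#' @export
print.pupil_ellipse <- function(x, ...) {
  cat(sprintf("pupil ellipse: center (%.3f, %.3f), axes %.3f/%.3f px, %.2f deg\n",
              x$center[1], x$center[2], x$major_len, x$minor_len,
              x$orientation))
  invisible(x)
}

#' Minor-axis line of a pupil ellipse
#'
#' The projected center of eye rotation lies on the extension of the minor
#' axis of every pupil ellipse observed during eccentric gaze, because the
#' pupil circle is foreshortened along the direction of gaze tilt. This returns
#' that line (a point and a unit direction; the sign of the direction is
#' immaterial).
#'
#' @param e a [pupil_ellipse()].
#' @param eccentricity_cutoff frames with minor/major axis ratio above this are
#'   rejected: near-frontal gaze leaves the minor-axis direction undefined.
#' @return list with `point` (ellipse center) and `direction` (unit vector
#'   along the minor axis).
#' @export
minor_axis_line <- function(e, eccentricity_cutoff = 0.995) {
  stopifnot(inherits(e, "pupil_ellipse"))
  if (e$minor_len / e$major_len > eccentricity_cutoff)
    stop_vog("ellipse too circular: minor-axis direction undefined",
             "vog3d_degeneracy_error")
  ang <- deg2rad(e$orientation + 90)
  list(point = e$center, direction = c(cos(ang), sin(ang)))
}

#' Center of eye rotation from minor-axis lines
#'
#' Ideally all minor axes intersect in one point; with measurement error they
#' do not, so the center is taken as the point minimizing the sum of squared
#' perpendicular distances to the lines. The objective is quadratic, so the
#' unique minimizer solves the 2x2 normal equations
#' \eqn{\sum_i (I - d_i d_i^T)\,x = \sum_i (I - d_i d_i^T)\,p_i}.
#'
#' @param lines list of lines as returned by [minor_axis_line()].
#' @param max_condition maximum condition number of the normal matrix; a bundle
#'   of near-parallel lines does not determine the center.
#' @return numeric length-2 center (yc, zc) in pixels.
#' @export
estimate_rotation_center <- function(lines, max_condition = 1e8) {
  if (length(lines) < 2)
    stop_vog("at least two minor-axis lines are required",
             "vog3d_degeneracy_error")
  A <- matrix(0, 2, 2)
  b <- c(0, 0)
  for (ln in lines) {
    d <- ln$direction / sqrt(sum(ln$direction^2))
    P <- diag(2) - tcrossprod(d)
    A <- A + P
    b <- b + P %*% ln$point
  }
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sv[2] <= 0 || sv[1] / sv[2] > max_condition)
    stop_vog("minor axes nearly parallel: rotation center undetermined",
             "vog3d_degeneracy_error")
  as.numeric(solve(A, b))
}

#' Radius of rotation of the pupil center
#'
#' When the eye is tilted by theta from frontal gaze, the minor/major axis
#' ratio of the pupil ellipse equals cos(theta) and the image distance r
#' between the rotation center and the ellipse center equals R sin(theta).
#' Eliminating theta gives
#' \deqn{R = r / \sqrt{1 - (\mathrm{minor}/\mathrm{major})^2}.}
#' Near frontal gaze the formula is 0/0, so too-circular frames are excluded.
#'
#' @param e a [pupil_ellipse()].
#' @param center rotation center (yc, zc) in pixels.
#' @param eccentricity_cutoff exclusion threshold on minor/major.
#' @return R in pixels, or `NA_real_` for an excluded (near-frontal) frame.
#' @export
compute_pupil_radius <- function(e, center, eccentricity_cutoff = 0.995) {
  stopifnot(inherits(e, "pupil_ellipse"))
  ratio <- e$minor_len / e$major_len
  if (ratio > eccentricity_cutoff) return(NA_real_)
  r <- sqrt(sum((e$center - center)^2))
  r / sqrt(1 - ratio^2)
}

#' Aggregate per-frame radius estimates
#'
#' The per-frame radius estimates of retained frames are averaged; excluded
#' frames (NA) are dropped first. An optional median aggregation is available
#' for noisy recordings.
#'
#' @param per_frame numeric vector of per-frame radii (NA = excluded frame).
#' @param use_median aggregate with the median instead of the mean.
#' @return aggregated radius in pixels.
#' @export
aggregate_radius <- function(per_frame, use_median = FALSE) {
  v <- per_frame[is.finite(per_frame)]
  if (length(v) == 0)
    stop_vog("no usable frames for radius estimation", "vog3d_calibration_error")
  if (use_median) stats::median(v) else mean(v)
}

# distance from ellipse center to the ellipse edge along the unit image
# direction u (point c of the freckle-radius construction: the ellipse
# quadratic is solved along the ray, positive root toward the freckle)
ellipse_edge_distance <- function(e, u) {
  phi <- deg2rad(e$orientation)
  u1 <- cos(phi) * u[1] + sin(phi) * u[2]
  u2 <- -sin(phi) * u[1] + cos(phi) * u[2]
  A <- e$major_len / 2
  B <- e$minor_len / 2
  1 / sqrt((u1 / A)^2 + (u2 / B)^2)
}

#' Radius of rotation of an iris freckle
#'
#' The freckle lies in the pupil plane at some in-plane distance d from the
#' pupil center, so its rotation radius is \eqn{R' = \sqrt{R^2 + d^2}}. The
#' in-plane distance is recovered from the image as
#' \deqn{d = (a/b) \cdot \mathrm{major\_len}/2,}
#' where a is the image distance from the ellipse center to the freckle
#' centroid and b the distance from the ellipse center to the point c where
#' the segment through the freckle crosses the ellipse edge: the ratio a/b is
#' invariant under the foreshortening of the projection, and the edge point
#' corresponds to the true pupil radius (major_len/2).
#'
#' @param e a [pupil_ellipse()].
#' @param freckle freckle centroid (yi, zi) in pixels.
#' @param R rotation radius of the pupil center, pixels.
#' @return R' in pixels.
#' @export
compute_freckle_radius <- function(e, freckle, R) {
  stopifnot(inherits(e, "pupil_ellipse"))
  if (!is.finite(R) || R <= 0)
    stop_vog("R must be positive", "vog3d_input_error")
  v <- as.numeric(freckle) - e$center
  a <- sqrt(sum(v^2))
  if (a == 0)
    stop_vog("freckle coincides with the pupil center", "vog3d_geometry_error")
  b <- ellipse_edge_distance(e, v / a)
  if (a < b)
    stop_vog("freckle lies inside the pupil ellipse", "vog3d_geometry_error")
  sqrt(R^2 + (a / b * e$major_len / 2)^2)
}

#' Select the reference frame
#'
#' The frame whose pupil center is nearest to the rotation center (yc, zc) is
#' used as the reference position; all rotation vectors are expressed relative
#' to it. Ties are broken by the earliest frame.
#'
#' @param frames data.frame with columns `yp`, `zp` (pupil center per frame).
#' @param center rotation center (yc, zc).
#' @return integer index (1-based) of the reference frame.
#' @export
select_reference_frame <- function(frames, center) {
  ok <- is.finite(frames$yp) & is.finite(frames$zp)
  if (!any(ok))
    stop_vog("no frames with a detected pupil", "vog3d_input_error")
  d2 <- (frames$yp - center[1])^2 + (frames$zp - center[2])^2
  d2[!ok] <- Inf
  which.min(d2)   # which.min returns the first minimum: earliest-index tie rule
}

#' Calibrate the eye model from a swirl recording
#'
#' Runs the full geometric calibration on per-frame landmark data obtained
#' while the eye sweeps through eccentric positions in several directions
#' (circular "swirl" movement): estimates the 2D center of eye rotation from
#' the minor-axis lines, the pupil-center rotation radius R, the freckle
#' rotation radius R', and selects the reference frame. The reference pupil and
#' freckle positions are lifted to 3D on their rotation spheres.
#'
#' @param frames data.frame with one row per frame and columns `yp`, `zp`
#'   (pupil-ellipse center), `major_len`, `minor_len`, `orientation`
#'   (ellipse axes/orientation), `yi`, `zi` (freckle centroid). NA entries mark
#'   detection gaps.
#' @param eccentricity_cutoff minor/major ratio above which a frame is excluded
#'   from center and radius estimation (near-frontal gaze).
#' @param use_median use median instead of mean when aggregating radii.
#' @param max_condition degeneracy bound passed to
#'   [estimate_rotation_center()].
#' @return object of class `vog3d_calibration`: list with `center`, `R`,
#'   `R_prime`, `reference_index`, `ref_pupil_3d`, `ref_freckle_3d`,
#'   `frames_used`.
#' @export
calibrate <- function(frames, eccentricity_cutoff = 0.995, use_median = FALSE,
                      max_condition = 1e8) {
  need <- c("yp", "zp", "major_len", "minor_len", "orientation", "yi", "zi")
  if (!all(need %in% names(frames)))
    stop_vog(paste("frames must have columns:", paste(need, collapse = ", ")),
             "vog3d_input_error")
  has_ellipse <- is.finite(frames$yp) & is.finite(frames$zp) &
    is.finite(frames$major_len) & is.finite(frames$minor_len) &
    is.finite(frames$orientation)
  ratio <- frames$minor_len / frames$major_len
  retained <- has_ellipse & ratio <= eccentricity_cutoff
  if (sum(retained) < 2)
    stop_vog("fewer than 2 usable (eccentric) frames for calibration",
             "vog3d_calibration_error")
  ells <- lapply(which(retained), function(i)
    pupil_ellipse(frames$yp[i], frames$zp[i], frames$major_len[i],
                  frames$minor_len[i], frames$orientation[i]))
  lines <- lapply(ells, minor_axis_line,
                  eccentricity_cutoff = eccentricity_cutoff)
  center <- estimate_rotation_center(lines, max_condition = max_condition)

  Rs <- vapply(ells, compute_pupil_radius, numeric(1), center = center,
               eccentricity_cutoff = eccentricity_cutoff)
  R <- aggregate_radius(Rs, use_median = use_median)

  idx_ret <- which(retained)
  has_freckle <- is.finite(frames$yi) & is.finite(frames$zi)
  Rps <- rep(NA_real_, length(idx_ret))
  for (k in seq_along(idx_ret)) {
    i <- idx_ret[k]
    if (has_freckle[i])
      Rps[k] <- compute_freckle_radius(ells[[k]], c(frames$yi[i], frames$zi[i]), R)
  }
  R_prime <- aggregate_radius(Rps, use_median = use_median)

  both <- has_ellipse & has_freckle
  ref_candidates <- frames
  ref_candidates$yp[!both] <- NA_real_
  ref_candidates$zp[!both] <- NA_real_
  ref_idx <- select_reference_frame(ref_candidates, center)

  ref_pupil_3d <- lift_to_sphere(c(frames$yp[ref_idx], frames$zp[ref_idx]),
                                 center, R)
  ref_freckle_3d <- lift_to_sphere(c(frames$yi[ref_idx], frames$zi[ref_idx]),
                                   center, R_prime)
  structure(list(center = center, R = R, R_prime = R_prime,
                 reference_index = ref_idx,
                 ref_pupil_3d = ref_pupil_3d,
                 ref_freckle_3d = ref_freckle_3d,
                 frames_used = sum(retained)),
            class = "vog3d_calibration")
}

#' @export
print.vog3d_calibration <- function(x, ...) {
  cat(sprintf(paste0("eye-rotation calibration\n",
                     "  center (yc, zc): (%.4f, %.4f) px\n",
                     "  R  (pupil center): %.4f px\n",
                     "  R' (iris freckle): %.4f px\n",
                     "  reference frame:   %d\n",
                     "  frames used:       %d\n"),
              x$center[1], x$center[2], x$R, x$R_prime,
              x$reference_index, x$frames_used))
  invisible(x)
}

#' Write / read a calibration report
#'
#' The calibration is serialized as a small key=value text file so the
#' reconstruction stage of the pipeline can consume it.
#'
#' @param cal a `vog3d_calibration` object.
#' @param path file path.
#' @return `read_calibration` returns a `vog3d_calibration`;
#'   `write_calibration` returns `path` invisibly.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "vog3d_calibration"))
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    paste0("yc=", num(cal$center[1])),
    paste0("zc=", num(cal$center[2])),
    paste0("R=", num(cal$R)),
    paste0("R_prime=", num(cal$R_prime)),
    paste0("reference_index=", cal$reference_index),
    paste0("frames_used=", cal$frames_used),
    paste0("ref_pupil_3d=", paste(num(cal$ref_pupil_3d), collapse = ",")),
    paste0("ref_freckle_3d=", paste(num(cal$ref_freckle_3d), collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  get1 <- function(k) as.numeric(vals[match(k, keys)])
  getv <- function(k) as.numeric(strsplit(vals[match(k, keys)], ",")[[1]])
  structure(list(center = c(get1("yc"), get1("zc")),
                 R = get1("R"), R_prime = get1("R_prime"),
                 reference_index = as.integer(get1("reference_index")),
                 ref_pupil_3d = getv("ref_pupil_3d"),
                 ref_freckle_3d = getv("ref_freckle_3d"),
                 frames_used = as.integer(get1("frames_used"))),
            class = "vog3d_calibration")
}
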