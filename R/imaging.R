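# Landmark extraction from grayscale images.
#
# Images are numeric matrices img[z, y] with gray values in [0, 255], z-up
# (row 1 is the bottom image row; the io layer flips raster files once at
# ingestion so every module downstream works in the z-up convention).

#' Region-of-interest specifications
#'
#' `roi_rect` is an axis-aligned pixel rectangle used for the left/right
#' pupil-edge searches. `roi_annulus` follows the curvature of the fitted pupil
#' ellipse: it keeps pixels whose distance beyond the ellipse edge, measured
#' along the ray from the ellipse center, lies between the two offsets —
#' the band used to search for an iris freckle.
#'
#' @param y0,z0,y1,z1 inclusive pixel bounds of the rectangle.
#' @param inner_offset,outer_offset distances beyond the pupil-ellipse edge in
#'   pixels (0 <= inner < outer).
#' @param angular_range length-2 vector of angles in degrees (atan2 convention,
#'   direction from the ellipse center); default keeps the full ring.
#' @return an object of class `roi_rect` or `roi_annulus`.
#' @export
roi_rect <- function(y0, z0, y1, z1) {
  if (y1 <= y0 || z1 <= z0)
    stop_vog("degenerate rectangle ROI", "vog3d_input_error")
  structure(list(y0 = y0, z0 = z0, y1 = y1, z1 = z1), class = "roi_rect")
}

#' @rdname roi_rect
#' @export
roi_annulus <- function(inner_offset, outer_offset,
                        angular_range = c(-180, 180)) {
  if (!(outer_offset > inner_offset) || inner_offset < 0)
    stop_vog("annulus offsets must satisfy 0 <= inner < outer",
             "vog3d_input_error")
  structure(list(inner = inner_offset, outer = outer_offset,
                 angular_range = angular_range), class = "roi_annulus")
}

#' Detection configuration
#'
#' Per-recording thresholds and blob-size limits. Because the infrared light
#' source leaves one side of the pupil brighter than the other, the left and
#' right pupil edges are binarized with separate thresholds.
#'
#' @param threshold_left,threshold_right gray-value thresholds (pixels at or
#'   below are pupil) for the left/right edge ROIs.
#' @param threshold_freckle gray threshold for the freckle search.
#' @param threshold_marker gray threshold (pixels at or above are marker) for
#'   the turntable markers.
#' @param eccentricity_cutoff minor/major ratio above which calibration frames
#'   are dropped.
#' @param min_area,max_area accepted freckle blob area in pixels^2.
#' @return object of class `detection_config`.
#' @export
detection_config <- function(threshold_left, threshold_right,
                             threshold_freckle, threshold_marker = 128,
                             eccentricity_cutoff = 0.995,
                             min_area = 4, max_area = 400) {
  thr <- c(threshold_left, threshold_right, threshold_freckle, threshold_marker)
  if (any(thr < 0 | thr > 255))
    stop_vog("thresholds must lie in [0, 255]", "vog3d_input_error")
  structure(list(threshold_left = threshold_left,
                 threshold_right = threshold_right,
                 threshold_freckle = threshold_freckle,
                 threshold_marker = threshold_marker,
                 eccentricity_cutoff = eccentricity_cutoff,
                 min_area = min_area, max_area = max_area),
            class = "detection_config")
}

#' Contrast enhancement by percentile stretch
#'
#' Monotone linear remap of the 1st..99th intensity percentiles onto the full
#' [0, 255] range, clamped. A constant image is returned unchanged. The output
#' is kept floating point (no rounding), so the remap is idempotent up to the
#' clamped tails and exactly invariant under affine input changes.
#'
#' @param img gray image matrix (values in [0, 255]).
#' @param probs the two stretch percentiles.
#' @return enhanced image matrix.
#' @export
enhance_contrast <- function(img, probs = c(0.01, 0.99)) {
  q <- stats::quantile(img, probs = probs, names = FALSE)
  if (q[2] <= q[1]) return(img)
  out <- (img - q[1]) * (255 / (q[2] - q[1]))
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

# threshold-crossing edge points of the largest dark region inside a rect ROI.
# For each 4-neighbor pair straddling the threshold, the crossing is placed by
# linear interpolation of intensity between the two pixel centers, giving
# subpixel edge coordinates. Pairs that would leave the ROI are skipped, so the
# artificial cut where the ROI crops the pupil contributes no spurious points.
edge_points_rect <- function(img, roi, threshold) {
  H <- nrow(img); W <- ncol(img)
  y0 <- max(1L, as.integer(roi$y0)); y1 <- min(W, as.integer(roi$y1))
  z0 <- max(1L, as.integer(roi$z0)); z1 <- min(H, as.integer(roi$z1))
  if (roi$y0 < 1 || roi$y1 > W || roi$z0 < 1 || roi$z1 > H)
    stop_vog("ROI outside the image", "vog3d_input_error")
  sub <- img[z0:z1, y0:y1, drop = FALSE]
  mask <- sub <= threshold
  if (!any(mask)) return(matrix(numeric(0), 0, 2))
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which.max(areas)
  comp <- lab == keep

  pts <- matrix(numeric(0), 0, 2)
  nr <- nrow(sub); nc <- ncol(sub)
  shift_pairs <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  idx <- which(comp, arr.ind = TRUE)   # (row = z, col = y) in sub coords
  for (s in shift_pairs) {
    nz <- idx[, 1] + s[1]
    ny <- idx[, 2] + s[2]
    inb <- nz >= 1 & nz <= nr & ny >= 1 & ny <= nc
    if (!any(inb)) next
    i0 <- idx[inb, , drop = FALSE]
    nz <- nz[inb]; ny <- ny[inb]
    v0 <- sub[i0]
    v1 <- sub[cbind(nz, ny)]
    out <- v1 > threshold          # neighbor on the bright side
    if (!any(out)) next
    i0 <- i0[out, , drop = FALSE]
    frac <- (threshold - v0[out]) / (v1[out] - v0[out])
    yy <- (i0[, 2] + frac * s[2]) + (y0 - 1)
    zz <- (i0[, 1] + frac * s[1]) + (z0 - 1)
    pts <- rbind(pts, cbind(yy, zz))
  }
  pts
}

#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to 2D points with the direct conic least-squares method
#' (quadratic constraint 4ac - b^2 = 1, solved via the numerically stable
#' block decomposition of the generalized eigenproblem). Points are centered
#' and scaled before fitting for conditioning.
#'
#' @param y,z point coordinates in pixels.
#' @return a [pupil_ellipse()].
#' @export
fit_ellipse <- function(y, z) {
  y <- as.numeric(y); z <- as.numeric(z)
  if (length(y) < 6)
    stop_vog("ellipse fit needs at least 6 points", "vog3d_detection_error")
  my <- mean(y); mz <- mean(z)
  s <- max(stats::sd(y), stats::sd(z))
  if (!is.finite(s) || s == 0)
    stop_vog("degenerate point set", "vog3d_detection_error")
  x1 <- (y - my) / s; x2 <- (z - mz) / s
  D1 <- cbind(x1^2, x1 * x2, x2^2)
  D2 <- cbind(x1, x2, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop_vog("singular design in ellipse fit", "vog3d_detection_error"))
  Mm <- S1 + S2 %*% Tm
  Mm <- rbind(Mm[3, ] / 2, -Mm[2, ], Mm[1, ] / 2)
  ev <- eigen(Mm)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0)
    stop_vog("point set does not admit an ellipse", "vog3d_detection_error")
  a1 <- V[, ok[1]]
  cf <- c(a1, as.numeric(Tm %*% a1))   # conic A B C D E F in scaled frame

  A <- cf[1]; B <- cf[2]; C <- cf[3]; D <- cf[4]; E <- cf[5]; Fc <- cf[6]
  ctr <- solve(matrix(c(2 * A, B, B, 2 * C), 2, 2), -c(D, E))
  mu <- A * ctr[1]^2 + B * ctr[1] * ctr[2] + C * ctr[2]^2 +
    D * ctr[1] + E * ctr[2] + Fc
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(Q, symmetric = TRUE)
  semi2 <- -mu / eg$values
  if (any(semi2 <= 0))
    stop_vog("fitted conic is not an ellipse", "vog3d_detection_error")
  semi <- sqrt(semi2)
  i_major <- which.max(semi)
  vmaj <- eg$vectors[, i_major]
  orient <- (atan2(vmaj[2], vmaj[1]) * 180 / pi) %% 180
  pupil_ellipse(my + s * ctr[1], mz + s * ctr[2],
                major_len = 2 * s * max(semi), minor_len = 2 * s * min(semi),
                orientation_deg = orient)
}

#' Detect the pupil ellipse in an eye image
#'
#' The left and right pupil edges are binarized inside their own rectangular
#' ROIs with separate thresholds (the illumination gradient makes one side of
#' the pupil brighter than the other). Within each ROI the largest dark
#' connected region is taken as the pupil part; its subpixel threshold-crossing
#' boundary points form the edge set. The pooled edge points from both ROIs are
#' fitted with a direct least-squares conic constrained to an ellipse.
#'
#' @param img gray image matrix (z-up).
#' @param cfg a [detection_config()].
#' @param roi_left,roi_right [roi_rect()] ROIs containing the left and right
#'   pupil edge.
#' @return a [pupil_ellipse()]; raises a `vog3d_detection_error` on failure.
#' @export
detect_pupil <- function(img, cfg, roi_left, roi_right) {
  stopifnot(inherits(cfg, "detection_config"),
            inherits(roi_left, "roi_rect"), inherits(roi_right, "roi_rect"))
  pts <- rbind(edge_points_rect(img, roi_left, cfg$threshold_left),
               edge_points_rect(img, roi_right, cfg$threshold_right))
  if (nrow(pts) < 6)
    stop_vog("too few pupil edge points", "vog3d_detection_error")
  fit_ellipse(pts[, 1], pts[, 2])
}

#' Detect the iris freckle near the pupil ellipse
#'
#' Searches an elliptical annulus that follows the curvature of the fitted
#' pupil ellipse at a configured distance beyond its edge. Pixels at or below
#' the freckle threshold are extracted; connected components with area inside
#' the configured range are candidates, and the centroid (unweighted center of
#' gravity of the binary pixel set) of the largest accepted component is
#' returned.
#'
#' @param img gray image matrix.
#' @param e the frame's [pupil_ellipse()].
#' @param cfg a [detection_config()].
#' @param roi a [roi_annulus()].
#' @return length-2 numeric (yi, zi), or NULL when no acceptable blob exists
#'   (a freckle gap for the frame).
#' @export
detect_freckle <- function(img, e, cfg, roi) {
  stopifnot(inherits(e, "pupil_ellipse"), inherits(cfg, "detection_config"),
            inherits(roi, "roi_annulus"))
  H <- nrow(img); W <- ncol(img)
  yy <- matrix(seq_len(W), H, W, byrow = TRUE)
  zz <- matrix(seq_len(H), H, W)
  dy <- yy - e$center[1]
  dz <- zz - e$center[2]
  phi <- deg2rad(e$orientation)
  u1 <- cos(phi) * dy + sin(phi) * dz
  u2 <- -sin(phi) * dy + cos(phi) * dz
  A <- e$major_len / 2; B <- e$minor_len / 2
  m <- sqrt((u1 / A)^2 + (u2 / B)^2)
  dist0 <- sqrt(dy^2 + dz^2)
  beyond <- dist0 * (1 - 1 / pmax(m, 1e-12))   # distance past the ellipse edge
  ann <- beyond >= roi$inner & beyond <= roi$outer
  if (!isTRUE(all.equal(roi$angular_range, c(-180, 180)))) {
    ang <- atan2(dz, dy) * 180 / pi
    ann <- ann & ang >= roi$angular_range[1] & ang <= roi$angular_range[2]
  }
  mask <- ann & img <= cfg$threshold_freckle
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  accept <- which(areas >= cfg$min_area & areas <= cfg$max_area)
  if (length(accept) == 0) return(NULL)
  best <- accept[which.max(areas[accept])]
  idx <- which(lab == best, arr.ind = TRUE)
  c(mean(idx[, 2]), mean(idx[, 1]))   # (y, z) = (col, row)
}

#' Angle of the line through two marker centroids
#'
#' The two turntable markers are an unordered pair, so the line direction is
#' defined modulo 180 degrees; the returned angle lies in [0, 180).
#'
#' @param c1,c2 marker centroids (y, z) in pixels.
#' @return angle in degrees.
#' @export
marker_line_angle <- function(c1, c2) {
  (atan2(c2[2] - c1[2], c2[1] - c1[1]) * 180 / pi) %% 180
}

# centers of gravity of the two largest bright blobs, or NULL if fewer than
# two. The centroid is intensity-weighted, so the anti-aliased marker edge
# contributes subpixel precision.
marker_centroids <- function(img, threshold) {
  mask <- img >= threshold
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  if (length(areas) < 2) return(NULL)
  ord <- order(areas, decreasing = TRUE)[1:2]
  lapply(ord, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    w <- img[idx]
    c(sum(idx[, 2] * w), sum(idx[, 1] * w)) / sum(w)
  })
}

#' Track the turntable angle from marker images
#'
#' Each frame is thresholded; the centroids of the two largest bright blobs
#' (the turntable markers) define a line whose direction is the table angle
#' modulo 180 degrees. The per-frame series is unwrapped by continuity (no
#' +-90 degree jumps between consecutive frames) and zeroed at the first valid
#' frame. Frames without exactly two detectable markers become gaps (NA).
#'
#' @param frames list of gray image matrices, frame-for-frame synchronized with
#'   the eye stream.
#' @param cfg a [detection_config()] (uses `threshold_marker`).
#' @param frame_rate sampling rate in Hz.
#' @param zero_start subtract the first valid angle (default TRUE).
#' @return data.frame with columns `t` (seconds) and `angle` (degrees,
#'   unwrapped).
#' @export
track_turntable <- function(frames, cfg, frame_rate = 240, zero_start = TRUE) {
  stopifnot(inherits(cfg, "detection_config"))
  n <- length(frames)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cc <- marker_centroids(frames[[i]], cfg$threshold_marker)
    if (!is.null(cc)) raw[i] <- marker_line_angle(cc[[1]], cc[[2]])
  }
  ang <- raw
  valid <- which(is.finite(raw))
  if (length(valid) >= 2) {
    prev <- valid[1]
    for (i in valid[-1]) {
      d <- raw[i] - ang[prev]
      d <- ((d + 90) %% 180) - 90   # shortest mod-180 step
      ang[i] <- ang[prev] + d
      prev <- i
    }
  }
  if (zero_start && length(valid) > 0) ang <- ang - ang[valid[1]]
  data.frame(t = (seq_len(n) - 1) / frame_rate, angle = ang)
}

#' Extract eye landmarks from a frame sequence
#'
#' Applies contrast enhancement, pupil-ellipse detection, and freckle detection
#' to every frame, emitting the per-frame landmark table consumed by the
#' calibration and reconstruction stages. Detection failures become NA gaps.
#'
#' @param frames list of gray image matrices.
#' @param cfg a [detection_config()].
#' @param roi_left,roi_right pupil-edge ROIs ([roi_rect()]).
#' @param roi_freckle freckle ROI ([roi_annulus()]).
#' @param frame_rate sampling rate in Hz.
#' @param enhance apply [enhance_contrast()] first (default TRUE).
#' @return data.frame with columns `t`, `yp`, `zp`, `major_len`, `minor_len`,
#'   `orientation`, `yi`, `zi`.
#' @export
detect_landmarks <- function(frames, cfg, roi_left, roi_right, roi_freckle,
                             frame_rate = 240, enhance = TRUE) {
  n <- length(frames)
  out <- data.frame(t = (seq_len(n) - 1) / frame_rate,
                    yp = NA_real_, zp = NA_real_,
                    major_len = NA_real_, minor_len = NA_real_,
                    orientation = NA_real_, yi = NA_real_, zi = NA_real_)
  for (i in seq_len(n)) {
    img <- if (enhance) enhance_contrast(frames[[i]]) else frames[[i]]
    e <- tryCatch(detect_pupil(img, cfg, roi_left, roi_right),
                  vog3d_detection_error = function(cond) NULL)
    if (is.null(e)) next
    out$yp[i] <- e$center[1]; out$zp[i] <- e$center[2]
    out$major_len[i] <- e$major_len; out$minor_len[i] <- e$minor_len
    out$orientation[i] <- e$orientation
    fk <- detect_freckle(img, e, cfg, roi_freckle)
    if (!is.null(fk)) { out$yi[i] <- fk[1]; out$zi[i] <- fk[2] }
  }
  out
}
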