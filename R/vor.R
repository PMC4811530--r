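# Sinusoid fitting of angular-velocity traces and VOR gain/phase.

wrap_pi <- function(p) {
  w <- (p + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)   # wrap to (-pi, pi]
}

# zero-phase Butterworth low-pass (order 2, applied forward and backward) with
# reflection padding to suppress end transients. Differentiation amplifies
# landmark noise in proportion to frequency, so the position series is
# filtered before differencing; applying the identical filter to the table
# angle keeps pass-band attenuation out of the gain ratio, and the zero-phase
# filter leaves phase untouched.
lowpass_series <- function(x, rate, cutoff_hz) {
  n <- length(x)
  if (cutoff_hz <= 0 || cutoff_hz >= rate / 2)
    stop_vog("low-pass cutoff must lie in (0, rate/2)", "vog3d_input_error")
  bf <- signal::butter(2, cutoff_hz / (rate / 2), type = "low")
  pad <- min(n - 1, ceiling(3 * rate / cutoff_hz))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(pad + 1):(pad + n)]
}

# residual sum of squares of the quadrature fit at frequency f
quad_rss <- function(t, x, f) {
  S <- sin(2 * pi * f * t); C <- cos(2 * pi * f * t)
  X <- cbind(S, C)
  cf <- qr.solve(crossprod(X), crossprod(X, x))
  sum((x - X %*% cf)^2)
}

#' Fit a sinusoid v sin(2 pi f t + p) to a series
#'
#' With a fixed frequency, the fit is linear least squares on the quadrature
#' pair sin(2 pi f t), cos(2 pi f t), and \eqn{v = \sqrt{A^2+B^2}},
#' \eqn{p = \mathrm{atan2}(B, A)}. With a free frequency, the periodogram peak
#' brackets a one-dimensional search that minimizes the residual of the same
#' linear fit; the returned amplitude is non-negative by construction and the
#' phase is wrapped to (-pi, pi].
#'
#' A constant (zero-variance) signal cannot constrain the phase; the fit is
#' returned with `v = 0`, `p = NA` and `flagged = TRUE`.
#'
#' @param t sample times in seconds (uniformly spaced recommended).
#' @param x signal values (e.g. angular velocity in degrees/second).
#' @param f frequency in Hz, or NULL to estimate it from the data.
#' @return object of class `sinusoid_fit`: list with `v` (amplitude, units of
#'   x), `f` (Hz), `p` (radians in (-pi, pi]), `rmse`, `flagged`.
#' @export
fit_sinusoid <- function(t, x, f = NULL) {
  t <- as.numeric(t); x <- as.numeric(x)
  keep <- is.finite(t) & is.finite(x)
  t <- t[keep]; x <- x[keep]
  n <- length(t)
  if (n < 8)
    stop_vog("too few samples for a sinusoid fit", "vog3d_input_error")
  if (stats::sd(x) == 0) {
    return(structure(list(v = 0, f = if (is.null(f)) NA_real_ else f,
                          p = NA_real_, rmse = 0, flagged = TRUE),
                     class = "sinusoid_fit"))
  }
  if (is.null(f)) {
    dt <- stats::median(diff(t))
    Tspan <- t[n] - t[1] + dt
    xc <- x - mean(x)
    sp <- Mod(stats::fft(xc))[2:floor(n / 2)]
    k <- which.max(sp)
    f0 <- k / Tspan
    df <- 1 / Tspan
    # coarse grid over the spectral peak, then Brent refinement
    grid <- seq(max(f0 - 1.5 * df, 0.25 / Tspan), f0 + 1.5 * df,
                length.out = 61)
    rss <- vapply(grid, function(fg) quad_rss(t, x, fg), numeric(1))
    fg <- grid[which.min(rss)]
    step <- grid[2] - grid[1]
    opt <- stats::optimize(function(fv) quad_rss(t, x, fv),
                           lower = max(fg - step, 1e-6), upper = fg + step,
                           tol = 1e-12)
    f <- opt$minimum
  }
  if (!is.finite(f) || f <= 0)
    stop_vog("frequency must be positive", "vog3d_input_error")
  if ((t[n] - t[1]) * f < 2)
    stop_vog("need at least two full cycles of data", "vog3d_input_error")
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- as.numeric(qr.solve(crossprod(X), crossprod(X, x)))
  v <- sqrt(sum(cf^2))
  p <- wrap_pi(atan2(cf[2], cf[1]))
  rmse <- sqrt(mean((x - X %*% cf)^2))
  structure(list(v = v, f = f, p = p, rmse = rmse, flagged = FALSE),
            class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf("sinusoid fit: %.4g * sin(2*pi*%.6g*t %+.4g)  rmse %.3g%s\n",
              x$v, x$f, x$p, x$rmse, if (x$flagged) "  [flagged]" else ""))
  invisible(x)
}

#' Signed eye rotation speed from a pose series
#'
#' Converts a reconstructed rotation-vector series into the scalar angular
#' velocity around the axis of eye rotation: the norm of the angular-velocity
#' vector, signed by its Z component so that rotation direction is preserved.
#' The series is split at landmark gaps (NA poses) and each contiguous segment
#' is differentiated independently; segments shorter than 3 samples are
#' dropped.
#'
#' An optional zero-phase low-pass (cutoff in Hz) can be applied to the
#' rotation-vector components before differentiation: differencing amplifies
#' landmark noise linearly with frequency, and the norm-with-sign transform
#' rectifies whatever noise survives into a positive amplitude bias, so noisy
#' recordings should be filtered. The default is no filtering.
#'
#' @param poses data.frame with columns `t`, `rx`, `ry`, `rz` (see
#'   [reconstruct_poses()]).
#' @param lowpass_hz optional low-pass cutoff in Hz applied to the
#'   rotation-vector series of each contiguous segment (NULL = no filtering).
#' @return data.frame with columns `t` and `speed` (degrees/second); rows at
#'   gaps carry NA.
#' @export
signed_eye_speed <- function(poses, lowpass_hz = NULL) {
  need <- c("t", "rx", "ry", "rz")
  if (!all(need %in% names(poses)))
    stop_vog("poses must have columns t, rx, ry, rz", "vog3d_input_error")
  n <- nrow(poses)
  ok <- is.finite(poses$rx) & is.finite(poses$ry) & is.finite(poses$rz)
  speed <- rep(NA_real_, n)
  # contiguous runs of valid frames
  rle_ok <- rle(ok)
  ends <- cumsum(rle_ok$lengths)
  starts <- ends - rle_ok$lengths + 1
  for (k in seq_along(rle_ok$values)) {
    if (!rle_ok$values[k] || rle_ok$lengths[k] < 3) next
    i <- starts[k]:ends[k]
    r <- as.matrix(poses[i, c("rx", "ry", "rz")])
    if (!is.null(lowpass_hz)) {
      rate <- 1 / mean(diff(poses$t[i]))
      r <- apply(r, 2, lowpass_series, rate = rate, cutoff_hz = lowpass_hz)
    }
    av <- angular_velocity(poses$t[i], r)
    speed[i] <- av$signed_speed
  }
  if (!any(is.finite(speed)))
    stop_vog("no segment long enough for velocity estimation",
             "vog3d_input_error")
  data.frame(t = poses$t, speed = speed)
}

#' VOR gain and phase from table and eye sinusoid fits
#'
#' A perfectly compensatory eye would rotate opposite the table: its angular
#' velocity would have the table amplitude and the table phase minus pi. Gain
#' is the eye/table amplitude ratio, and phase is the lead of the eye fit
#' over that ideal compensatory sinusoid,
#' \eqn{\mathrm{phase} = p_e - (p_t - \pi)} wrapped to (-pi, pi], reported in
#' degrees (positive = eye leads the table).
#'
#' The eye fit must have been made at the table frequency (the stated
#' procedure: the frequency is estimated once, from the table trace).
#'
#' @param table_fit,eye_fit `sinusoid_fit` objects for the turntable and eye
#'   angular-velocity traces.
#' @return object of class `vor_result`: list with `gain`, `phase_deg`,
#'   `phase_rad`, `f`, `table_fit`, `eye_fit`.
#' @export
compute_gain_phase <- function(table_fit, eye_fit) {
  stopifnot(inherits(table_fit, "sinusoid_fit"),
            inherits(eye_fit, "sinusoid_fit"))
  if (!isTRUE(abs(table_fit$f - eye_fit$f) <= 1e-9 * max(table_fit$f, 1)))
    stop_vog("eye fit must reuse the table frequency", "vog3d_contract_error")
  if (table_fit$v <= 0)
    stop_vog("table fit has zero amplitude", "vog3d_input_error")
  gain <- eye_fit$v / table_fit$v
  phase <- wrap_pi(eye_fit$p - (table_fit$p - pi))
  structure(list(gain = gain, phase_deg = rad2deg(phase), phase_rad = phase,
                 f = table_fit$f, table_fit = table_fit, eye_fit = eye_fit),
            class = "vor_result")
}

#' @export
print.vor_result <- function(x, ...) {
  cat(sprintf(paste0("VOR at %.4g Hz\n",
                     "  gain:  %.4f  (%.4g / %.4g deg/s)\n",
                     "  phase: %.4f deg (%.4f rad), positive = eye leads\n"),
              x$f, x$gain, x$eye_fit$v, x$table_fit$v,
              x$phase_deg, x$phase_rad))
  invisible(x)
}

#' One-shot VOR analysis from table angle and eye poses
#'
#' Differentiates the unwrapped table angle with the same central-difference
#' scheme used for eye velocity, fits the table velocity with a free frequency,
#' fits the signed eye rotation speed at that frequency, and returns gain and
#' phase.
#'
#' @param table data.frame with columns `t` (seconds) and `angle` (degrees,
#'   unwrapped).
#' @param poses reconstructed pose series (see [reconstruct_poses()]).
#' When `lowpass_hz` is set, the identical zero-phase low-pass is applied to
#' the table angle and to the eye rotation-vector series, so the filter's
#' pass-band attenuation cancels in the gain ratio and no phase shift is
#' introduced; noisy recordings should use a cutoff a small multiple of the
#' stimulus frequency.
#'
#' @param f optional fixed stimulus frequency in Hz; default estimates it from
#'   the table trace.
#' @param lowpass_hz optional low-pass cutoff in Hz applied symmetrically to
#'   both streams before differencing (NULL = none).
#' @return a `vor_result` (see [compute_gain_phase()]).
#' @export
vor_analysis <- function(table, poses, f = NULL, lowpass_hz = NULL) {
  if (nrow(table) != nrow(poses))
    stop_vog("table and eye streams differ in frame count",
             "vog3d_contract_error")
  ok <- is.finite(table$angle)
  if (sum(ok) < 3)
    stop_vog("too few valid table frames", "vog3d_input_error")
  tt <- table$t[ok]
  ang <- table$angle[ok]
  if (!is.null(lowpass_hz))
    ang <- lowpass_series(ang, 1 / mean(diff(tt)), lowpass_hz)
  vel <- central_diff(ang, mean(diff(tt)))[, 1]
  table_fit <- fit_sinusoid(tt, vel, f = f)
  eye <- signed_eye_speed(poses, lowpass_hz = lowpass_hz)
  eye_fit <- fit_sinusoid(eye$t, eye$speed, f = table_fit$f)
  compute_gain_phase(table_fit, eye_fit)
}
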