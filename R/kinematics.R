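# ---- internal vector helpers -------------------------------------------------

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stop_vog <- function(msg, class) {
  stop(structure(class = c(class, "vog3d_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Rotation matrix from axis and angle (Rodrigues' formula)
#'
#' Builds the exact rotation matrix for a rotation of `angle_deg` degrees about
#' the unit axis `axis`, using Rodrigues' formula
#' \eqn{R = I + \sin\theta K + (1-\cos\theta)K^2} where K is the skew matrix of
#' the axis. Serves as the forward-model oracle for the rotation-vector
#' conversions.
#'
#' @param axis numeric length-3 unit vector (X toward the camera, Y right from
#'   the examiner's view, Z up).
#' @param angle_deg rotation angle in degrees (right-hand rule about `axis`).
#' @return 3x3 rotation matrix.
#' @export
rodrigues_matrix <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  if (length(axis) != 3 || !all(is.finite(axis)))
    stop_vog("axis must be a finite length-3 vector", "vog3d_input_error")
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-8)
    stop_vog("axis must have unit norm", "vog3d_input_error")
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation vector for a rotation about an axis
#'
#' Convenience constructor: the rotation vector of a rotation by `angle_deg`
#' about unit `axis` is \eqn{\tan(\theta/2)} times the axis.
#'
#' @inheritParams rodrigues_matrix
#' @return numeric length-3 rotation vector (unitless, magnitude tan(theta/2)).
#' @export
rotation_vector <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-8)
    stop_vog("axis must have unit norm", "vog3d_input_error")
  tan(deg2rad(angle_deg) / 2) * axis
}

#' Eye pose matrix from reference and current landmark triads
#'
#' The eye pose is the rotation taking the reference landmark configuration to
#' the current one. Each configuration is summarized by the triad of the 3D
#' pupil-center vector, the 3D iris-freckle vector, and their cross product
#' (all measured from the center of eye rotation). With the triads arranged as
#' columns of matrices A_ref and A_cur, the pose matrix solves
#' M A_ref = A_cur, i.e. M = A_cur A_ref^-1. The cross-product column is used
#' raw (not normalized); since rotations preserve cross products, M is an exact
#' rotation for exact rigid input.
#'
#' @param ref_pupil,ref_freckle 3D landmark vectors at the reference position.
#' @param cur_pupil,cur_freckle 3D landmark vectors at the current position.
#' @param max_condition maximum acceptable condition number of the reference
#'   triad; beyond it the configuration is treated as degenerate.
#' @param orthogonalize if TRUE, project M onto the nearest rotation matrix by
#'   polar decomposition (useful for noisy landmarks; default FALSE leaves the
#'   raw product).
#' @return 3x3 pose matrix.
#' @export
pose_matrix <- function(ref_pupil, ref_freckle, cur_pupil, cur_freckle,
                        max_condition = 1e8, orthogonalize = FALSE) {
  rp <- as.numeric(ref_pupil); rf <- as.numeric(ref_freckle)
  cp <- as.numeric(cur_pupil); cf <- as.numeric(cur_freckle)
  A_ref <- cbind(rp, rf, cross3(rp, rf), deparse.level = 0)
  A_cur <- cbind(cp, cf, cross3(cp, cf), deparse.level = 0)
  sv <- svd(A_ref, nu = 0, nv = 0)$d
  if (sv[3] <= 0 || sv[1] / sv[3] > max_condition)
    stop_vog("reference landmark triad is singular or ill-conditioned",
             "vog3d_degeneracy_error")
  M <- A_cur %*% solve(A_ref)
  if (orthogonalize) {
    s <- svd(M)
    M <- s$u %*% t(s$v)
    if (det(M) < 0) M <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  }
  M
}

#' Rotation vector of an eye pose matrix
#'
#' Converts a pose matrix M to the rotation vector
#' \deqn{r = (R_{32}-R_{23},\; R_{13}-R_{31},\; R_{21}-R_{12}) / (1 + \mathrm{tr}\,M),}
#' whose direction is the rotation axis and whose magnitude is
#' \eqn{\tan(\theta/2)} of the rotation angle relative to the reference
#' position.
#'
#' @param M 3x3 pose matrix.
#' @param trace_eps rejection threshold on 1 + trace(M); rotations approaching
#'   180 degrees are outside the physiological range and are refused rather
#'   than amplified.
#' @return numeric length-3 rotation vector.
#' @export
rotation_vector_from_matrix <- function(M, trace_eps = 1e-8) {
  if (!is.matrix(M) || any(dim(M) != c(3, 3)) || !all(is.finite(M)))
    stop_vog("M must be a finite 3x3 matrix", "vog3d_input_error")
  den <- 1 + M[1, 1] + M[2, 2] + M[3, 3]
  if (den <= trace_eps)
    stop_vog("rotation angle too close to 180 degrees (1 + trace ~ 0)",
             "vog3d_range_error")
  c(M[3, 2] - M[2, 3], M[1, 3] - M[3, 1], M[2, 1] - M[1, 2]) / den
}

#' Axis-angle representation of a rotation vector
#'
#' Rescales a rotation vector r (magnitude tan(theta/2)) to the axis-angle
#' vector a = 2 atan(|r|) r / |r|, reported in degrees: the direction is the
#' rotation axis and the magnitude is the Euler rotation angle.
#'
#' @param r numeric length-3 rotation vector.
#' @return numeric length-3 axis-angle vector in degrees; (0,0,0) maps to
#'   (0,0,0).
#' @export
axis_angle_from_rotation_vector <- function(r) {
  r <- as.numeric(r)
  if (length(r) != 3 || !all(is.finite(r)))
    stop_vog("r must be a finite length-3 vector", "vog3d_input_error")
  n <- sqrt(sum(r^2))
  if (n == 0) return(c(0, 0, 0))
  rad2deg(2 * atan(n)) * r / n
}

# central differences with 2-point one-sided stencils at the ends;
# x is an n-vector or n x k matrix sampled at uniform spacing dt
central_diff <- function(x, dt) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- x
  d[2:(n - 1), ] <- (x[3:n, , drop = FALSE] - x[1:(n - 2), , drop = FALSE]) / (2 * dt)
  d[1, ] <- (x[2, ] - x[1, ]) / dt
  d[n, ] <- (x[n, ] - x[n - 1, ]) / dt
  d
}

#' Angular velocity from a rotation-vector time series
#'
#' Computes the angular-velocity vector
#' \deqn{\omega = 2\,(\dot r + r \times \dot r)/(1 + |r|^2)}
#' from a uniformly sampled rotation-vector series, with the time derivative
#' estimated by central differences (one-sided two-point stencils at the two
#' endpoints). The signed rotation speed is the Euclidean norm of omega signed
#' by its Z (yaw) component, so that a single scalar trace encodes rotation
#' direction about the (Z-dominant) axis of eye rotation.
#'
#' @param t numeric vector of sample times in seconds, strictly increasing and
#'   uniformly spaced (relative tolerance 1e-6).
#' @param r n x 3 matrix (or data.frame) of rotation vectors, one row per
#'   sample.
#' @return data.frame with columns `t`, `wx`, `wy`, `wz` (degrees/second) and
#'   `signed_speed` (degrees/second, norm of omega signed by wz).
#' @export
angular_velocity <- function(t, r) {
  t <- as.numeric(t)
  r <- as.matrix(r)
  storage.mode(r) <- "double"
  n <- length(t)
  if (n < 3)
    stop_vog("angular velocity needs at least 3 samples", "vog3d_input_error")
  if (nrow(r) != n || ncol(r) != 3)
    stop_vog("r must be an n x 3 matrix matching t", "vog3d_input_error")
  dts <- diff(t)
  if (any(dts <= 0))
    stop_vog("t must be strictly increasing", "vog3d_input_error")
  dt <- mean(dts)
  if (any(abs(dts - dt) > 1e-6 * dt))
    stop_vog("t must be uniformly spaced (relative tolerance 1e-6)",
             "vog3d_input_error")
  dr <- central_diff(r, dt)
  cr <- cbind(r[, 2] * dr[, 3] - r[, 3] * dr[, 2],
              r[, 3] * dr[, 1] - r[, 1] * dr[, 3],
              r[, 1] * dr[, 2] - r[, 2] * dr[, 1])
  w <- 2 * (dr + cr) / (1 + rowSums(r^2))   # rad/s
  w <- rad2deg(w)
  speed <- sqrt(rowSums(w^2))
  sgn <- ifelse(w[, 3] < 0, -1, 1)
  data.frame(t = t, wx = w[, 1], wy = w[, 2], wz = w[, 3],
             signed_speed = speed * sgn)
}
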