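#' Quaternion utilities
#'
#' Vectorized unit-quaternion operations used throughout the rigid-body
#' kinematics. Quaternions are stored as n x 4 numeric matrices in
#' scalar-first order `(w, x, y, z)`; a single quaternion may be given as a
#' length-4 vector. All rotation quaternions map body-frame vectors into the
#' earth frame: `v_earth = q %q% v_body %q% q*`.
#'
#' @name quaternion
#' @keywords internal
NULL

as_quat_matrix <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  stopifnot(ncol(q) == 4)
  q
}

#' Normalize quaternions to unit length
#' @param q n x 4 matrix or length-4 vector, scalar-first.
#' @return n x 4 matrix of unit quaternions.
#' @export
quat_normalize <- function(q) {
  q <- as_quat_matrix(q)
  q / sqrt(rowSums(q^2))
}

#' Hamilton product of quaternion arrays
#'
#' Row-wise product `a * b`; either argument may be a single quaternion which
#' is recycled.
#' @param a,b n x 4 matrices (or length-4 vectors), scalar-first.
#' @return n x 4 matrix.
#' @export
quat_multiply <- function(a, b) {
  a <- as_quat_matrix(a); b <- as_quat_matrix(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  cbind(w, x, y, z, deparse.level = 0)
}

#' Quaternion conjugate
#' @param q n x 4 matrix or length-4 vector.
#' @return n x 4 matrix.
#' @export
quat_conjugate <- function(q) {
  q <- as_quat_matrix(q)
  cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4], deparse.level = 0)
}

#' Rotate vectors by quaternions
#'
#' Applies `v' = q v q*` row-wise (body-to-earth for segment orientations).
#' @param q n x 4 quaternions (or a single one, recycled).
#' @param v n x 3 vectors (or a single one, recycled).
#' @return n x 3 matrix of rotated vectors.
#' @export
quat_rotate <- function(q, v) {
  q <- as_quat_matrix(q)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  n <- max(nrow(q), nrow(v))
  if (nrow(q) == 1L) q <- q[rep(1L, n), , drop = FALSE]
  if (nrow(v) == 1L) v <- v[rep(1L, n), , drop = FALSE]
  # v' = v + 2 q_w (u x v) + 2 u x (u x v), u = vector part
  u <- q[, 2:4, drop = FALSE]
  uv <- cross3(u, v)
  uuv <- cross3(u, uv)
  v + 2 * q[, 1] * uv + 2 * uuv
}

#' Row-wise cross product of 3-vectors
#' @param a,b n x 3 matrices.
#' @return n x 3 matrix.
#' @keywords internal
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1], deparse.level = 0)
}

#' Quaternion from axis-angle
#' @param axis unit 3-vector (or n x 3 matrix of unit vectors).
#' @param angle rotation angle(s) in radians.
#' @return n x 4 matrix of unit quaternions.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  if (is.null(dim(axis))) axis <- matrix(axis, nrow = 1)
  n <- max(nrow(axis), length(angle))
  if (nrow(axis) == 1L) axis <- axis[rep(1L, n), , drop = FALSE]
  angle <- rep_len(angle, n)
  h <- angle / 2
  cbind(cos(h), sin(h) * axis[, 1], sin(h) * axis[, 2], sin(h) * axis[, 3],
        deparse.level = 0)
}

#' Convert a single quaternion to a 3 x 3 rotation matrix
#' @param q length-4 unit quaternion, scalar-first.
#' @return 3 x 3 rotation matrix (body to earth).
#' @export
quat_to_matrix <- function(q) {
  q <- as.numeric(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Convert a 3 x 3 rotation matrix to a quaternion
#' @param R rotation matrix.
#' @return length-4 unit quaternion with non-negative scalar part.
#' @export
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Relative rotation angle between quaternion pairs
#' @param a,b n x 4 matrices.
#' @return numeric vector of angles (rad) of the rotation taking `a` to `b`.
#' @export
quat_angle_between <- function(a, b) {
  d <- quat_multiply(quat_conjugate(as_quat_matrix(a)), as_quat_matrix(b))
  2 * atan2(sqrt(rowSums(d[, 2:4, drop = FALSE]^2)), abs(d[, 1]))
}
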