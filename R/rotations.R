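# Quaternion and rotation-matrix algebra.
#
# Conventions used throughout the package:
#  * a quaternion is a numeric vector c(w, x, y, z), unit norm, hemisphere w >= 0;
#  * q represents the orientation of a body (sensor or segment) frame relative to
#    the lab frame: v_lab = R(q) %*% v_body, i.e. the columns of R(q) are the body
#    axes expressed in lab coordinates;
#  * the lab frame is right-handed, x = skating direction, z = up;
#  * orientation series store one quaternion per row of an n x 4 matrix.

#' Normalize a quaternion
#'
#' Scales to unit norm and flips the sign so that `w >= 0` (the hemisphere
#' convention used package-wide; `q` and `-q` encode the same rotation).
#'
#' @param q Numeric vector `c(w, x, y, z)`.
#' @return Unit quaternion with non-negative scalar part.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < .Machine$double.eps * 10)
    stop("cannot normalize a zero quaternion", call. = FALSE)
  q <- q / n
  if (q[1] < 0) q <- -q
  q
}

#' Quaternion product
#'
#' Hamilton product `a %q% b`; composing rotations, `R(quat_multiply(a, b)) =
#' R(a) %*% R(b)`.
#'
#' @param a,b Quaternions `c(w, x, y, z)`.
#' @return The product quaternion (not re-normalized).
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' @rdname quat_multiply
#' @export
quat_conjugate <- function(a) c(a[1], -a[2], -a[3], -a[4])

#' Rotate a 3-vector by a quaternion
#'
#' Applies the body-to-lab rotation encoded by `q`: `quat_rotate(q, v_body)`
#' gives `v_lab`.
#'
#' @param q Unit quaternion.
#' @param v Numeric 3-vector.
#' @return Rotated 3-vector.
#' @export
quat_rotate <- function(q, v) {
  # q * (0, v) * q^-1, expanded for speed
  t <- 2 * cross3(q[2:4], v)
  v + q[1] * t + cross3(q[2:4], t)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Convert between quaternions and rotation matrices
#'
#' `quat_to_matrix` returns the direction-cosine matrix `R` with
#' `v_lab = R %*% v_body`. `matrix_to_quat` is its inverse (Shepperd's method,
#' numerically stable for all rotations).
#'
#' @param q Unit quaternion.
#' @param R 3x3 proper rotation matrix.
#' @return A 3x3 matrix, resp. a unit quaternion.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' @rdname quat_to_matrix
#' @export
matrix_to_quat <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  quat_normalize(q)
}

#' Axis-angle and rotation-vector forms
#'
#' `quat_from_axis_angle(axis, angle)` builds the unit quaternion for a
#' rotation of `angle` radians about `axis`. `quat_from_rotvec(v)` takes a
#' rotation vector (axis times angle, radians); `quat_to_rotvec` inverts it.
#'
#' @param axis Numeric 3-vector (need not be unit length).
#' @param angle Rotation angle in radians.
#' @param v Rotation vector in radians.
#' @return A unit quaternion, resp. a 3-vector.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps * 10) stop("zero rotation axis", call. = FALSE)
  quat_normalize(c(cos(angle / 2), sin(angle / 2) * axis / n))
}

#' @rdname quat_from_axis_angle
#' @export
quat_from_rotvec <- function(v) {
  angle <- sqrt(sum(v^2))
  if (angle < 1e-300) return(c(1, 0, 0, 0))
  # sinc form is stable for small angles
  c(cos(angle / 2), v * (sin(angle / 2) / angle))
}

#' @rdname quat_from_axis_angle
#' @export
quat_to_rotvec <- function(q) {
  q <- quat_normalize(q)
  s <- sqrt(sum(q[2:4]^2))
  if (s < 1e-300) return(c(0, 0, 0))
  angle <- 2 * atan2(s, q[1])
  q[2:4] * (angle / s)
}

#' Geodesic angle between two orientations
#'
#' The smallest rotation angle (radians) taking orientation `a` to `b`; the
#' error metric used for all orientation comparisons in the package.
#'
#' @param a,b Unit quaternions.
#' @return Angle in radians, in `[0, pi]`.
#' @export
quat_angle <- function(a, b) {
  d <- abs(sum(a * b))
  2 * acos(min(1, d))
}

#' Validate a rotation matrix
#'
#' Checks orthonormality and `det = +1` within `tol`.
#'
#' @param R 3x3 matrix.
#' @param tol Numeric tolerance.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
check_rotation <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || any(dim(R) != c(3, 3)) || any(!is.finite(R)))
    stop("not a finite 3x3 matrix", call. = FALSE)
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("matrix is not orthonormal within tolerance", call. = FALSE)
  if (abs(det(R) - 1) > tol)
    stop("matrix determinant is not +1 within tolerance", call. = FALSE)
  invisible(TRUE)
}

#' Orientation time series
#'
#' Container pairing timestamps with one unit quaternion per sample
#' (lab-to-body convention, see [quat_to_matrix]).
#'
#' @param t Numeric vector of timestamps (s), strictly increasing.
#' @param q n x 4 matrix of quaternions, one row per sample.
#' @return An object of class `orientation_series`.
#' @export
orientation_series <- function(t, q) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 4)
  stopifnot(length(t) == nrow(q), ncol(q) == 4)
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  q <- t(apply(q, 1, quat_normalize))
  structure(list(t = as.numeric(t), q = q), class = "orientation_series")
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("<orientation_series: %d samples, %.2f-%.2f s>\n",
              length(x$t), min(x$t), max(x$t)))
  invisible(x)
}

#' @export
length.orientation_series <- function(x) length(x$t)

# mean orientation of a window: normalized sum of hemisphere-aligned quaternions
# (adequate for tightly clustered samples, e.g. a static calibration window)
quat_mean <- function(qmat) {
  ref <- qmat[1, ]
  s <- colSums(qmat * ifelse(qmat %*% ref >= 0, 1, -1)[, 1])
  quat_normalize(s)
}
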