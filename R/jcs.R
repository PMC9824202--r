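# Grood-Suntay joint coordinate system (JCS) angle decomposition.
#
# Segment frames follow the package convention x = anterior, y = proximal
# (longitudinal, up), z = mediolateral (to the right, right leg). The JCS
# axes are then: e1 = proximal z (flexion/extension), e3 = distal y
# (internal/external rotation), e2 = floating axis (ab/adduction). This is
# algebraically the intrinsic Z-X'-Y'' Cardan sequence of the relative
# rotation M = R_prox^T R_dist:
#
#   M = Rz(flexion) Rx(adduction) Ry(rotation)
#
# Sign conventions (right leg): positive flexion tilts the distal anterior
# axis upward (hip flexion, knee "extension-positive" convention is NOT used
# - knee flexion is negative under this sign - and ankle dorsiflexion is
# positive); positive adduction moves the distal end toward the midline;
# positive rotation is internal. The left-side signs mirror by negating
# adduction and rotation.

#' Compose a JCS rotation
#'
#' Builds the relative rotation matrix corresponding to given flexion,
#' adduction and rotation angles (degrees), i.e. the exact inverse of the
#' decomposition in [jcs_angles]. Used by the stride simulator's forward
#' kinematics and by round-trip tests.
#'
#' @param flexion,adduction,rotation Angles in degrees.
#' @return 3x3 rotation matrix `Rz(flexion) Rx(adduction) Ry(rotation)`.
#' @export
jcs_rotation <- function(flexion, adduction, rotation) {
  f <- flexion * pi / 180; a <- adduction * pi / 180; r <- rotation * pi / 180
  Rz <- matrix(c(cos(f), -sin(f), 0, sin(f), cos(f), 0, 0, 0, 1), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
  Ry <- matrix(c(cos(r), 0, sin(r), 0, 1, 0, -sin(r), 0, cos(r)), 3, byrow = TRUE)
  Rz %*% Rx %*% Ry
}

# decompose one relative rotation matrix into (flexion, adduction, rotation) deg
.jcs_decompose <- function(M) {
  adduction <- asin(max(-1, min(1, M[3, 2])))
  flexion <- atan2(-M[1, 2], M[2, 2])
  rotation <- atan2(-M[3, 1], M[3, 3])
  c(flexion, adduction, rotation) * 180 / pi
}

# remove +-360 deg jumps within a trace
unwrap_deg <- function(x) {
  if (length(x) < 2) return(x)
  d <- diff(x)
  steps <- -360 * round(d / 360)
  x + c(0, cumsum(steps))
}

#' Joint angles in the joint coordinate system
#'
#' Decomposes the per-sample relative rotation of a distal segment with
#' respect to its proximal segment into Grood-Suntay flexion, adduction and
#' rotation angles (degrees); see the convention notes in [jcs_rotation].
#' Traces are unwrapped within the trial (no ±360 deg jumps). Samples with
#' |adduction| within 1 deg of the 90 deg floating-axis singularity are
#' flagged in the `gimbal` attribute and raise a warning.
#'
#' @param r_proximal,r_distal [orientation_series] of the two segments on a
#'   common clock.
#' @param joint Label stored with the output, one of `"hip"`, `"knee"`,
#'   `"ankle"`.
#' @return Object of class `joint_angle_series`: data frame with columns `t`,
#'   `flexion`, `adduction`, `rotation` (degrees) and attributes `joint` and
#'   `gimbal` (logical per sample).
#' @export
jcs_angles <- function(r_proximal, r_distal, joint = c("hip", "knee", "ankle")) {
  joint <- match.arg(joint)
  stopifnot(inherits(r_proximal, "orientation_series"),
            inherits(r_distal, "orientation_series"))
  if (length(r_proximal$t) != length(r_distal$t) ||
      max(abs(r_proximal$t - r_distal$t)) > 1e-9)
    stop("proximal and distal series are not on a common clock", call. = FALSE)
  n <- length(r_proximal$t)
  ang <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    M <- crossprod(quat_to_matrix(r_proximal$q[i, ]),
                   quat_to_matrix(r_distal$q[i, ]))
    ang[i, ] <- .jcs_decompose(M)
  }
  ang[, 1] <- unwrap_deg(ang[, 1])
  ang[, 3] <- unwrap_deg(ang[, 3])
  gimbal <- abs(ang[, 2]) > 89
  if (any(gimbal))
    warning(sprintf("jcs_angles(%s): %d sample(s) near the floating-axis singularity",
                    joint, sum(gimbal)), call. = FALSE)
  out <- data.frame(t = r_proximal$t, flexion = ang[, 1],
                    adduction = ang[, 2], rotation = ang[, 3])
  structure(out, class = c("joint_angle_series", "data.frame"),
            joint = joint, gimbal = gimbal)
}

#' Angle-series accessors
#'
#' `joint_of` returns the joint label of a [jcs_angles] result.
#'
#' @param x A `joint_angle_series`.
#' @return Character scalar.
#' @export
joint_of <- function(x) attr(x, "joint")
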