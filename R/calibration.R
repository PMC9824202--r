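# Marker-based calibration rotations: sensor-to-plate and sensor-to-body,
# both estimated in a static window at the start of the capturing session,
# plus the per-sample composition giving segment orientations from fused
# sensor orientations.

#' Plate frame from its retro-reflective markers
#'
#' Builds the rigid-plate coordinate frame from at least three labelled
#' markers fixed on the sensor mounting plate. Axis recipe (markers in listed
#' order P1, P2, P3): origin at P1, x along `P2 - P1`, z along
#' `x × (P3 - P1)`, y completing the right-handed frame; so markers at
#' `(0,0,0)`, `(1,0,0)`, `(0,1,0)` give the identity frame.
#'
#' @param markers 3 x 3 (or more rows) numeric matrix, one marker per row,
#'   lab-frame metres.
#' @return 3x3 rotation matrix (lab-to-plate, columns = plate axes in lab).
#' @export
plate_frame_from_markers <- function(markers) {
  markers <- as.matrix(markers)
  if (nrow(markers) < 3 || any(!is.finite(markers)))
    stop("need >= 3 finite plate markers", call. = FALSE)
  x <- markers[2, ] - markers[1, ]
  v <- markers[3, ] - markers[1, ]
  z <- cross3(x, v)
  nx <- sqrt(sum(x^2)); nz <- sqrt(sum(z^2))
  if (nx < 1e-12 || nz < 1e-9 * nx * sqrt(sum(v^2)) || nz < 1e-12)
    stop("degenerate geometry: plate markers collinear or coincident", call. = FALSE)
  x <- x / nx; z <- z / nz
  R <- cbind(x, cross3(z, x), z)
  dimnames(R) <- NULL
  R
}

#' Sensor-to-plate calibration rotation
#'
#' Constant rotation relating the fused sensor orientation to the marker-based
#' plate orientation, estimated while both are captured in the same still
#' window: `r_plate = r_sensor %*% r_sensor_to_plate`.
#'
#' @param q_sensor_static Unit quaternion (fused sensor orientation, static).
#' @param r_plate_static 3x3 rotation matrix from [plate_frame_from_markers].
#' @return 3x3 rotation matrix.
#' @export
compute_sensor_to_plate <- function(q_sensor_static, r_plate_static) {
  if (abs(sqrt(sum(q_sensor_static^2)) - 1) > 1e-6)
    stop("invalid rotation: quaternion is not unit norm", call. = FALSE)
  check_rotation(r_plate_static, tol = 1e-6)
  t(quat_to_matrix(q_sensor_static)) %*% r_plate_static
}

#' Sensor-to-body calibration rotation
#'
#' Constant alignment mapping the sensor frame onto the anatomical segment
#' frame, from the static upright calibration pose:
#' `r_segment = r_sensor %*% r_sensor_to_body`. Identical composition to
#' [compute_sensor_to_plate] with the anatomical frame in place of the plate
#' frame.
#'
#' @param q_sensor_static Unit quaternion (fused sensor orientation, static).
#' @param segment_frame_static 3x3 rotation matrix of the marker-based
#'   anatomical frame in the same window (see [anatomical_frame]).
#' @return 3x3 rotation matrix.
#' @export
compute_sensor_to_body <- function(q_sensor_static, segment_frame_static) {
  compute_sensor_to_plate(q_sensor_static, segment_frame_static)
}

#' Segment orientation stream from a fused sensor stream
#'
#' Right-composes every sensor quaternion with the constant sensor-to-body
#' alignment from the same session.
#'
#' @param q_sensor An [orientation_series] of fused sensor orientations.
#' @param r_sensor_to_body 3x3 rotation matrix from [compute_sensor_to_body]
#'   (or the chained sensor-to-plate and plate-to-body rotations).
#' @return An [orientation_series] of segment orientations.
#' @export
segment_orientation <- function(q_sensor, r_sensor_to_body) {
  stopifnot(inherits(q_sensor, "orientation_series"))
  check_rotation(r_sensor_to_body, tol = 1e-6)
  qc <- matrix_to_quat(r_sensor_to_body)
  out <- t(apply(q_sensor$q, 1, function(q) quat_multiply(q, qc)))
  orientation_series(q_sensor$t, out)
}
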