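# Complementary-filter sensor fusion: gyroscope strapdown integration with
# proportional corrections toward the accelerometer (gravity) and magnetometer
# (heading) reference directions.

#' Raw IMU recording
#'
#' Bundles the three tri-axial channels of one sensor for one trial on a
#' uniform clock. Accelerometer samples are specific force in m/s^2 (a
#' stationary sensor reads +9.81 along lab z, i.e. gravity is included);
#' gyroscope samples are body-frame angular rate in rad/s, with sample `i`
#' interpreted as the mean rate over `[t_i, t_{i+1})`; magnetometer samples
#' are in Gauss.
#'
#' @param t Timestamps in seconds, uniformly spaced.
#' @param gyro,accel,mag n x 3 numeric matrices.
#' @return An object of class `imu_recording` with element `fs` (Hz).
#' @export
imu_recording <- function(t, gyro, accel, mag) {
  gyro <- as.matrix(gyro); accel <- as.matrix(accel); mag <- as.matrix(mag)
  n <- length(t)
  if (!all(c(nrow(gyro), nrow(accel), nrow(mag)) == n))
    stop("channel sample counts differ", call. = FALSE)
  stopifnot(ncol(gyro) == 3, ncol(accel) == 3, ncol(mag) == 3)
  dt <- diff(t)
  if (n > 1 && (any(dt <= 0) || diff(range(dt)) > 1e-6))
    stop("timestamps must be uniform and increasing", call. = FALSE)
  structure(list(t = as.numeric(t), gyro = gyro, accel = accel, mag = mag,
                 fs = if (n > 1) 1 / dt[1] else NA_real_),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording: %d samples @ %.1f Hz>\n", length(x$t), x$fs))
  invisible(x)
}

#' Complementary filter parameters
#'
#' Per-sample proportional gains and reference vectors for [fuse_imu]. The
#' accelerometer correction is additionally weighted by an
#' acceleration-magnitude trust gate: full weight while `|norm(accel) - norm(ref_gravity)|`
#' is below `accel_trust_band[1]` m/s^2, tapering linearly to zero at
#' `accel_trust_band[2]`. The gate suppresses the gravity correction while the
#' segment itself accelerates (push-off, leg swing), when the measured specific
#' force no longer points along gravity.
#'
#' @param accel_gain Proportional gain of the gravity (roll/pitch) correction,
#'   per sample, in `[0, 1]`.
#' @param mag_gain Proportional gain of the heading correction, per sample, in
#'   `[0, 1]`. Applied only about the gravity axis so the magnetometer cannot
#'   disturb inclination.
#' @param ref_gravity Specific force read by a stationary sensor, lab frame
#'   (m/s^2).
#' @param ref_field Magnetic field in the lab frame (Gauss); must not be
#'   parallel to `ref_gravity`.
#' @param accel_trust_band Two increasing non-negative numbers (m/s^2), see
#'   above.
#' @return An object of class `fusion_params`.
#' @export
fusion_params <- function(accel_gain = 0.0005, mag_gain = 0.005,
                          ref_gravity = c(0, 0, 9.81),
                          ref_field = c(0.4, 0, -0.3),
                          accel_trust_band = c(0.5, 2)) {
  stopifnot(accel_gain >= 0, accel_gain <= 1, mag_gain >= 0, mag_gain <= 1,
            length(ref_gravity) == 3, length(ref_field) == 3,
            length(accel_trust_band) == 2,
            accel_trust_band[1] >= 0,
            accel_trust_band[2] > accel_trust_band[1])
  ng <- sqrt(sum(ref_gravity^2)); nf <- sqrt(sum(ref_field^2))
  if (ng == 0 || nf == 0)
    stop("reference vectors must be non-zero", call. = FALSE)
  cosang <- abs(sum(ref_gravity * ref_field)) / (ng * nf)
  if (cosang > 1 - 1e-6)
    stop("reference gravity and field must not be parallel", call. = FALSE)
  structure(list(accel_gain = accel_gain, mag_gain = mag_gain,
                 ref_gravity = ref_gravity, ref_field = ref_field,
                 accel_trust_band = accel_trust_band),
            class = "fusion_params")
}

#' Static orientation from one accelerometer/magnetometer sample
#'
#' TRIAD algorithm: builds orthonormal triads from the two reference vectors in
#' the lab frame and the two measured vectors in the body frame; the rotation
#' mapping one onto the other is the body-to-lab orientation. Used to
#' initialize [fuse_imu] and valid only while the sensor is (quasi-)static.
#'
#' @param accel,mag Measured 3-vectors (body frame).
#' @param params A [fusion_params] object supplying the lab references.
#' @return Unit quaternion (lab-to-body convention of [quat_to_matrix]).
#' @export
quat_from_triad <- function(accel, mag, params = fusion_params()) {
  triad <- function(a, b) {
    t1 <- a / sqrt(sum(a^2))
    t2 <- cross3(a, b); t2 <- t2 / sqrt(sum(t2^2))
    cbind(t1, t2, cross3(t1, t2))
  }
  Tlab <- triad(params$ref_gravity, params$ref_field)
  Tbody <- triad(accel, mag)
  matrix_to_quat(Tlab %*% t(Tbody))
}

#' Fuse an IMU recording into an orientation time series
#'
#' Strapdown integration of the gyroscope (first-order quaternion exponential
#' update per sample), with per-sample proportional corrections:
#' \itemize{
#'   \item gravity: the measured specific-force direction is compared with the
#'     direction predicted from the current orientation estimate; the estimate
#'     is rotated toward agreement by `accel_gain` times the discrepancy,
#'     weighted by the acceleration-magnitude trust gate (see
#'     [fusion_params]);
#'   \item heading: the same construction with the magnetometer, restricted to
#'     rotation about the gravity axis so it only steers yaw.
#' }
#' Zero-norm accelerometer or magnetometer samples skip their correction for
#' that sample (a single warning reports the count).
#'
#' @param rec An [imu_recording] (already low-pass filtered upstream).
#' @param params A [fusion_params] object.
#' @param q0 Initial orientation quaternion; default is a TRIAD fix from the
#'   first sample.
#' @return An [orientation_series], one quaternion per input sample.
#' @export
fuse_imu <- function(rec, params = fusion_params(), q0 = NULL) {
  stopifnot(inherits(rec, "imu_recording"), inherits(params, "fusion_params"))
  n <- length(rec$t)
  dt <- if (n > 1) rec$t[2] - rec$t[1] else 0
  gdir <- params$ref_gravity / sqrt(sum(params$ref_gravity^2))
  bdir <- params$ref_field / sqrt(sum(params$ref_field^2))
  gmag <- sqrt(sum(params$ref_gravity^2))
  band <- params$accel_trust_band

  if (is.null(q0)) q0 <- quat_from_triad(rec$accel[1, ], rec$mag[1, ], params)
  q <- quat_normalize(q0)

  out <- matrix(NA_real_, n, 4)
  skipped <- 0L

  correct <- function(q, i) {
    # gravity correction (roll/pitch)
    a <- rec$accel[i, ]
    na <- sqrt(sum(a^2))
    if (na == 0) { skipped <<- skipped + 1L } else if (params$accel_gain > 0) {
      w <- 1 - (abs(na - gmag) - band[1]) / (band[2] - band[1])
      w <- min(1, max(0, w))
      if (w > 0) {
        u <- a / na
        v <- quat_rotate(quat_conjugate(q), gdir)     # predicted gravity, body frame
        q <- quat_multiply(q, quat_from_rotvec(params$accel_gain * w * cross3(u, v)))
      }
    }
    # heading correction (yaw only)
    m <- rec$mag[i, ]
    nm <- sqrt(sum(m^2))
    if (nm == 0) { skipped <<- skipped + 1L } else if (params$mag_gain > 0) {
      u <- m / nm
      v <- quat_rotate(quat_conjugate(q), bdir)
      vg <- quat_rotate(quat_conjugate(q), gdir)
      d <- params$mag_gain * cross3(u, v)
      q <- quat_multiply(q, quat_from_rotvec(sum(d * vg) * vg))
    }
    quat_normalize(q)
  }

  q <- correct(q, 1L)
  out[1, ] <- q
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      q <- quat_multiply(q, quat_from_rotvec(rec$gyro[i, ] * dt))
      q <- correct(q, i + 1L)
      out[i + 1, ] <- q
    }
  }
  if (skipped > 0)
    warning(sprintf("fuse_imu: %d zero-norm reference samples skipped", skipped),
            call. = FALSE)
  orientation_series(rec$t, out)
}
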