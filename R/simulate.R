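# Synthetic skating cohorts with known ground truth: stride kinematics from
# periodic keypoint splines, forward-kinematics segment poses and virtual
# markers, virtual IMU readouts with a documented noise model, and stride
# events. This module is the test bed for every other stage.

# keypoint phases within one stride (fractions of stride_duration)
.KP_PHASES <- c(ic = 0, mid = 0.35, po = 0.7, poe = 0.9)

#' Stride kinematics parameters
#'
#' Keypoint joint angles (degrees) at the stride events — initial contact,
#' mid-stance, push-off start, push-off end — through which C2-smooth
#' periodic cubic splines are drawn, plus CoM sway amplitudes and the
#' calibre effect sizes. Defaults describe a forward skating stride of the
#' right (dominant) leg in the package's JCS sign convention (knee flexion
#' negative, ankle dorsiflexion positive).
#'
#' `calibre_deltas` are degree offsets added to the keypoints that generate
#' the named features, for high-calibre participants only; supported names:
#' `dorsiflexion_range` (ankle flexion mid-stance keypoint),
#' `hip_adduction_at_push_off` (hip adduction push-off keypoint),
#' `knee_flexion_at_push_off` (knee flexion push-off keypoint).
#'
#' @param stride_duration Stride period in seconds.
#' @param keypoints Named list `joint -> axis -> numeric(4)` of angles (deg)
#'   at phases `ic`, `mid`, `po`, `poe`.
#' @param com_sway_ml,com_sway_vertical CoM sway amplitudes (m).
#' @param speed Forward skating speed (m/s).
#' @param pelvis_height Standing pelvis height (m).
#' @param calibre_deltas Named numeric vector of high-calibre keypoint
#'   offsets (deg), see above.
#' @param effort_sd Sd of the per-trial whole-body "effort" amplitude factor
#'   (dimensionless, multiplicative; scales all keypoints and CoM sway
#'   coherently and is the dominant trial-to-trial variability, reflecting
#'   tightly coupled whole-body coordination within a stride).
#' @param keypoint_cv_trial Relative sd of the independent per-keypoint
#'   per-trial jitter (fraction of the keypoint value; deliberately small
#'   next to `effort_sd`, see the methods vignette).
#' @param keypoint_cv_participant Relative sd of the constant
#'   per-participant per-keypoint offsets.
#' @param static_duration Still standing prefix used for calibration (s).
#' @param ramp_duration Smooth transition from standing to the stride (s).
#' @return Object of class `stride_params`.
#' @export
stride_params <- function(stride_duration = 1.2,
                          keypoints = default_keypoints(),
                          com_sway_ml = 0.04, com_sway_vertical = 0.02,
                          speed = 2, pelvis_height = 0.95,
                          calibre_deltas = c(dorsiflexion_range = 5,
                                             hip_adduction_at_push_off = -4,
                                             knee_flexion_at_push_off = 5),
                          effort_sd = 0.05,
                          keypoint_cv_trial = 0.001,
                          keypoint_cv_participant = 0.0005,
                          static_duration = 2, ramp_duration = 0.5) {
  stopifnot(stride_duration > 0, com_sway_ml >= 0, com_sway_vertical >= 0,
            static_duration > 0, ramp_duration > 0)
  .check_keypoints(keypoints)
  ok <- c("dorsiflexion_range", "hip_adduction_at_push_off",
          "knee_flexion_at_push_off")
  if (length(calibre_deltas) > 0 &&
      !all(names(calibre_deltas) %in% ok))
    stop("unsupported calibre_deltas name(s): ",
         paste(setdiff(names(calibre_deltas), ok), collapse = ", "),
         call. = FALSE)
  structure(list(stride_duration = stride_duration, keypoints = keypoints,
                 com_sway_ml = com_sway_ml,
                 com_sway_vertical = com_sway_vertical,
                 speed = speed, pelvis_height = pelvis_height,
                 calibre_deltas = calibre_deltas,
                 effort_sd = effort_sd,
                 keypoint_cv_trial = keypoint_cv_trial,
                 keypoint_cv_participant = keypoint_cv_participant,
                 static_duration = static_duration,
                 ramp_duration = ramp_duration),
            class = "stride_params")
}

#' @rdname stride_params
#' @export
default_keypoints <- function() {
  kp <- function(ic, mid, po, poe) c(ic = ic, mid = mid, po = po, poe = poe)
  list(
    hip = list(flexion = kp(45, 40, 20, 12),
               adduction = kp(5, 0, -10, -4),
               rotation = kp(3, 0, -5, 0)),
    knee = list(flexion = kp(-55, -45, -30, -20),
                adduction = kp(2, 0, -2, 0),
                rotation = kp(5, 0, -8, -2)),
    ankle = list(flexion = kp(5, 18, -10, 0),
                 adduction = kp(2, 0, -3, -1),
                 rotation = kp(0, 2, -4, 0)))
}

.check_keypoints <- function(kp) {
  lims <- c(flexion = 120, adduction = 45, rotation = 45)
  for (joint in c("hip", "knee", "ankle")) {
    for (axis in c("flexion", "adduction", "rotation")) {
      v <- kp[[joint]][[axis]]
      if (is.null(v) || length(v) != 4 || any(!is.finite(v)))
        stop("keypoints$", joint, "$", axis, " must be 4 finite angles",
             call. = FALSE)
      if (any(abs(v) > lims[axis]))
        stop("keypoint outside anatomical range: ", joint, " ", axis,
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' IMU and marker noise model
#'
#' White-noise, bias, marker-noise and mounting-misalignment magnitudes of
#' the virtual measurement chain. The defaults are the realistic set used by
#' the validation surrogate experiments; `noise_model(0, 0, 0, 0, 0, 0)`
#' gives noise-free recordings.
#'
#' @param gyro_white_sigma Gyroscope white noise sd, deg/s.
#' @param gyro_bias_range Half-width of the uniform per-trial constant
#'   gyroscope bias, deg/s (per axis, `U(-b, b)`).
#' @param accel_white_sigma Accelerometer white noise sd, m/s^2.
#' @param mag_white_sigma Magnetometer white noise sd, Gauss.
#' @param marker_noise_sigma Isotropic marker position noise sd, m.
#' @param misalignment_max Maximum random sensor-to-segment mounting rotation
#'   per participant, deg (recovered by the calibration stage).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(gyro_white_sigma = 0.3, gyro_bias_range = 0.5,
                        accel_white_sigma = 0.05, mag_white_sigma = 0.005,
                        marker_noise_sigma = 0.001, misalignment_max = 2) {
  v <- c(gyro_white_sigma, gyro_bias_range, accel_white_sigma,
         mag_white_sigma, marker_noise_sigma, misalignment_max)
  if (any(v < 0)) stop("noise magnitudes must be >= 0", call. = FALSE)
  structure(list(gyro_white_sigma = gyro_white_sigma,
                 gyro_bias_range = gyro_bias_range,
                 accel_white_sigma = accel_white_sigma,
                 mag_white_sigma = mag_white_sigma,
                 marker_noise_sigma = marker_noise_sigma,
                 misalignment_max = misalignment_max),
            class = "noise_model")
}

# periodic spline through the stride keypoints, evaluated at phases (any real;
# wrapped into [0, 1))
.stride_curve <- function(values4, phases) {
  x <- c(.KP_PHASES, 1)
  y <- c(values4, values4[1])
  stats::spline(x, y, method = "periodic", xout = phases %% 1)$y
}

#' Generate one stride's ground-truth kinematics and events
#'
#' Builds the trial timeline (still standing, smooth ramp, one complete
#' stride), the C2-smooth periodic joint angle trajectories through the
#' keypoints, the CoM/pelvis path, and — unless `kinematics_only` — the
#' forward-kinematics chain pelvis->thigh->shank->foot giving ground-truth
#' segment orientations and origins. Events sit at the keypoint phase times
#' of the stride.
#'
#' @param params A [stride_params] object (keypoints already jittered by the
#'   cohort generator, if any).
#' @param fs Sampling rate, Hz.
#' @param kinematics_only If `TRUE`, skip the forward-kinematics pose chain
#'   (fast path for feature-level simulation).
#' @return List with `t`, `events` ([stride_events]), `angles` (named list of
#'   [jcs_angles]-compatible `joint_angle_series`), `com`
#'   ([com_proxy]-compatible trajectory), and unless `kinematics_only`:
#'   `orientations` and `origins` per segment (pelvis, thigh, shank, foot).
#' @export
generate_stride <- function(params = stride_params(), fs = 100,
                            kinematics_only = FALSE) {
  stopifnot(inherits(params, "stride_params"))
  .check_keypoints(params$keypoints)
  dt <- 1 / fs
  t_ic <- params$static_duration + params$ramp_duration
  t_end <- t_ic + params$stride_duration
  t <- seq(0, t_end, by = dt)
  phase <- (t - t_ic) / params$stride_duration
  # blend factor: 0 while standing, smooth to 1 across the ramp
  blend <- smoothstep((t - params$static_duration) / params$ramp_duration)

  n <- length(t)
  angles <- list()
  for (joint in c("hip", "knee", "ankle")) {
    kpj <- params$keypoints[[joint]]
    angles[[joint]] <- structure(
      fast_df(list(t = t,
                   flexion = blend * .stride_curve(kpj$flexion, phase),
                   adduction = blend * .stride_curve(kpj$adduction, phase),
                   rotation = blend * .stride_curve(kpj$rotation, phase)), n),
      class = c("joint_angle_series", "data.frame"), joint = joint)
  }

  # CoM / pelvis origin path: forward progression with smooth speed ramp,
  # blended mediolateral (1 cycle/stride) and vertical (2 cycles/stride) sway
  vfwd <- params$speed * blend
  px <- cumtrapz_uniform(vfwd, dt)
  py <- blend * params$com_sway_ml * sin(2 * pi * phase)
  pz <- params$pelvis_height + blend * params$com_sway_vertical *
    sin(4 * pi * phase)
  com <- structure(fast_df(list(t = t, x = px, y = py, z = pz), n),
                   class = c("com_trajectory", "data.frame"))

  ev <- stride_events(t_ic, t_ic + .KP_PHASES[["po"]] * params$stride_duration,
                      t_ic + .KP_PHASES[["poe"]] * params$stride_duration)
  out <- list(t = t, events = ev, angles = angles, com = com, fs = fs,
              params = params)
  if (!kinematics_only) out <- c(out, .forward_kinematics(out))
  out
}

# segment dimensions (m) and joint-centre offsets of the virtual skater
.SKEL <- list(hip_offset = c(0, -0.10, 0.09),   # pelvis frame -> right hip centre
              thigh_length = 0.41,               # hip -> knee centre
              shank_length = 0.40,               # knee -> ankle centre
              ankle_in_foot = c(0.02, 0.07, 0))  # foot-frame position of ankle centre

.forward_kinematics <- function(kin) {
  n <- length(kin$t)
  com <- cbind(kin$com$x, kin$com$y, kin$com$z)
  segs <- c("pelvis", "thigh", "shank", "foot")
  q <- lapply(segs, function(s) matrix(NA_real_, n, 4))
  names(q) <- segs
  orig <- lapply(segs, function(s) matrix(NA_real_, n, 3))
  names(orig) <- segs
  Rp <- diag(3)                       # pelvis orientation: level, facing +x
  qp <- matrix_to_quat(Rp)
  for (i in seq_len(n)) {
    hip_c <- com[i, ] + Rp %*% .SKEL$hip_offset
    Rt <- Rp %*% jcs_rotation(kin$angles$hip$flexion[i],
                              kin$angles$hip$adduction[i],
                              kin$angles$hip$rotation[i])
    knee_c <- hip_c + Rt %*% c(0, -.SKEL$thigh_length, 0)
    Rs <- Rt %*% jcs_rotation(kin$angles$knee$flexion[i],
                              kin$angles$knee$adduction[i],
                              kin$angles$knee$rotation[i])
    ankle_c <- knee_c + Rs %*% c(0, -.SKEL$shank_length, 0)
    Rf <- Rs %*% jcs_rotation(kin$angles$ankle$flexion[i],
                              kin$angles$ankle$adduction[i],
                              kin$angles$ankle$rotation[i])
    foot_o <- ankle_c - Rf %*% .SKEL$ankle_in_foot
    q$pelvis[i, ] <- qp; q$thigh[i, ] <- matrix_to_quat(Rt)
    q$shank[i, ] <- matrix_to_quat(Rs); q$foot[i, ] <- matrix_to_quat(Rf)
    orig$pelvis[i, ] <- com[i, ]; orig$thigh[i, ] <- knee_c
    orig$shank[i, ] <- ankle_c; orig$foot[i, ] <- foot_o
  }
  list(orientations = lapply(q, function(m) orientation_series(kin$t, m)),
       origins = orig)
}

#' Landmark template of the virtual skater
#'
#' Anatomical landmark positions expressed in each segment's own frame
#' (x anterior, y up, z right), laid out so that the [segment_recipes]
#' applied to the template reproduce the segment frame exactly. Synthetic
#' stand-in for a real marker protocol.
#'
#' @return Named list `segment -> label -> numeric(3)` (metres).
#' @export
landmark_template <- function() {
  list(
    pelvis = list(RASIS = c(0.18, 0, 0.13), LASIS = c(0.18, 0, -0.13),
                  RPSIS = c(0, 0, 0.05), LPSIS = c(0, 0, -0.05)),
    thigh = list(HIP = c(0, 0.41, 0), KNEE_LAT = c(0, 0, 0.05),
                 KNEE_MED = c(0, 0, -0.05)),
    shank = list(KNEE_LAT = c(0, 0.40, 0.05), KNEE_MED = c(0, 0.40, -0.05),
                 ANK_LAT = c(0, 0, 0.04), ANK_MED = c(0, 0, -0.04)),
    foot = list(HEEL = c(-0.06, 0, 0), TOE = c(0.19, 0, 0),
                MT1 = c(0.10, 0, -0.04), MT5 = c(0.10, 0, 0.05)))
}

# sensor mount points in the segment frame and the plate marker layout
.SENSOR_MOUNTS <- list(pelvis = c(-0.12, 0.02, 0), thigh = c(0.05, 0.20, 0.05),
                       shank = c(0.03, 0.20, 0.03), foot = c(0.04, 0.05, 0.02))
.PLATE_PTS <- rbind(c(0, 0, 0), c(0.10, 0, 0), c(0, 0.07, 0))

#' Virtual marker trajectories for one trial
#'
#' Applies each segment's ground-truth pose to the landmark template (and to
#' the sensor plate marker layout) and adds isotropic Gaussian noise.
#' Anatomical labels follow [landmark_template]; shared labels (knee
#' epicondyles) are emitted once, from the thigh pose. Plate markers are
#' labelled `<SEGMENT>_P1..P3` (segment in upper case).
#'
#' @param kin A [generate_stride] result (with forward kinematics).
#' @param mounts Named list of 3x3 sensor-from-segment mounting rotations
#'   (default identity; the cohort generator passes the misaligned mounts).
#' @param noise_sigma Marker noise sd in metres.
#' @param seed Integer seed for the noise.
#' @param template Landmark template, default [landmark_template()].
#' @return A [marker_set].
#' @export
synthesize_markers <- function(kin, mounts = NULL, noise_sigma = 0, seed = 1,
                               template = landmark_template()) {
  stopifnot(!is.null(kin$orientations))
  n <- length(kin$t)
  segs <- names(template)
  if (is.null(mounts))
    mounts <- stats::setNames(lapply(segs, function(s) diag(3)), segs)
  out <- list()
  for (seg in segs) {
    qs <- kin$orientations[[seg]]$q
    o <- kin$origins[[seg]]
    for (lab in names(template[[seg]])) {
      if (!is.null(out[[lab]])) next   # shared labels emitted once
      p <- template[[seg]][[lab]]
      out[[lab]] <- t(vapply(seq_len(n), function(i)
        o[i, ] + quat_rotate(qs[i, ], p), numeric(3)))
    }
    # plate markers, rigid with the (misaligned) sensor frame
    A <- mounts[[seg]]
    for (j in 1:3) {
      lab <- sprintf("%s_P%d", toupper(seg), j)
      out[[lab]] <- t(vapply(seq_len(n), function(i)
        o[i, ] + quat_rotate(qs[i, ], .SENSOR_MOUNTS[[seg]] +
                                        A %*% .PLATE_PTS[j, ]), numeric(3)))
    }
  }
  if (noise_sigma > 0) {
    out <- with_seed(seed, lapply(out, function(m)
      m + matrix(stats::rnorm(length(m), sd = noise_sigma), nrow(m))))
  }
  marker_set(kin$t, out)
}

#' Virtual IMU readout of one segment's sensor
#'
#' Differentiates the ground-truth sensor pose into the ideal inertial and
#' magnetic signals, then applies the noise model:
#' \itemize{
#'   \item gyroscope: body-frame angular velocity from the quaternion
#'     increment per sample (forward difference, matching the integration
#'     scheme of [fuse_imu]) plus a constant per-trial bias and white noise;
#'   \item accelerometer: specific force (linear acceleration minus gravity,
#'     central second difference of the sensor position) rotated into the
#'     sensor frame, plus white noise;
#'   \item magnetometer: the lab reference field in the sensor frame plus
#'     white noise.
#' }
#' Signals are clipped at the hardware full-scale ranges (±2000 deg/s,
#' ±160 m/s^2, ±1.9 Gauss); clipping on more than 1% of samples raises a
#' warning.
#'
#' @param orient Ground-truth segment [orientation_series].
#' @param origin n x 3 matrix of segment origin positions (m, lab).
#' @param noise A [noise_model].
#' @param misalignment 3x3 sensor-from-segment mounting rotation.
#' @param seed Integer seed.
#' @param mount Sensor position in the segment frame (m).
#' @param ref_field Lab magnetic field (Gauss).
#' @param gravity Lab gravity vector (m/s^2), default `c(0, 0, -9.81)`.
#' @return An [imu_recording] in the sensor frame.
#' @export
synthesize_imu <- function(orient, origin, noise = noise_model(0, 0, 0, 0, 0, 0),
                           misalignment = diag(3), seed = 1,
                           mount = c(0, 0, 0),
                           ref_field = c(0.4, 0, -0.3),
                           gravity = c(0, 0, -9.81)) {
  stopifnot(inherits(orient, "orientation_series"),
            inherits(noise, "noise_model"))
  n <- length(orient$t)
  dt <- orient$t[2] - orient$t[1]
  qa <- matrix_to_quat(misalignment)
  qs <- t(apply(orient$q, 1, function(q) quat_multiply(q, qa)))
  pos <- t(vapply(seq_len(n), function(i)
    origin[i, ] + quat_rotate(orient$q[i, ], mount), numeric(3)))

  gyro <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    dq <- quat_multiply(quat_conjugate(qs[i, ]), qs[i + 1, ])
    gyro[i, ] <- quat_to_rotvec(dq) / dt
  }
  if (n > 1) gyro[n, ] <- gyro[n - 1, ]

  acc_lab <- (rbind(pos[1, ], pos[-n, ]) - 2 * pos +
                rbind(pos[-1, ], pos[n, ])) / dt^2
  acc_lab[c(1, n), ] <- 0             # endpoints: held still / replicated
  accel <- mag <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    Rt <- t(quat_to_matrix(qs[i, ]))
    accel[i, ] <- Rt %*% (acc_lab[i, ] - gravity)
    mag[i, ] <- Rt %*% ref_field
  }

  d2r <- pi / 180
  with_seed(seed, {
    bias <- stats::runif(3, -noise$gyro_bias_range, noise$gyro_bias_range) * d2r
    gyro <- gyro + matrix(bias, n, 3, byrow = TRUE) +
      matrix(stats::rnorm(3 * n, sd = noise$gyro_white_sigma * d2r), n)
    accel <- accel + matrix(stats::rnorm(3 * n, sd = noise$accel_white_sigma), n)
    mag <- mag + matrix(stats::rnorm(3 * n, sd = noise$mag_white_sigma), n)
  })

  clip <- function(x, lim, what) {
    over <- abs(x) > lim
    if (mean(over) > 0.01)
      warning(sprintf("synthesize_imu: %.1f%% of %s samples clipped at full scale",
                      100 * mean(over), what), call. = FALSE)
    pmin(pmax(x, -lim), lim)    # x first: pmin/pmax keep the first arg's dim
  }
  gyro <- clip(gyro, 2000 * d2r, "gyroscope")
  accel <- clip(accel, 160, "accelerometer")
  mag <- clip(mag, 1.9, "magnetometer")
  imu_recording(orient$t, gyro, accel, mag)
}

# random rotation with angle <= max_deg (uniform axis, uniform angle)
.random_small_rotation <- function(max_deg) {
  if (max_deg <= 0) return(diag(3))
  ax <- stats::rnorm(3)
  ang <- stats::runif(1, 0, max_deg) * pi / 180
  quat_to_matrix(quat_from_axis_angle(ax, ang))
}

# jittered copy of the stride parameters for one trial: every keypoint (and
# CoM amplitude) is scaled by (effort + participant offset + trial jitter),
# all three relative, so trial-to-trial variation is coherent across the body
.jitter_params <- function(params, part_offsets, effort, deltas) {
  cv <- params$keypoint_cv_trial
  kp <- params$keypoints
  for (joint in names(kp)) for (axis in names(kp[[joint]])) {
    base <- kp[[joint]][[axis]]
    kp[[joint]][[axis]] <- base * (effort + part_offsets[[joint]][[axis]] +
                                     stats::rnorm(4, sd = cv))
  }
  if (length(deltas) > 0) {
    if ("dorsiflexion_range" %in% names(deltas))
      kp$ankle$flexion["mid"] <- kp$ankle$flexion["mid"] +
        deltas[["dorsiflexion_range"]]
    if ("hip_adduction_at_push_off" %in% names(deltas))
      kp$hip$adduction["po"] <- kp$hip$adduction["po"] +
        deltas[["hip_adduction_at_push_off"]]
    if ("knee_flexion_at_push_off" %in% names(deltas))
      kp$knee$flexion["po"] <- kp$knee$flexion["po"] +
        deltas[["knee_flexion_at_push_off"]]
  }
  p <- params
  p$keypoints <- kp
  p$com_sway_ml <- params$com_sway_ml *
    (effort + part_offsets$com[1] + stats::rnorm(1, sd = cv))
  p$com_sway_vertical <- params$com_sway_vertical *
    (effort + part_offsets$com[2] + stats::rnorm(1, sd = cv))
  p
}

#' Generate a full synthetic skating cohort
#'
#' Simulates `n_high + n_low` participants with `trials` strides each.
#' Skating experience is drawn per group (high: 18 +- 4 y, low: 6 +- 6 y,
#' truncated at 0.5 y; redrawn until the 1-D k-means of [kmeans_calibre]
#' reproduces the intended split, so labels and experience are consistent).
#' Each participant gets constant keypoint offsets and a random
#' sensor-mounting misalignment per segment; each trial gets a shared
#' "effort" amplitude factor, independent keypoint jitter and — for the high
#' group — the calibre deltas. With `signals = TRUE` every trial also carries
#' virtual markers and the four IMU recordings.
#'
#' All randomness flows from `seed` through named sub-streams
#' ([substream_seed]); the same seed reproduces the cohort exactly.
#'
#' @param n_high,n_low Group sizes.
#' @param trials Trials per participant.
#' @param params A [stride_params] object.
#' @param noise A [noise_model].
#' @param seed Integer cohort seed.
#' @param fs Sampling rate, Hz.
#' @param signals If `TRUE`, synthesize markers and IMU streams per trial
#'   (required for the angle pipeline; feature-level studies can skip them).
#' @return Object of class `skating_cohort`: list with `features`
#'   (data frame: participant, calibre, trial, the 12 ground-truth features),
#'   `experience` (named vector), `calibre` (named factor), `trials` (nested
#'   list `participant -> trial` with kinematics, events, and if requested
#'   `markers` + `imu`), `mounts`, and the generation settings.
#' @export
generate_cohort <- function(n_high = 6, n_low = 6, trials = 5,
                            params = stride_params(), noise = noise_model(),
                            seed = 1, fs = 100, signals = FALSE) {
  stopifnot(inherits(params, "stride_params"), inherits(noise, "noise_model"))
  n <- n_high + n_low
  ids <- sprintf("P%02d", seq_len(n))
  calibre <- factor(rep(c("high", "low"), c(n_high, n_low)),
                    levels = c("low", "high"))
  names(calibre) <- ids

  experience <- with_seed(substream_seed(seed, "experience"), {
    for (attempt in 1:100) {
      e <- c(pmax(0.5, stats::rnorm(n_high, 18, 4)),
             pmax(0.5, stats::rnorm(n_low, 6, 6)))
      names(e) <- ids
      split <- try(kmeans_calibre(e), silent = TRUE)
      if (!inherits(split, "try-error") && all(split == calibre)) break
    }
    e
  })

  mounts <- with_seed(substream_seed(seed, "mounts"), {
    lapply(ids, function(id) {
      m <- lapply(names(.SENSOR_MOUNTS), function(s)
        .random_small_rotation(noise$misalignment_max))
      names(m) <- names(.SENSOR_MOUNTS)
      m
    })
  })
  names(mounts) <- ids

  part_offsets <- with_seed(substream_seed(seed, "participants"), {
    lapply(ids, function(id) {
      po <- lapply(params$keypoints, function(jj)
        lapply(jj, function(a)
          stats::rnorm(4, sd = params$keypoint_cv_participant)))
      po$com <- stats::rnorm(2, sd = params$keypoint_cv_participant)
      po
    })
  })
  names(part_offsets) <- ids

  fmat <- matrix(NA_real_, n * trials, 12,
                 dimnames = list(NULL, feature_names()))
  fpart <- character(n * trials); ftrial <- integer(n * trials)
  trial_data <- stats::setNames(vector("list", n), ids)
  row <- 0L
  for (pi in seq_len(n)) {
    id <- ids[pi]
    deltas <- if (calibre[pi] == "high") params$calibre_deltas else numeric(0)
    trial_data[[id]] <- vector("list", trials)
    for (tr in seq_len(trials)) {
      kseed <- substream_seed(seed, sprintf("kin_%s_%d", id, tr))
      ptrial <- with_seed(kseed, {
        effort <- 1 + stats::rnorm(1, sd = params$effort_sd)
        .jitter_params(params, part_offsets[[id]], effort, deltas)
      })
      kin <- generate_stride(ptrial, fs = fs, kinematics_only = !signals)
      if (signals) {
        nseed <- substream_seed(seed, sprintf("noise_%s_%d", id, tr))
        kin$markers <- synthesize_markers(kin, mounts[[id]],
                                          noise$marker_noise_sigma,
                                          seed = nseed)
        kin$imu <- stats::setNames(lapply(names(.SENSOR_MOUNTS), function(s)
          synthesize_imu(kin$orientations[[s]], kin$origins[[s]], noise,
                         misalignment = mounts[[id]][[s]],
                         seed = substream_seed(nseed, s),
                         mount = .SENSOR_MOUNTS[[s]])),
          names(.SENSOR_MOUNTS))
      }
      trial_data[[id]][[tr]] <- kin
      row <- row + 1L
      fmat[row, ] <- extract_features(kin$angles, kin$com, kin$events)
      fpart[row] <- id; ftrial[row] <- tr
    }
  }
  features <- data.frame(participant = fpart,
                         calibre = calibre[fpart],
                         trial = ftrial, fmat, row.names = NULL)
  structure(list(features = features, experience = experience,
                 calibre = calibre, trials = trial_data, mounts = mounts,
                 params = params, noise = noise, seed = seed, fs = fs,
                 signals = signals),
            class = "skating_cohort")
}

#' @export
print.skating_cohort <- function(x, ...) {
  cat(sprintf("<skating_cohort: %d participants x %d trials, signals: %s>\n",
              length(x$calibre), max(x$features$trial),
              if (isTRUE(x$signals)) "yes" else "no"))
  invisible(x)
}
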