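# The full angle pipeline: filter -> fusion -> calibration -> segment
# orientations -> JCS angles, for both the IMU chain and the marker-based
# reference chain, plus cohort-level validation, feature extraction and
# classification drivers.

.JOINTS <- list(hip = c("pelvis", "thigh"), knee = c("thigh", "shank"),
                ankle = c("shank", "foot"))

# restrict a joint_angle_series to a time window, preserving class/attributes
clip_angles <- function(series, window) {
  sel <- series$t >= window[1] - 1e-9 & series$t <= window[2] + 1e-9
  structure(data.frame(t = series$t[sel], flexion = series$flexion[sel],
                       adduction = series$adduction[sel],
                       rotation = series$rotation[sel]),
            class = c("joint_angle_series", "data.frame"),
            joint = attr(series, "joint"))
}

#' Joint angles of one trial from its IMU recordings
#'
#' Runs the wearable chain for one trial: each sensor's channels are low-pass
#' filtered (zero-phase Butterworth, `filter_order`/`filter_cutoff_hz`) and
#' fused into sensor orientations; the still calibration window at the start
#' of the trial gives, per segment, the sensor-to-plate rotation (fused
#' sensor vs plate-marker frame), the plate-to-body rotation (plate frame vs
#' anatomical frame), and hence the chained sensor-to-body alignment; the
#' aligned segment orientation streams are decomposed into hip, knee and
#' ankle JCS angles.
#'
#' @param imu Named list of [imu_recording]s (`pelvis`, `thigh`, `shank`,
#'   `foot`).
#' @param markers A [marker_set] with the plate and anatomical markers (used
#'   only inside the calibration window).
#' @param calib_window Numeric `c(t0, t1)`: the still window (s).
#' @param fusion A [fusion_params] object.
#' @param filter_order,filter_cutoff_hz Butterworth settings.
#' @param recipes Segment recipe table.
#' @return List with `angles` (named list of [jcs_angles] results),
#'   `segments` (orientation series per segment) and `calibration`
#'   (per-segment `r_sensor_to_plate`, `r_plate_to_body`, `r_sensor_to_body`).
#' @export
trial_angles_imu <- function(imu, markers, calib_window = c(0.2, 1.8),
                             fusion = fusion_params(), filter_order = 4,
                             filter_cutoff_hz = 15,
                             recipes = segment_recipes()) {
  segs <- c("pelvis", "thigh", "shank", "foot")
  stopifnot(all(segs %in% names(imu)), inherits(markers, "marker_set"))
  fs <- imu[[1]]$fs
  fused <- lapply(imu[segs], function(rec) {
    filt <- imu_recording(rec$t,
                          butterworth_lowpass(rec$gyro, filter_order,
                                              filter_cutoff_hz, fs),
                          butterworth_lowpass(rec$accel, filter_order,
                                              filter_cutoff_hz, fs),
                          butterworth_lowpass(rec$mag, filter_order,
                                              filter_cutoff_hz, fs))
    fuse_imu(filt, fusion)
  })
  csel <- markers$t >= calib_window[1] & markers$t <= calib_window[2]
  if (!any(csel)) stop("empty calibration window", call. = FALSE)
  cidx <- which(csel)
  calibration <- list()
  segments <- list()
  for (seg in segs) {
    plate_labels <- sprintf("%s_P%d", toupper(seg), 1:3)
    if (!all(plate_labels %in% names(markers$markers)))
      stop("missing plate markers for ", seg, call. = FALSE)
    r_plate <- quat_to_matrix(quat_mean(t(vapply(cidx, function(i) {
      matrix_to_quat(plate_frame_from_markers(
        t(vapply(plate_labels, function(l) markers$markers[[l]][i, ],
                 numeric(3)))))
    }, numeric(4)))))
    fsel <- fused[[seg]]$t >= calib_window[1] & fused[[seg]]$t <= calib_window[2]
    q_static <- quat_mean(fused[[seg]]$q[fsel, , drop = FALSE])
    r_seg_static <- quat_to_matrix(quat_mean(t(vapply(cidx, function(i) {
      matrix_to_quat(anatomical_frame(markers, seg, i, recipes)$r)
    }, numeric(4)))))
    r_s2p <- compute_sensor_to_plate(q_static, r_plate)
    r_p2b <- crossprod(r_plate, r_seg_static)   # t(r_plate) %*% r_seg_static
    r_s2b <- r_s2p %*% r_p2b
    calibration[[seg]] <- list(r_sensor_to_plate = r_s2p,
                               r_plate_to_body = r_p2b,
                               r_sensor_to_body = r_s2b)
    segments[[seg]] <- segment_orientation(fused[[seg]], r_s2b)
  }
  angles <- lapply(names(.JOINTS), function(j)
    jcs_angles(segments[[.JOINTS[[j]][1]]], segments[[.JOINTS[[j]][2]]], j))
  names(angles) <- names(.JOINTS)
  list(angles = angles, segments = segments, calibration = calibration)
}

#' Joint angles of one trial from the marker reference
#'
#' The gold-standard chain: per-sample anatomical frames from the landmark
#' markers, decomposed into the same JCS angles.
#'
#' @param markers A [marker_set].
#' @param recipes Segment recipe table.
#' @return List with `angles` and `segments` as in [trial_angles_imu].
#' @export
trial_angles_markers <- function(markers, recipes = segment_recipes()) {
  segs <- c("pelvis", "thigh", "shank", "foot")
  segments <- lapply(segs, function(s)
    reference_segment_orientation(markers, s, recipes))
  names(segments) <- segs
  angles <- lapply(names(.JOINTS), function(j)
    jcs_angles(segments[[.JOINTS[[j]][1]]], segments[[.JOINTS[[j]][2]]], j))
  names(angles) <- names(.JOINTS)
  list(angles = angles, segments = segments)
}

#' Validate the IMU chain against the marker chain over a cohort
#'
#' For every trial of a signals-bearing synthetic cohort (or any equivalent
#' list structure), computes both angle chains, the per-axis RMS error over
#' the stride window, and the three-step aggregation of [aggregate_rms].
#'
#' @param cohort A [generate_cohort] result with `signals = TRUE`.
#' @param fusion,filter_order,filter_cutoff_hz Pipeline settings.
#' @return An `rms_report` (see [aggregate_rms]).
#' @export
cohort_validation <- function(cohort, fusion = fusion_params(),
                              filter_order = 4, filter_cutoff_hz = 15) {
  stopifnot(inherits(cohort, "skating_cohort"))
  if (!isTRUE(cohort$signals))
    stop("cohort was generated without signals; rerun with signals = TRUE",
         call. = FALSE)
  calib <- c(0.2, cohort$params$static_duration - 0.2)
  rows <- list()
  for (id in names(cohort$trials)) {
    for (tr in seq_along(cohort$trials[[id]])) {
      trial <- cohort$trials[[id]][[tr]]
      win <- c(trial$events$t_initial_contact, trial$events$t_push_off_end)
      est <- trial_angles_imu(trial$imu, trial$markers, calib, fusion,
                              filter_order, filter_cutoff_hz)
      ref <- trial_angles_markers(trial$markers)
      for (j in names(.JOINTS)) {
        r <- rms_error(clip_angles(est$angles[[j]], win),
                       clip_angles(ref$angles[[j]], win))
        rows[[length(rows) + 1]] <-
          data.frame(participant = id, trial = tr, joint = j,
                     axis = names(r), rms = unname(r))
      }
    }
  }
  aggregate_rms(do.call(rbind, rows))
}

#' Feature table of a cohort through the measurement chain
#'
#' Extracts the twelve features per trial from the IMU-pipeline joint angles
#' (the validated wearable output) together with the marker-based CoM proxy
#' and the reference stride events, mirroring the feature table the
#' classification stage consumes. Body axes for the CoM projection come from
#' the marker-based pelvis frame averaged over the stride.
#'
#' @inheritParams cohort_validation
#' @return Data frame: `participant`, `calibre`, `trial`, twelve feature
#'   columns.
#' @export
cohort_features_imu <- function(cohort, fusion = fusion_params(),
                                filter_order = 4, filter_cutoff_hz = 15) {
  stopifnot(inherits(cohort, "skating_cohort"), isTRUE(cohort$signals))
  calib <- c(0.2, cohort$params$static_duration - 0.2)
  rows <- list()
  for (id in names(cohort$trials)) {
    for (tr in seq_along(cohort$trials[[id]])) {
      trial <- cohort$trials[[id]][[tr]]
      win <- c(trial$events$t_initial_contact, trial$events$t_push_off_end)
      est <- trial_angles_imu(trial$imu, trial$markers, calib, fusion,
                              filter_order, filter_cutoff_hz)
      pelvis_ref <- reference_segment_orientation(trial$markers, "pelvis")
      fv <- extract_features(est$angles, com_proxy(trial$markers),
                             trial$events,
                             body_axes_from_pelvis(pelvis_ref, win))
      rows[[length(rows) + 1]] <-
        data.frame(participant = id,
                   calibre = as.character(cohort$calibre[id]),
                   trial = tr, t(fv))
    }
  }
  out <- do.call(rbind, rows)
  out$calibre <- factor(out$calibre, levels = c("low", "high"))
  out
}

#' Run the complete analysis pipeline
#'
#' Convenience driver reproducing the study design on a feature table:
#' Friedman feature selection, subject-wise KNN cross-validation over
#' `ks`, and optionally the PCA feature-space variant.
#'
#' @param features Cohort feature table (columns `participant`, `calibre`,
#'   `trial`, feature columns), e.g. from [generate_cohort] (ground truth)
#'   or [cohort_features_imu] (measurement chain).
#' @param alpha Friedman selection level.
#' @param ks Neighbour counts.
#' @param pca `"off"` (selected features), `"all12"` (PCA on all twelve
#'   features) or `"selected3"` (PCA on the selected features).
#' @param n_components Components kept in the PCA variants.
#' @param seed Seed for the fold scheme.
#' @return List with `selection` ([select_features] result), `scheme`,
#'   `metrics` (per-k data frame) and, for PCA variants, `pca`.
#' @export
run_classification <- function(features, alpha = 0.05, ks = 1:15,
                               pca = c("off", "all12", "selected3"),
                               n_components = 3, seed = 1) {
  pca <- match.arg(pca)
  selection <- select_features(features, alpha = alpha)
  participants <- unique(features$participant)
  scheme <- build_fold_scheme(participants, seed = seed)
  pca_fit <- NULL
  if (pca == "off") {
    if (length(selection$selected) == 0)
      stop("no features selected at alpha = ", alpha, call. = FALSE)
    space <- selection$selected
  } else {
    feats <- if (pca == "all12") feature_names() else selection$selected
    if (length(feats) < n_components)
      stop("fewer selected features than components", call. = FALSE)
    pca_fit <- pca_embed(features, feats, n_components)
    space <- pca_fit$scores
  }
  metrics <- cross_validate(features, scheme, space, ks = ks)
  list(selection = selection, scheme = scheme, metrics = metrics,
       pca = pca_fit)
}
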