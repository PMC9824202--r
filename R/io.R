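# File formats: IMU CSV (t, gx..mz), marker CSV (t, <LABEL>_x/_y/_z),
# per-trial events CSV, features CSV, rotation-matrix calibration text, and
# the directory-based pipeline driver.

#' Read and write IMU recordings as CSV
#'
#' Dialect: columns `t, gx, gy, gz, ax, ay, az, mx, my, mz`; SI units
#' (seconds, rad/s, m/s^2, Gauss); one file per sensor per trial.
#'
#' @param rec An [imu_recording].
#' @param path File path.
#' @return `read_imu_csv` returns an [imu_recording].
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  d <- data.frame(t = rec$t, gx = rec$gyro[, 1], gy = rec$gyro[, 2],
                  gz = rec$gyro[, 3], ax = rec$accel[, 1],
                  ay = rec$accel[, 2], az = rec$accel[, 3],
                  mx = rec$mag[, 1], my = rec$mag[, 2], mz = rec$mag[, 3])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("t", "gx", "gy", "gz", "ax", "ay", "az", "mx", "my", "mz")
  if (!all(need %in% names(d)))
    stop("IMU CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  imu_recording(d$t, as.matrix(d[c("gx", "gy", "gz")]),
                as.matrix(d[c("ax", "ay", "az")]),
                as.matrix(d[c("mx", "my", "mz")]))
}

#' Read and write marker sets as CSV
#'
#' Dialect: column `t` plus `<LABEL>_x`, `<LABEL>_y`, `<LABEL>_z` triplets,
#' metres (millimetres are auto-detected on read, see [marker_set]).
#'
#' @param ms A [marker_set].
#' @param path File path.
#' @return `read_marker_csv` returns a [marker_set].
#' @export
write_marker_csv <- function(ms, path) {
  stopifnot(inherits(ms, "marker_set"))
  d <- data.frame(t = ms$t)
  for (lab in names(ms$markers)) {
    m <- ms$markers[[lab]]
    d[[paste0(lab, "_x")]] <- m[, 1]
    d[[paste0(lab, "_y")]] <- m[, 2]
    d[[paste0(lab, "_z")]] <- m[, 3]
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_csv
#' @export
read_marker_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!"t" %in% names(d)) stop("marker CSV needs a t column", call. = FALSE)
  xs <- grep("_x$", names(d), value = TRUE)
  labs <- sub("_x$", "", xs)
  markers <- lapply(labs, function(l)
    as.matrix(d[paste0(l, c("_x", "_y", "_z"))]))
  names(markers) <- labs
  marker_set(d$t, markers)
}

#' Read and write stride events
#'
#' One row per trial: `participant, trial, t_ic, t_po_start, t_po_end`
#' (seconds).
#'
#' @param events Data frame in that layout.
#' @param path File path.
#' @return `read_events_csv` returns the data frame.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("participant", "trial", "t_ic", "t_po_start", "t_po_end")
  if (!all(need %in% names(d)))
    stop("events CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  d
}

#' Serialize calibration rotations as text
#'
#' One line per named rotation: the name followed by the nine direction
#' cosines row-major.
#'
#' @param calib Named list of 3x3 rotation matrices (nesting allowed; names
#'   are joined with `.`).
#' @param path File path.
#' @return `read_calibration` returns a flat named list of matrices.
#' @export
write_calibration <- function(calib, path) {
  flat <- list()
  flatten <- function(x, prefix) {
    if (is.matrix(x)) flat[[prefix]] <<- x
    else for (nm in names(x)) flatten(x[[nm]], paste(c(prefix, nm), collapse = "."))
  }
  flatten(calib, character(0))
  lines <- vapply(names(flat), function(nm)
    paste(nm, paste(format(t(flat[[nm]]), digits = 17), collapse = " ")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    out[[parts[1]]] <- matrix(as.numeric(parts[-1]), 3, 3, byrow = TRUE)
  }
  out
}

#' Write a synthetic cohort to disk in the package CSV dialects
#'
#' Writes, under `dir`: `metadata.csv` (participant, calibre, experience),
#' `events.csv`, per-trial `markers_<participant>_<trial>.csv` and
#' `imu_<participant>_<trial>_<sensor>.csv`, and the ground-truth
#' `features_truth.csv`.
#'
#' @param cohort A [generate_cohort] result with `signals = TRUE`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "skating_cohort"), isTRUE(cohort$signals))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(participant = names(cohort$calibre),
                     calibre = as.character(cohort$calibre),
                     experience = unname(cohort$experience))
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  ev <- list()
  for (id in names(cohort$trials)) {
    for (tr in seq_along(cohort$trials[[id]])) {
      trial <- cohort$trials[[id]][[tr]]
      ev[[length(ev) + 1]] <- data.frame(
        participant = id, trial = tr,
        t_ic = trial$events$t_initial_contact,
        t_po_start = trial$events$t_push_off_start,
        t_po_end = trial$events$t_push_off_end)
      write_marker_csv(trial$markers,
                       file.path(dir, sprintf("markers_%s_%d.csv", id, tr)))
      for (s in names(trial$imu))
        write_imu_csv(trial$imu[[s]],
                      file.path(dir, sprintf("imu_%s_%d_%s.csv", id, tr, s)))
    }
  }
  write_events_csv(do.call(rbind, ev), file.path(dir, "events.csv"))
  utils::write.csv(cohort$features, file.path(dir, "features_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Run the full pipeline on a data directory
#'
#' End-to-end driver over the on-disk layout of [write_cohort] (or any real
#' recordings exported in the same dialects): for every trial listed in
#' `events.csv`, runs the IMU angle chain and the marker reference chain,
#' accumulates the RMS validation report, extracts the feature table through
#' the measurement chain, then performs Friedman selection and the
#' subject-wise KNN cross-validation. All stage outputs are written under
#' `out_dir`: `rms_report.json`, `rms_per_trial.csv`, `features.csv`,
#' `metrics.csv` (columns `k, sensitivity, specificity, accuracy, precision`)
#' and per-trial calibration files.
#'
#' @param data_dir Input directory.
#' @param out_dir Output directory (created; default `file.path(data_dir,
#'   "out")`).
#' @param calib_window Still-window `c(t0, t1)` used for calibration (s).
#' @param fusion A [fusion_params] object.
#' @param filter_order,filter_cutoff_hz Butterworth settings.
#' @param alpha,ks,pca,seed Classification settings (see
#'   [run_classification]).
#' @return List with `report` (`rms_report`), `features`, `classification`.
#' @export
run_pipeline <- function(data_dir, out_dir = file.path(data_dir, "out"),
                         calib_window = c(0.2, 1.8),
                         fusion = fusion_params(), filter_order = 4,
                         filter_cutoff_hz = 15, alpha = 0.05, ks = 1:15,
                         pca = "off", seed = 1) {
  meta_path <- file.path(data_dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("missing metadata.csv", call. = FALSE)
  meta <- utils::read.csv(meta_path)
  events <- read_events_csv(file.path(data_dir, "events.csv"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sensors <- c("pelvis", "thigh", "shank", "foot")
  rows <- list(); frows <- list()
  for (r in seq_len(nrow(events))) {
    id <- events$participant[r]; tr <- events$trial[r]
    mpath <- file.path(data_dir, sprintf("markers_%s_%d.csv", id, tr))
    if (!file.exists(mpath))
      stop("pipeline stage 'angles': missing marker file for trial ",
           id, "/", tr, call. = FALSE)
    markers <- read_marker_csv(mpath)
    imu <- lapply(sensors, function(s) {
      p <- file.path(data_dir, sprintf("imu_%s_%d_%s.csv", id, tr, s))
      if (!file.exists(p))
        stop("pipeline stage 'angles': missing IMU file for trial ",
             id, "/", tr, " sensor ", s, call. = FALSE)
      read_imu_csv(p)
    })
    names(imu) <- sensors
    est <- trial_angles_imu(imu, markers, calib_window, fusion,
                            filter_order, filter_cutoff_hz)
    ref <- trial_angles_markers(markers)
    write_calibration(lapply(est$calibration, `[`,
                             c("r_sensor_to_plate", "r_sensor_to_body")),
                      file.path(out_dir, sprintf("calib_%s_%d.txt", id, tr)))
    win <- c(events$t_ic[r], events$t_po_end[r])
    ev <- stride_events(events$t_ic[r], events$t_po_start[r],
                        events$t_po_end[r])
    for (j in names(.JOINTS)) {
      rr <- rms_error(clip_angles(est$angles[[j]], win),
                      clip_angles(ref$angles[[j]], win))
      rows[[length(rows) + 1]] <- data.frame(
        participant = id, trial = tr, joint = j, axis = names(rr),
        rms = unname(rr))
    }
    pelvis_ref <- reference_segment_orientation(markers, "pelvis")
    fv <- extract_features(est$angles, com_proxy(markers), ev,
                           body_axes_from_pelvis(pelvis_ref, win))
    frows[[length(frows) + 1]] <- data.frame(
      participant = id,
      calibre = meta$calibre[match(id, meta$participant)],
      trial = tr, t(fv))
  }
  report <- aggregate_rms(do.call(rbind, rows))
  features <- do.call(rbind, frows)
  features$calibre <- factor(features$calibre, levels = c("low", "high"))
  write_rms_report(report, file.path(out_dir, "rms_report.json"),
                   file.path(out_dir, "rms_per_trial.csv"))
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  classification <- run_classification(features, alpha = alpha, ks = ks,
                                       pca = pca, seed = seed)
  utils::write.csv(
    classification$metrics[c("k", "sensitivity", "specificity", "accuracy",
                             "precision")],
    file.path(out_dir, "metrics.csv"), row.names = FALSE)
  list(report = report, features = features, classification = classification)
}
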