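# Extraction of the twelve calibre-distinctive kinematic features from joint
# angle series, the CoM proxy trajectory, and stride events.

#' Canonical feature names
#'
#' The twelve calibre-distinctive features, in their canonical order:
#' ankle dorsiflexion range; ankle adduction at the end of push-off; hip
#' flexion at initial contact; hip adduction at push-off; hip adduction at
#' initial contact; dorsiflexion at push-off; knee flexion at push-off; hip
#' flexion average over the stride; IQR and range of CoM motion along the
#' body mediolateral axis; IQR and range of CoM motion in the body sagittal
#' plane (vertical excursion component).
#'
#' @return Character vector of length 12.
#' @export
feature_names <- function() {
  c("dorsiflexion_range", "ankle_adduction_at_push_off_end",
    "hip_flexion_at_initial_contact", "hip_adduction_at_push_off",
    "hip_adduction_at_initial_contact", "dorsiflexion_at_push_off",
    "knee_flexion_at_push_off", "hip_flexion_average",
    "com_ml_iqr", "com_ml_range", "com_sagittal_iqr", "com_sagittal_range")
}

#' Stride temporal events
#'
#' Event timestamps of one skating stride, taken as inputs (reference-system
#' detections): blade initial contact, start of the push-off, end of the
#' push-off. The stride analysis window used for ranges, IQRs and averages is
#' `[t_initial_contact, t_push_off_end]`.
#'
#' @param t_initial_contact,t_push_off_start,t_push_off_end Seconds.
#' @return Object of class `stride_events`.
#' @export
stride_events <- function(t_initial_contact, t_push_off_start, t_push_off_end) {
  if (!(t_initial_contact < t_push_off_end) ||
      !(t_initial_contact <= t_push_off_start) ||
      !(t_push_off_start <= t_push_off_end))
    stop("events must be ordered: initial contact <= push-off start <= push-off end",
         call. = FALSE)
  structure(list(t_initial_contact = t_initial_contact,
                 t_push_off_start = t_push_off_start,
                 t_push_off_end = t_push_off_end),
            class = "stride_events")
}

# index of the sample nearest to t_event; ties resolved to the earlier sample
.nearest_index <- function(t, t_event) {
  if (t_event < t[1] - 1e-9 || t_event > t[length(t)] + 1e-9)
    stop("event time outside the series range", call. = FALSE)
  d <- abs(t - t_event)
  which(d <= min(d) + 1e-12)[1]
}

#' Angle value at a stride event
#'
#' Reads one axis of a joint angle series at the sample nearest to the event
#' time (ties go to the earlier sample of the 100 Hz grid).
#'
#' @param series A [jcs_angles] result.
#' @param axis One of `"flexion"`, `"adduction"`, `"rotation"`.
#' @param t_event Event time in seconds, inside the series range.
#' @return Angle in degrees.
#' @export
value_at_event <- function(series, axis = c("flexion", "adduction", "rotation"),
                           t_event) {
  axis <- match.arg(axis)
  stopifnot(inherits(series, "joint_angle_series"))
  series[[axis]][.nearest_index(series$t, t_event)]
}

#' Angle excursion over a window
#'
#' `max - min` of one axis over the stride window.
#'
#' @inheritParams value_at_event
#' @param window Numeric `c(t_start, t_end)` in seconds.
#' @return Range in degrees (non-negative).
#' @export
axis_range <- function(series, axis = c("flexion", "adduction", "rotation"),
                       window) {
  axis <- match.arg(axis)
  stopifnot(inherits(series, "joint_angle_series"), length(window) == 2)
  sel <- series$t >= window[1] - 1e-9 & series$t <= window[2] + 1e-9
  if (!any(sel)) stop("empty window", call. = FALSE)
  x <- series[[axis]][sel]
  max(x) - min(x)
}

#' Body axes for CoM projection
#'
#' Mediolateral and vertical body axes taken from the pelvis anatomical frame
#' averaged over the stride window (mean orientation of the window's
#' quaternions). Columns: x = anterior, y = vertical, z = mediolateral.
#'
#' @param pelvis An [orientation_series] for the pelvis segment.
#' @param window Numeric `c(t_start, t_end)` in seconds.
#' @return 3x3 rotation matrix.
#' @export
body_axes_from_pelvis <- function(pelvis, window) {
  stopifnot(inherits(pelvis, "orientation_series"))
  sel <- pelvis$t >= window[1] - 1e-9 & pelvis$t <= window[2] + 1e-9
  if (!any(sel)) stop("empty window", call. = FALSE)
  quat_to_matrix(quat_mean(pelvis$q[sel, , drop = FALSE]))
}

#' CoM dispersion in a body plane
#'
#' Interquartile range (linear-interpolation quartiles) and range of the CoM
#' coordinate projected on the body mediolateral axis, or of its vertical
#' excursion within the sagittal plane, over the stride window. The
#' anteroposterior progression component is dominated by the skating
#' displacement itself, so the sagittal-plane measure defaults to the
#' vertical component; set `sagittal_component = "anteroposterior"` for the
#' alternative reading.
#'
#' @param com A [com_proxy] trajectory.
#' @param plane `"mediolateral"` or `"sagittal"`.
#' @param window Numeric `c(t_start, t_end)` in seconds.
#' @param body_axes 3x3 matrix of body axes (columns x anterior, y vertical,
#'   z mediolateral), e.g. from [body_axes_from_pelvis]. Default: lab axes
#'   reordered to that convention.
#' @param sagittal_component Which sagittal-plane component to measure.
#' @return List with `iqr` and `range`, metres.
#' @export
com_dispersion <- function(com, plane = c("mediolateral", "sagittal"), window,
                           body_axes = NULL,
                           sagittal_component = c("vertical", "anteroposterior")) {
  plane <- match.arg(plane)
  sagittal_component <- match.arg(sagittal_component)
  stopifnot(inherits(com, "com_trajectory"), length(window) == 2)
  if (is.null(body_axes))
    body_axes <- cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0)) # lab: x fwd, z up
  sel <- com$t >= window[1] - 1e-9 & com$t <= window[2] + 1e-9
  if (!any(sel)) stop("empty window", call. = FALSE)
  p <- cbind(com$x, com$y, com$z)[sel, , drop = FALSE]
  axis <- if (plane == "mediolateral") body_axes[, 3]
          else if (sagittal_component == "vertical") body_axes[, 2]
          else body_axes[, 1]
  x <- as.numeric(p %*% axis)
  list(iqr = .q7(x, 0.75) - .q7(x, 0.25), range = max(x) - min(x))
}

#' Extract the twelve-feature vector of one trial
#'
#' Populates all twelve calibre-distinctive features (see [feature_names])
#' from the three joint angle series, the CoM proxy and the stride events.
#' Instant features are read with [value_at_event]; ranges, IQRs and the hip
#' flexion average are computed over the stride window
#' `[t_initial_contact, t_push_off_end]`. "Push-off instant" features use
#' `t_push_off_start`; "end of push-off" uses `t_push_off_end`.
#'
#' @param angles Named list with [jcs_angles] elements `hip`, `knee`,
#'   `ankle`, on a common clock.
#' @param com A [com_proxy] trajectory on the same clock.
#' @param events A [stride_events] object.
#' @param body_axes Optional 3x3 body-axis matrix for the CoM projections
#'   (see [com_dispersion]).
#' @param sagittal_component Passed to [com_dispersion].
#' @return Named numeric vector of length 12.
#' @export
extract_features <- function(angles, com, events, body_axes = NULL,
                             sagittal_component = c("vertical", "anteroposterior")) {
  sagittal_component <- match.arg(sagittal_component)
  stopifnot(all(c("hip", "knee", "ankle") %in% names(angles)),
            inherits(events, "stride_events"))
  win <- c(events$t_initial_contact, events$t_push_off_end)
  hip <- angles$hip; knee <- angles$knee; ankle <- angles$ankle
  sel <- hip$t >= win[1] - 1e-9 & hip$t <= win[2] + 1e-9
  ml <- com_dispersion(com, "mediolateral", win, body_axes)
  sg <- com_dispersion(com, "sagittal", win, body_axes, sagittal_component)
  out <- c(
    dorsiflexion_range = axis_range(ankle, "flexion", win),
    ankle_adduction_at_push_off_end =
      value_at_event(ankle, "adduction", events$t_push_off_end),
    hip_flexion_at_initial_contact =
      value_at_event(hip, "flexion", events$t_initial_contact),
    hip_adduction_at_push_off =
      value_at_event(hip, "adduction", events$t_push_off_start),
    hip_adduction_at_initial_contact =
      value_at_event(hip, "adduction", events$t_initial_contact),
    dorsiflexion_at_push_off =
      value_at_event(ankle, "flexion", events$t_push_off_start),
    knee_flexion_at_push_off =
      value_at_event(knee, "flexion", events$t_push_off_start),
    hip_flexion_average = mean(hip$flexion[sel]),
    com_ml_iqr = ml$iqr, com_ml_range = ml$range,
    com_sagittal_iqr = sg$iqr, com_sagittal_range = sg$range)
  out[feature_names()]
}
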