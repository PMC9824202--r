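# Three-step RMS validation of IMU-derived joint angles against the
# marker-based reference: per-trial RMS, per-participant averaging across
# trials, cohort-level boxplot statistics.

#' Per-axis RMS error between two joint angle series
#'
#' Root-mean-square of the sample-wise difference for each JCS axis, over the
#' full (common) clock of the two series.
#'
#' @param a,b [jcs_angles] results on a common clock.
#' @return Named numeric vector `c(flexion=, adduction=, rotation=)`, degrees.
#' @export
rms_error <- function(a, b) {
  stopifnot(inherits(a, "joint_angle_series"), inherits(b, "joint_angle_series"))
  if (nrow(a) != nrow(b) || max(abs(a$t - b$t)) > 1e-9)
    stop("alignment error: series differ in length or clock", call. = FALSE)
  vapply(c("flexion", "adduction", "rotation"),
         function(ax) sqrt(mean((a[[ax]] - b[[ax]])^2)), numeric(1))
}

# linear-interpolation quartiles (stats::quantile type 7), the documented rule
.q7 <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

.boxplot_stats <- function(x) {
  q1 <- .q7(x, 0.25); q3 <- .q7(x, 0.75)
  iqr <- q3 - q1
  lo <- if (any(x >= q1 - 1.5 * iqr)) min(x[x >= q1 - 1.5 * iqr]) else min(x)
  hi <- if (any(x <= q3 + 1.5 * iqr)) max(x[x <= q3 + 1.5 * iqr]) else max(x)
  c(median = .q7(x, 0.5), q1 = q1, q3 = q3,
    whisker_low = lo, whisker_high = hi, max = max(x))
}

#' Aggregate per-trial RMS errors into a validation report
#'
#' Implements the enumerated aggregation: (1) per-trial RMS values are taken
#' as given; (2) the RMS of each participant is the arithmetic mean over that
#' participant's trials; (3) the participant means are summarized per
#' joint/axis as boxplot statistics (median, linear-interpolation quartiles,
#' 1.5 IQR whiskers, max). Participants with no trials are excluded with a
#' warning.
#'
#' @param per_trial Data frame with columns `participant`, `trial`, `joint`,
#'   `axis`, `rms` (degrees), e.g. from [cohort_validation].
#' @return Object of class `rms_report`: list with elements `per_trial`,
#'   `per_participant` (participant x joint/axis means) and `cohort` (one row
#'   per joint/axis of boxplot statistics plus the participant-mean maximum).
#' @export
aggregate_rms <- function(per_trial) {
  need <- c("participant", "trial", "joint", "axis", "rms")
  stopifnot(all(need %in% names(per_trial)))
  if (any(is.na(per_trial$rms)) || any(per_trial$rms < 0))
    stop("per-trial RMS values must be finite and non-negative", call. = FALSE)
  per_participant <- stats::aggregate(
    rms ~ participant + joint + axis, data = per_trial, FUN = mean)
  names(per_participant)[names(per_participant) == "rms"] <- "mean_rms"
  cells <- split(per_participant,
                 interaction(per_participant$joint, per_participant$axis,
                             drop = TRUE))
  cohort <- do.call(rbind, lapply(cells, function(d) {
    data.frame(joint = d$joint[1], axis = d$axis[1],
               as.list(.boxplot_stats(d$mean_rms)))
  }))
  rownames(cohort) <- NULL
  structure(list(per_trial = per_trial, per_participant = per_participant,
                 cohort = cohort),
            class = "rms_report")
}

#' @export
print.rms_report <- function(x, ...) {
  cat(sprintf("<rms_report: %d trials, %d participants>\n",
              nrow(unique(x$per_trial[c("participant", "trial")])),
              length(unique(x$per_participant$participant))))
  cat(sprintf("max participant-averaged RMS: %.2f deg\n",
              max(x$per_participant$mean_rms)))
  print(x$cohort, digits = 3)
  invisible(x)
}

#' Maximum participant-averaged RMS error
#'
#' The headline validation number: the largest entry of the
#' participant-averaged RMS table across joints and axes.
#'
#' @param report An [aggregate_rms] report.
#' @return Numeric scalar, degrees.
#' @export
max_participant_rms <- function(report) {
  stopifnot(inherits(report, "rms_report"))
  max(report$per_participant$mean_rms)
}

#' Serialize / plot a validation report
#'
#' `write_rms_report` writes the report as JSON plus a tidy CSV of per-trial
#' values; `plot.rms_report` draws the per-joint-axis boxplots of
#' participant-averaged RMS errors.
#'
#' @param report An [aggregate_rms] report.
#' @param path_json,path_csv Output paths.
#' @export
write_rms_report <- function(report, path_json, path_csv) {
  stopifnot(inherits(report, "rms_report"))
  jsonlite::write_json(list(per_participant = report$per_participant,
                            cohort = report$cohort),
                       path_json, digits = NA, auto_unbox = TRUE)
  utils::write.csv(report$per_trial, path_csv, row.names = FALSE)
  invisible(report)
}

#' @param x An `rms_report`.
#' @param ... Passed to [graphics::boxplot].
#' @rdname write_rms_report
#' @export
plot.rms_report <- function(x, ...) {
  d <- x$per_participant
  cell <- interaction(d$joint, d$axis, sep = " ")
  graphics::boxplot(d$mean_rms ~ cell, las = 2,
                    ylab = "participant-averaged RMS error (deg)",
                    xlab = "", ...)
  invisible(x)
}
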