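# Marker-based kinematics: labelled marker trajectories, anatomical segment
# frames built from landmark recipes (Cappozzo-style conventions), the
# marker-based reference orientation stream, and the PSIS-midpoint CoM proxy.

#' Labelled 3D marker trajectories
#'
#' Container for motion-capture marker data on a common clock. Coordinates are
#' metres internally; if the median absolute coordinate exceeds 10 the input is
#' taken to be millimetres and converted (with a message), matching common
#' motion-capture exports.
#'
#' @param t Timestamps in seconds.
#' @param markers Named list of n x 3 numeric matrices, one per marker label.
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(t, markers) {
  stopifnot(is.list(markers), !is.null(names(markers)), length(markers) > 0)
  n <- length(t)
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    stopifnot(nrow(m) == n, ncol(m) == 3)
    m
  })
  med <- stats::median(abs(unlist(markers)), na.rm = TRUE)
  if (is.finite(med) && med > 10) {
    message("marker_set: coordinates look like millimetres (median |x| > 10); converting to metres")
    markers <- lapply(markers, function(m) m / 1000)
  }
  structure(list(t = as.numeric(t), markers = markers), class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set: %d labels x %d samples>\n",
              length(x$markers), length(x$t)))
  invisible(x)
}

#' Segment landmark recipes (convention table)
#'
#' The anatomical frame of each segment is built from two landmark-derived
#' direction vectors: a primary axis taken as-is and a secondary axis
#' orthogonalized against it, the third axis completing a right-handed frame
#' (x anterior, y proximal/up, z to the right for the right leg). Each vector
#' runs from the midpoint of the `from` labels to the midpoint of the `to`
#' labels; the origin is the midpoint of the `origin` labels. The table is
#' also shipped as `inst/extdata/segment_recipes.json` so alternative landmark
#' sets can be declared without code changes and loaded with
#' [read_segment_recipes].
#'
#' @return Named list of recipes (segments `pelvis`, `thigh`, `shank`,
#'   `foot`).
#' @export
segment_recipes <- function() {
  list(
    pelvis = list(
      required  = c("RASIS", "LASIS", "RPSIS", "LPSIS"),
      origin    = c("RASIS", "LASIS"),
      primary   = list(axis = "z", from = "LASIS", to = "RASIS"),
      secondary = list(axis = "x", from = c("RPSIS", "LPSIS"),
                       to = c("RASIS", "LASIS"))),
    thigh = list(
      required  = c("HIP", "KNEE_LAT", "KNEE_MED"),
      origin    = c("KNEE_LAT", "KNEE_MED"),
      primary   = list(axis = "y", from = c("KNEE_LAT", "KNEE_MED"), to = "HIP"),
      secondary = list(axis = "z", from = "KNEE_MED", to = "KNEE_LAT")),
    shank = list(
      required  = c("KNEE_LAT", "KNEE_MED", "ANK_LAT", "ANK_MED"),
      origin    = c("ANK_LAT", "ANK_MED"),
      primary   = list(axis = "y", from = c("ANK_LAT", "ANK_MED"),
                       to = c("KNEE_LAT", "KNEE_MED")),
      secondary = list(axis = "z", from = "ANK_MED", to = "ANK_LAT")),
    foot = list(
      required  = c("HEEL", "TOE", "MT1", "MT5"),
      origin    = "HEEL",
      primary   = list(axis = "x", from = "HEEL", to = "TOE"),
      secondary = list(axis = "z", from = "MT1", to = "MT5"))
  )
}

#' Read a segment recipe table from JSON
#'
#' @param path Path to a JSON file with the structure of [segment_recipes].
#' @return Named list of recipes.
#' @export
read_segment_recipes <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(r) {
    list(required = as.character(r$required),
         origin = as.character(r$origin),
         primary = list(axis = r$primary$axis,
                        from = as.character(r$primary$from),
                        to = as.character(r$primary$to)),
         secondary = list(axis = r$secondary$axis,
                          from = as.character(r$secondary$from),
                          to = as.character(r$secondary$to)))
  })
}

# midpoint of one or more labels at one sample
.mid <- function(ms, labels, i) {
  p <- vapply(labels, function(l) ms$markers[[l]][i, ], numeric(3))
  rowMeans(matrix(p, nrow = 3))
}

# cyclic completion: x = y x z, y = z x x, z = x x y
.complete_axes <- function(axes) {
  have <- names(axes)
  missing <- setdiff(c("x", "y", "z"), have)
  axes[[missing]] <- switch(missing,
    x = cross3(axes$y, axes$z),
    y = cross3(axes$z, axes$x),
    z = cross3(axes$x, axes$y))
  cbind(axes$x, axes$y, axes$z)
}

#' Anatomical segment frame from landmarks
#'
#' Applies the segment's landmark recipe (see [segment_recipes]) at one
#' sample: primary axis normalized as-is, secondary axis orthogonalized
#' against it, third axis by right-handed completion.
#'
#' @param markers A [marker_set].
#' @param segment One of `"pelvis"`, `"thigh"`, `"shank"`, `"foot"` (or any
#'   segment named in `recipes`).
#' @param sample_index Sample (row) index at which to evaluate.
#' @param recipes Recipe table, default [segment_recipes()].
#' @return List with `origin` (metres, lab) and `r` (3x3 lab-to-segment
#'   rotation, columns = segment axes in lab), class `segment_frame`.
#' @export
anatomical_frame <- function(markers, segment, sample_index = 1L,
                             recipes = segment_recipes()) {
  stopifnot(inherits(markers, "marker_set"))
  rec <- recipes[[segment]]
  if (is.null(rec)) stop("unknown segment: ", segment, call. = FALSE)
  missing <- setdiff(rec$required, names(markers$markers))
  if (length(missing) > 0)
    stop("missing landmark(s) for ", segment, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  i <- sample_index
  vals <- unlist(lapply(rec$required, function(l) markers$markers[[l]][i, ]))
  if (any(!is.finite(vals)))
    stop("missing landmark data (NaN) for ", segment, " at sample ", i,
         call. = FALSE)
  e1 <- .mid(markers, rec$primary$to, i) - .mid(markers, rec$primary$from, i)
  n1 <- sqrt(sum(e1^2))
  e2 <- .mid(markers, rec$secondary$to, i) - .mid(markers, rec$secondary$from, i)
  if (n1 < 1e-9 || sqrt(sum(e2^2)) < 1e-9)
    stop("degenerate geometry: coincident landmarks for ", segment, call. = FALSE)
  e1 <- e1 / n1
  e2 <- e2 - sum(e2 * e1) * e1
  n2 <- sqrt(sum(e2^2))
  if (n2 < 1e-9)
    stop("degenerate geometry: collinear landmarks for ", segment, call. = FALSE)
  e2 <- e2 / n2
  axes <- stats::setNames(list(e1, e2), c(rec$primary$axis, rec$secondary$axis))
  R <- .complete_axes(axes)
  dimnames(R) <- NULL
  structure(list(origin = .mid(markers, rec$origin, i), r = R),
            class = "segment_frame")
}

#' Marker-based reference segment orientation stream
#'
#' Evaluates [anatomical_frame] at every sample; this is the gold-standard
#' orientation stream the IMU chain is validated against.
#'
#' @inheritParams anatomical_frame
#' @return An [orientation_series].
#' @export
reference_segment_orientation <- function(markers, segment,
                                          recipes = segment_recipes()) {
  stopifnot(inherits(markers, "marker_set"))
  rec <- recipes[[segment]]
  if (is.null(rec)) stop("unknown segment: ", segment, call. = FALSE)
  bad <- which(vapply(seq_along(markers$t), function(i) {
    any(!is.finite(unlist(lapply(rec$required,
                                 function(l) markers$markers[[l]][i, ]))))
  }, logical(1)))
  if (length(bad) > 0)
    stop("marker gap(s) for ", segment, " at sample(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  q <- t(vapply(seq_along(markers$t), function(i) {
    matrix_to_quat(anatomical_frame(markers, segment, i, recipes)$r)
  }, numeric(4)))
  orientation_series(markers$t, q)
}

#' Centre-of-mass proxy from the PSIS markers
#'
#' The body CoM stand-in used by the dispersion features: the per-sample
#' midpoint of the left and right posterior superior iliac spine markers.
#'
#' @param markers A [marker_set] containing `LPSIS` and `RPSIS`.
#' @return Object of class `com_trajectory`: data frame with columns `t`,
#'   `x`, `y`, `z` (metres, lab frame).
#' @export
com_proxy <- function(markers) {
  stopifnot(inherits(markers, "marker_set"))
  missing <- setdiff(c("LPSIS", "RPSIS"), names(markers$markers))
  if (length(missing) > 0)
    stop("missing landmark(s): ", paste(missing, collapse = ", "), call. = FALSE)
  p <- (markers$markers$LPSIS + markers$markers$RPSIS) / 2
  structure(data.frame(t = markers$t, x = p[, 1], y = p[, 2], z = p[, 3]),
            class = c("com_trajectory", "data.frame"))
}
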