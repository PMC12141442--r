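#' Pose track container
#'
#' A pose track holds the per-frame coordinates of the 8 skeletal key-points
#' of one larva in one recording epoch, together with a per-frame validity
#' mask, the acquisition frame rate and the spatial calibration. Coordinates
#' use the raster convention: origin at the top-left of the image, x
#' rightward, y downward; "up" in the well image is the negative y
#' direction. Frames masked invalid are excluded, never interpolated.
#'
#' @param coords Numeric array `T x 8 x 2` of key-point coordinates
#'   (`[, , 1]` = x, `[, , 2]` = y).
#' @param fps Acquisition frame rate in frames/s (default 160).
#' @param unit Unit of `coords`: `"mm"` or `"px"`.
#' @param mm_per_px Spatial scale, mm per pixel. Default 0.0249 (a 6.38 mm
#'   well diameter spanning 256 px; diameter from the 0.32 cm^2 circular
#'   well area).
#' @param valid Logical vector of length `T`; `FALSE` marks frames removed
#'   by cleaning or missing at acquisition. Defaults to frames whose
#'   coordinates are all finite.
#' @param well_id,epoch_label Identifiers; `epoch_label` one of
#'   `"baseline"`, `"TP1"`, `"TP2"`, `"other"`.
#' @param well_center Length-2 numeric, centre of the circular well in the
#'   same unit as `coords` (or `NULL` if unknown).
#' @param well_radius Well radius in the same unit (or `NULL`).
#' @param skeleton A [skeleton_spec()].
#' @return An object of class `pose_track`.
#' @export
pose_track <- function(coords, fps = 160, unit = c("mm", "px"),
                       mm_per_px = 0.0249, valid = NULL,
                       well_id = "well", epoch_label = "other",
                       well_center = NULL, well_radius = NULL,
                       skeleton = skeleton_spec()) {
  unit <- match.arg(unit)
  if (length(dim(coords)) != 3L || dim(coords)[2] != 8L || dim(coords)[3] != 2L)
    stop("coords must be a T x 8 x 2 array")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be > 0")
  if (!is.numeric(mm_per_px) || mm_per_px <= 0) stop("mm_per_px must be > 0")
  if (!is.null(well_radius) && well_radius <= 0) stop("well_radius must be > 0")
  n <- dim(coords)[1]
  if (is.null(valid)) {
    valid <- apply(is.finite(coords), 1L, all)
  }
  stopifnot(length(valid) == n, is.logical(valid))
  valid <- valid & apply(is.finite(coords), 1L, all)
  epoch_label <- match.arg(epoch_label, c("baseline", "TP1", "TP2", "other"))
  structure(list(coords = coords, fps = fps, unit = unit,
                 mm_per_px = mm_per_px, valid = valid,
                 well_id = well_id, epoch_label = epoch_label,
                 well_center = well_center, well_radius = well_radius,
                 skeleton = skeleton),
            class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("pose_track '%s' (%s): %d frames @ %g fps, unit %s\n",
              x$well_id, x$epoch_label, n_frames(x), x$fps, x$unit))
  cat(sprintf("  valid frames: %d/%d\n", sum(x$valid), n_frames(x)))
  if (!is.null(x$well_radius))
    cat(sprintf("  well: center (%g, %g), radius %g %s\n",
                x$well_center[1], x$well_center[2], x$well_radius, x$unit))
  invisible(x)
}

#' Number of frames in a pose track
#' @param track A `pose_track`.
#' @return Integer frame count.
#' @export
n_frames <- function(track) dim(track$coords)[1]

#' Convert a pose track between pixel and millimetre units
#'
#' Conversion is exactly multiplicative by `mm_per_px` (coordinates and well
#' geometry alike) and therefore invertible to floating tolerance.
#'
#' @param track A `pose_track`.
#' @param unit Target unit, `"mm"` or `"px"`.
#' @return The converted `pose_track` (unchanged if already in `unit`).
#' @export
convert_unit <- function(track, unit = c("mm", "px")) {
  unit <- match.arg(unit)
  if (track$unit == unit) return(track)
  f <- if (unit == "mm") track$mm_per_px else 1 / track$mm_per_px
  track$coords <- track$coords * f
  if (!is.null(track$well_center)) track$well_center <- track$well_center * f
  if (!is.null(track$well_radius)) track$well_radius <- track$well_radius * f
  track$unit <- unit
  track
}

#' @export
`[.pose_track` <- function(x, i) {
  x$coords <- x$coords[i, , , drop = FALSE]
  x$valid <- x$valid[i]
  x
}
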