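deg <- function(rad) rad * 180 / pi

# wrap a degree angle to (-180, 180]
wrap_angle <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

# heading angle in degrees, counterclockwise-positive in a y-up frame.
# Raster coordinates are y-down, so y is sign-flipped here (once).
heading_angle_deg <- function(vx, vy) deg(atan2(-vy, vx))

#' Tail angle of one pose
#'
#' Unsigned angle between the tail vector (center to caudal fin) and the
#' caudal extension of the body axis (snout to center): 0 degrees for a
#' straight, fully extended larva; 180 degrees when the tail tip touches
#' the snout.
#'
#' @param snout,center,caudal_fin Length-2 coordinates.
#' @return Angle in degrees in `[0, 180]`, or `NA` if either vector has
#'   zero length.
#' @export
tail_angle <- function(snout, center, caudal_fin) {
  u <- center - snout       # caudal extension of the body axis
  v <- caudal_fin - center  # tail vector
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  deg(acos(max(-1, min(1, sum(u * v) / (nu * nv)))))
}

#' Per-frame speed, maximum speed and total distance of a cleaned track
#'
#' Speed at a valid frame is the COM displacement from the previous valid
#' frame divided by the elapsed time across the actual frame gap; it is
#' undefined (`NA`) on the first valid frame of the track. Total distance
#' sums displacements between consecutive valid frames and is reported in
#' metres.
#'
#' @param track A cleaned [pose_track()] in mm with at least 2 valid frames.
#' @return List with `speed` (mm/s, length `T`), `max_speed` (mm/s),
#'   `total_distance_m` (m) and `dist_cum` (cumulative distance, m).
#' @export
speed_series <- function(track) {
  track <- convert_unit(track, "mm")
  if (sum(track$valid) < 2L) stop("speed needs at least 2 valid frames")
  com <- track_com(track)
  n <- n_frames(track)
  speed <- rep(NA_real_, n)
  dist_cum <- rep(NA_real_, n)
  v <- which(track$valid)
  steps <- sqrt(rowSums((com[v[-1], , drop = FALSE] -
                         com[v[-length(v)], , drop = FALSE])^2))
  gaps <- diff(v) / track$fps
  speed[v[-1]] <- steps / gaps
  dist_cum[v] <- c(0, cumsum(steps)) / 1000  # mm -> m
  list(speed = speed, max_speed = max(speed, na.rm = TRUE),
       total_distance_m = sum(steps) / 1000, dist_cum = dist_cum)
}

#' Per-frame heading-angle change
#'
#' The heading vector points from the center key-point to the snout (the
#' direction the animal faces). The change at a valid frame is the signed
#' smallest rotation from the previous valid frame's heading, wrapped to
#' `(-180, 180]`, counterclockwise-positive in a y-up frame (raster y-down
#' input is sign-flipped once internally).
#'
#' @param track A cleaned [pose_track()].
#' @return Numeric vector of length `T` (degrees; `NA` on invalid frames,
#'   the first valid frame, and frames with a degenerate heading vector).
#' @export
heading_change <- function(track) {
  si <- kp_index(track$skeleton, "snout")
  ci <- kp_index(track$skeleton, "center")
  n <- n_frames(track)
  hx <- track$coords[, si, 1L] - track$coords[, ci, 1L]
  hy <- track$coords[, si, 2L] - track$coords[, ci, 2L]
  ok <- track$valid & (hx != 0 | hy != 0)
  ang <- rep(NA_real_, n)
  ang[ok] <- heading_angle_deg(hx[ok], hy[ok])
  out <- rep(NA_real_, n)
  v <- which(ok)
  if (length(v) >= 2L)
    out[v[-1]] <- wrap_angle(ang[v[-1]] - ang[v[-length(v)]])
  out
}

#' Per-frame inter-eye distance
#'
#' Euclidean distance between the two eye key-points; approximately 0.2 mm
#' for an upright larva and near 0 when only one eye is visible, making it
#' a proxy for posture loss.
#'
#' @param track A [pose_track()] in mm.
#' @return Numeric vector of length `T` (mm; `NA` on invalid frames).
#' @export
inter_eye_distance <- function(track) {
  track <- convert_unit(track, "mm")
  li <- kp_index(track$skeleton, "eye_left")
  ri <- kp_index(track$skeleton, "eye_right")
  d <- sqrt((track$coords[, li, 1L] - track$coords[, ri, 1L])^2 +
            (track$coords[, li, 2L] - track$coords[, ri, 2L])^2)
  d[!track$valid] <- NA_real_
  d
}

#' Full per-frame kinematic series of a cleaned track
#'
#' Computes, on one shared frame index: COM, speed (mm/s), cumulative
#' distance (m), tail angle (deg), signed and absolute heading change
#' (deg), and inter-eye distance (mm), plus epoch summaries.
#'
#' @param track A cleaned [pose_track()] in mm.
#' @return Object of class `kinematic_series`: a list with `frames` (a
#'   data frame, one row per frame) and `summary` (max speed, total
#'   distance in m, mean inter-eye distance, tail-angle and heading-change
#'   quantiles over valid frames).
#' @export
kinematic_series <- function(track) {
  track <- convert_unit(track, "mm")
  sp <- speed_series(track)
  com <- track_com(track)
  n <- n_frames(track)
  si <- kp_index(track$skeleton, "snout")
  ci <- kp_index(track$skeleton, "center")
  fi <- kp_index(track$skeleton, "caudal_fin")
  th <- rep(NA_real_, n)
  for (i in which(track$valid))
    th[i] <- tail_angle(track$coords[i, si, ], track$coords[i, ci, ],
                        track$coords[i, fi, ])
  hc <- heading_change(track)
  d <- inter_eye_distance(track)
  frames <- data.frame(frame = seq_len(n) - 1L,
                       valid = track$valid,
                       com_x = com[, 1L], com_y = com[, 2L],
                       speed = sp$speed, dist_cum = sp$dist_cum,
                       tail_angle = th, heading_change = hc,
                       heading_change_abs = abs(hc),
                       inter_eye = d)
  qs <- function(x) stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95),
                                    na.rm = TRUE, names = TRUE)
  summary <- list(max_speed = sp$max_speed,
                  total_distance_m = sp$total_distance_m,
                  mean_inter_eye = mean(d, na.rm = TRUE),
                  tail_angle_q = qs(th),
                  heading_change_abs_q = qs(abs(hc)))
  structure(list(frames = frames, summary = summary,
                 well_id = track$well_id, epoch_label = track$epoch_label,
                 fps = track$fps),
            class = "kinematic_series")
}

#' @export
print.kinematic_series <- function(x, ...) {
  s <- x$summary
  cat(sprintf("kinematic_series '%s' (%s): %d frames @ %g fps\n",
              x$well_id, x$epoch_label, nrow(x$frames), x$fps))
  cat(sprintf("  max speed %.1f mm/s | distance %.3f m | mean inter-eye %.3f mm\n",
              s$max_speed, s$total_distance_m, s$mean_inter_eye))
  cat(sprintf("  median tail angle %.1f deg | median |heading change| %.2f deg/frame\n",
              s$tail_angle_q[["50%"]], s$heading_change_abs_q[["50%"]]))
  invisible(x)
}

#' Write a kinematic series as CSV
#' @param kin A [kinematic_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinematics <- function(kin, path) {
  utils::write.csv(
    kin$frames[, c("frame", "com_x", "com_y", "speed", "dist_cum",
                   "tail_angle", "heading_change", "inter_eye")],
    path, row.names = FALSE)
  invisible(path)
}
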