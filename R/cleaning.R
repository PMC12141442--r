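#' Track-cleaning configuration
#'
#' Parameters of the cleaning cascade applied to raw pose tracks before any
#' kinematic analysis: a biologically implausible-speed gate, a
#' well-boundary gate on the center key-point, a centre-of-mass distance
#' gate on every key-point, and per-feature wavelet denoising.
#'
#' @param speed_max Speed gate in mm/s (default 120, the empirical upper
#'   bound of real larval swim speeds in a well).
#' @param com_factor Key-points further than `com_factor` x body length from
#'   the frame COM invalidate the frame (default 0.7).
#' @param wavelet_name Orthonormal wavelet used for denoising
#'   (default `"sym4"`).
#' @param sigma_per_feature Numeric vector of 16 noise scales (one per x/y
#'   of each key-point) or `"estimate"` to estimate each from the track.
#' @param body_length_mm Larval length in mm, or `"estimate"` (median over
#'   valid frames of the midline polyline length snout to caudal fin).
#' @return Object of class `cleaning_config`.
#' @export
cleaning_config <- function(speed_max = 120, com_factor = 0.7,
                            wavelet_name = "sym4",
                            sigma_per_feature = "estimate",
                            body_length_mm = "estimate") {
  stopifnot(speed_max > 0, com_factor > 0)
  wavelet_filters(wavelet_name)  # validates the name
  if (is.numeric(sigma_per_feature) && length(sigma_per_feature) != 16L)
    stop("sigma_per_feature must be length 16 (x and y of each key-point)")
  structure(list(speed_max = speed_max, com_factor = com_factor,
                 wavelet_name = wavelet_name,
                 sigma_per_feature = sigma_per_feature,
                 body_length_mm = body_length_mm),
            class = "cleaning_config")
}

#' Centre of mass of one pose frame
#'
#' Arithmetic mean of the 6 midline key-points; the two eye points are
#' excluded because they bias the COM toward the head.
#'
#' @param frame_coords `8 x 2` matrix of key-point coordinates.
#' @param skeleton A [skeleton_spec()].
#' @return Length-2 numeric (x, y).
#' @export
compute_com <- function(frame_coords, skeleton = skeleton_spec()) {
  if (!all(is.finite(frame_coords))) stop("invalid frame: non-finite coordinates")
  colMeans(frame_coords[skeleton$midline, , drop = FALSE])
}

# COM for every frame of a track: T x 2 matrix (NA rows where invalid)
track_com <- function(track) {
  n <- n_frames(track)
  com <- matrix(NA_real_, n, 2L)
  mid <- track$skeleton$midline
  com[track$valid, 1L] <- rowMeans(track$coords[track$valid, mid, 1L, drop = FALSE])
  com[track$valid, 2L] <- rowMeans(track$coords[track$valid, mid, 2L, drop = FALSE])
  com
}

#' Estimate larval body length from a track
#'
#' Median over valid frames of the polyline length along the midline
#' key-points from snout to caudal fin.
#'
#' @param track A [pose_track()] in mm.
#' @return Body length in mm.
#' @export
estimate_body_length <- function(track) {
  mid <- track$skeleton$midline
  v <- which(track$valid)
  if (!length(v)) stop("no valid frames to estimate body length from")
  seg <- function(i) {
    p <- track$coords[i, mid, , drop = TRUE]
    sum(sqrt(rowSums(diff(p)^2)))
  }
  stats::median(vapply(v, seg, numeric(1)))
}

#' Implausible-speed gate
#'
#' Invalidates frames whose COM displacement from the previous valid frame,
#' divided by the elapsed time across the actual frame gap, exceeds
#' `speed_max`. The gap-aware denominator means an already-removed frame
#' cannot fabricate an apparent speed. The first valid frame is never
#' removed by this rule. After a removal the reference frame stays the last
#' retained frame.
#'
#' @param track A [pose_track()] in mm.
#' @param cfg A [cleaning_config()].
#' @return List with the updated `track` and `removed` (frame indices,
#'   1-based, invalidated by this gate).
#' @export
speed_gate <- function(track, cfg = cleaning_config()) {
  stopifnot(track$unit == "mm")
  com <- track_com(track)
  valid <- track$valid
  removed <- integer(0)
  prev <- NA_integer_
  for (i in seq_len(n_frames(track))) {
    if (!valid[i]) next
    if (!is.na(prev)) {
      dt <- (i - prev) / track$fps
      sp <- sqrt(sum((com[i, ] - com[prev, ])^2)) / dt
      if (sp > cfg$speed_max) {
        valid[i] <- FALSE
        removed <- c(removed, i)
        next  # reference stays at prev
      }
    }
    prev <- i
  }
  track$valid <- valid
  list(track = track, removed = removed)
}

#' Well-boundary gate
#'
#' Invalidates frames where the center key-point lies strictly outside the
#' circular well (closed-disk convention: a point exactly on the boundary
#' is retained).
#'
#' @param track A [pose_track()] with `well_center` and `well_radius` set.
#' @param cfg A [cleaning_config()] (unused fields tolerated; present for a
#'   uniform gate signature).
#' @return List with updated `track` and `removed` indices.
#' @export
well_gate <- function(track, cfg = cleaning_config()) {
  if (is.null(track$well_center) || is.null(track$well_radius))
    stop("well gate requires well_center and well_radius on the track")
  ci <- kp_index(track$skeleton, "center")
  d <- sqrt((track$coords[, ci, 1L] - track$well_center[1])^2 +
            (track$coords[, ci, 2L] - track$well_center[2])^2)
  bad <- which(track$valid & d > track$well_radius)
  track$valid[bad] <- FALSE
  list(track = track, removed = bad)
}

#' COM-distance gate
#'
#' Invalidates frames where any key-point sits more than
#' `com_factor` x body length away from that frame's centre of mass.
#'
#' @param track A [pose_track()] in mm.
#' @param cfg A [cleaning_config()].
#' @return List with updated `track`, `removed` indices, and the
#'   `body_length` used (mm).
#' @export
com_gate <- function(track, cfg = cleaning_config()) {
  if (!any(track$valid))
    return(list(track = track, removed = integer(0),
                body_length = NA_real_))
  bl <- cfg$body_length_mm
  if (identical(bl, "estimate")) bl <- estimate_body_length(track)
  com <- track_com(track)
  lim <- cfg$com_factor * bl
  n <- n_frames(track)
  bad <- integer(0)
  for (i in which(track$valid)) {
    d <- sqrt((track$coords[i, , 1L] - com[i, 1L])^2 +
              (track$coords[i, , 2L] - com[i, 2L])^2)
    if (any(d > lim)) bad <- c(bad, i)
  }
  track$valid[bad] <- FALSE
  list(track = track, removed = bad, body_length = bl)
}

# contiguous runs of valid frames as (start, end) pairs
valid_runs <- function(valid) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Clean a pose track
#'
#' Runs the full cleaning cascade in order: speed gate, well-boundary gate,
#' COM-distance gate, then per-feature wavelet denoising of each contiguous
#' surviving segment (no bridging across removed frames). A frame failing
#' several rules is attributed to the first gate that fires. Gates only
#' ever set valid frames invalid; cleaning never resurrects frames.
#'
#' @param track A [pose_track()]; converted to mm if in px.
#' @param cfg A [cleaning_config()].
#' @return List with `track` (cleaned) and `report`, a `cleaning_report`
#'   holding per-rule removal counts, retained count, the body length and
#'   per-feature sigma used, and a `usable` flag (FALSE when no frames
#'   survive).
#' @export
clean_track <- function(track, cfg = cleaning_config()) {
  track <- convert_unit(track, "mm")
  n <- n_frames(track)
  pre_invalid <- sum(!track$valid)
  g1 <- speed_gate(track, cfg)
  g2 <- if (!is.null(track$well_center) && !is.null(track$well_radius))
    well_gate(g1$track, cfg) else list(track = g1$track, removed = integer(0))
  g3 <- com_gate(g2$track, cfg)
  track <- g3$track
  # per-feature sigma (16 features: x and y of each key-point)
  sig <- cfg$sigma_per_feature
  if (identical(sig, "estimate")) {
    sig <- numeric(16L)
    v <- track$valid
    if (sum(v) >= 8L) {
      f <- 0L
      for (k in 1:8) for (c in 1:2) {
        f <- f + 1L
        sig[f] <- estimate_sigma(track$coords[v, k, c], cfg$wavelet_name)
      }
    }
  }
  # denoise each contiguous valid segment, per feature
  runs <- valid_runs(track$valid)
  min_len <- 2L * length(wavelet_filters(cfg$wavelet_name)$lo)
  if (nrow(runs)) for (r in seq_len(nrow(runs))) {
    s <- runs[r, 1L]; e <- runs[r, 2L]
    if (e - s + 1L < min_len) next  # too short to denoise; left unchanged
    f <- 0L
    for (k in 1:8) for (c in 1:2) {
      f <- f + 1L
      track$coords[s:e, k, c] <-
        wavelet_denoise(track$coords[s:e, k, c], sigma = sig[f],
                        wavelet = cfg$wavelet_name)
    }
  }
  # consistency pass: denoising can perturb coordinates near segment
  # boundaries, so the gates are re-checked on the final coordinates; any
  # extra removal keeps its rule attribution. Gates still only ever set
  # valid frames invalid.
  p1 <- speed_gate(track, cfg)
  p2 <- if (!is.null(track$well_center) && !is.null(track$well_radius))
    well_gate(p1$track, cfg) else list(track = p1$track, removed = integer(0))
  p3 <- com_gate(p2$track, cfg)
  track <- p3$track
  g1$removed <- c(g1$removed, p1$removed)
  g2$removed <- c(g2$removed, p2$removed)
  g3$removed <- c(g3$removed, p3$removed)
  retained <- sum(track$valid)
  report <- structure(list(
    n_frames = n,
    pre_invalid = pre_invalid,
    removed_speed = length(g1$removed),
    removed_well = length(g2$removed),
    removed_com = length(g3$removed),
    removed_speed_frames = g1$removed,
    removed_well_frames = g2$removed,
    removed_com_frames = g3$removed,
    retained = retained,
    body_length = g3$body_length,
    sigma_per_feature = sig,
    usable = retained > 0L), class = "cleaning_report")
  list(track = track, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("cleaning_report: %d frames; removed %d (speed) + %d (well) + %d (COM); retained %d\n",
              x$n_frames, x$removed_speed, x$removed_well, x$removed_com,
              x$retained))
  cat(sprintf("  body length %.3f mm; usable: %s\n", x$body_length, x$usable))
  invisible(x)
}

#' Average per-feature sigma over an acquisition batch
#'
#' Estimates the 16 per-feature noise scales for each track of a well-plate
#' acquisition and averages them feature-wise, for use as a shared
#' `sigma_per_feature` in [cleaning_config()].
#'
#' @param tracks List of [pose_track()] objects from one acquisition.
#' @param wavelet Filter name.
#' @return Numeric vector of 16 averaged sigmas.
#' @export
estimate_sigma_batch <- function(tracks, wavelet = "sym4") {
  mats <- lapply(tracks, function(tr) {
    v <- tr$valid
    if (sum(v) < 8L) return(NULL)
    s <- numeric(16L); f <- 0L
    for (k in 1:8) for (c in 1:2) {
      f <- f + 1L
      s[f] <- estimate_sigma(tr$coords[v, k, c], wavelet)
    }
    s
  })
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (!length(mats)) stop("no track long enough for sigma estimation")
  colMeans(do.call(rbind, mats))
}
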