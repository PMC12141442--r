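#' Windowing parameters
#'
#' @param window_len Window length in frames (default 60; 0.375 s at
#'   160 fps).
#' @param stride Start-to-start spacing of overlapping windows in frames
#'   (default 15).
#' @param drop_incomplete Drop windows containing any invalid frame
#'   (default TRUE); removed frames are never interpolated.
#' @return Object of class `windowing_params`.
#' @export
windowing_params <- function(window_len = 60L, stride = 15L,
                             drop_incomplete = TRUE) {
  window_len <- as.integer(window_len); stride <- as.integer(stride)
  stopifnot(window_len >= 2L, stride >= 1L, stride <= window_len)
  structure(list(window_len = window_len, stride = stride,
                 drop_incomplete = drop_incomplete),
            class = "windowing_params")
}

#' Cut a track into overlapping pose windows
#'
#' Windows start at frames `0, stride, 2*stride, ...` (0-based); the last
#' start is the largest with a complete window inside the track. Windows
#' containing any invalid frame are dropped when `drop_incomplete`.
#'
#' @param track A cleaned [pose_track()].
#' @param params A [windowing_params()].
#' @return List of raw (unaligned) windows, each a list with `start_frame`
#'   (0-based), `coords` (`window_len x 8 x 2`) and `track_id`. Empty when
#'   the track is shorter than `window_len`.
#' @export
make_windows <- function(track, params = windowing_params()) {
  n <- n_frames(track)
  w <- params$window_len
  if (n < w) return(list())
  starts <- seq(0L, n - w, by = params$stride)
  out <- vector("list", length(starts))
  keep <- logical(length(starts))
  for (j in seq_along(starts)) {
    s <- starts[j]
    idx <- (s + 1L):(s + w)
    if (params$drop_incomplete && !all(track$valid[idx])) next
    out[[j]] <- list(start_frame = s,
                     coords = track$coords[idx, , , drop = FALSE],
                     track_id = track$well_id)
    keep[j] <- TRUE
  }
  out[keep]
}

#' Egocentrically align a pose window
#'
#' A single rigid transform is computed from the window's first frame: a
#' rotation about the first frame's center key-point mapping its heading
#' vector (center to snout) onto the canonical up axis (negative y in the
#' raster convention, i.e. head up on screen), followed by a translation
#' taking that center to the origin. The same transform is applied to all
#' frames of the window, so pairwise key-point distances (and all
#' within-window motion) are preserved; later frames are not
#' re-canonicalized.
#'
#' @param window A raw window from [make_windows()], or a bare
#'   `w x 8 x 2` array.
#' @param skeleton A [skeleton_spec()].
#' @return The window with `coords` aligned (and `aligned = TRUE`); for a
#'   bare array input, the aligned array.
#' @export
egocentric_align <- function(window, skeleton = skeleton_spec()) {
  bare <- is.array(window)
  coords <- if (bare) window else window$coords
  si <- kp_index(skeleton, "snout")
  ci <- kp_index(skeleton, "center")
  pivot <- coords[1L, ci, ]
  h <- coords[1L, si, ] - pivot
  if (sum(h^2) == 0)
    stop("degenerate heading in first frame; window rejected")
  # rotation taking h to (0, -|h|): canonical head-up in raster coordinates
  phi <- atan2(-1, 0) - atan2(h[2], h[1])
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L, 2L)
  w <- dim(coords)[1]
  flat <- matrix(coords, w * 8L, 2L)  # (frame, kp) pairs stacked
  flat <- sweep(flat, 2L, pivot) %*% t(R)
  aligned <- array(flat, dim(coords))
  if (bare) return(aligned)
  window$coords <- aligned
  window$aligned <- TRUE
  window
}

#' Flatten an aligned window to a feature vector
#'
#' Frame-major, then key-point, then (x, y): a 60-frame window becomes a
#' vector of length `60 * 8 * 2 = 960`, element `((f*8) + k)*2 + c`
#' (0-based) holding frame `f`, key-point `k`, coordinate `c`.
#'
#' @param window An aligned window (list or bare `w x 8 x 2` array).
#' @return Numeric vector of length `w * 16`.
#' @export
flatten_features <- function(window) {
  coords <- if (is.array(window)) window else window$coords
  d <- dim(coords)
  if (length(d) != 3L || d[2] != 8L || d[3] != 2L)
    stop("window must be w x 8 x 2")
  # aperm to (coord, kp, frame) then flatten reversed gives frame-major order
  as.vector(aperm(coords, c(3L, 2L, 1L)))
}

#' Inverse of [flatten_features()]
#' @param v Feature vector of length `w * 16`.
#' @return `w x 8 x 2` array.
#' @export
unflatten_features <- function(v) {
  if (length(v) %% 16L != 0L) stop("feature length must be a multiple of 16")
  w <- length(v) %/% 16L
  aperm(array(v, c(2L, 8L, w)), c(3L, 2L, 1L))
}
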