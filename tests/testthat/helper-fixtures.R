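# Fixture builders shared across test files. Poses here are constructed
# independently of the simulator so they can serve as oracles for it.

# a straight 8-key-point pose: snout at `head`, body along -heading,
# length 4 mm, eyes +-0.1 mm lateral at 0.3 mm behind the snout.
# Returns an 8 x 2 matrix in skeleton order.
straight_pose <- function(head = c(3, 3), heading_deg = 0, length_mm = 4,
                          eye_half = 0.1) {
  a <- heading_deg * pi / 180
  u <- c(cos(a), sin(a))
  b <- -u
  nrm <- c(-u[2], u[1])
  seg <- length_mm / 5
  snout <- head
  pts <- rbind(
    snout,
    snout + 0.3 * b + eye_half * nrm,
    snout + 0.3 * b - eye_half * nrm,
    snout + 1 * seg * b,
    snout + 2 * seg * b,
    snout + 3 * seg * b,
    snout + 4 * seg * b,
    snout + 5 * seg * b)
  unname(pts)
}

# track of n frames whose pose is `pose` shifted by per-frame offsets
# (n x 2 matrix or NULL for stationary), with optional iid jitter
make_track <- function(pose, n = 10, offsets = NULL, noise_sd = 0,
                       fps = 160, well_center = c(3.2, 3.2),
                       well_radius = 3.19, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  coords <- array(NA_real_, c(n, 8, 2))
  for (i in seq_len(n)) {
    off <- if (is.null(offsets)) c(0, 0) else offsets[i, ]
    coords[i, , ] <- sweep(pose, 2, -off)
  }
  if (noise_sd > 0) coords <- coords + rnorm(length(coords), 0, noise_sd)
  pose_track(coords, fps = fps, unit = "mm", well_center = well_center,
             well_radius = well_radius, ...)
}

# a small deterministic frame stack
toy_stack <- function(frames) frame_stack(frames, well_id = "toy", fps = 160)

# literal per-pixel activity oracle (independent of the vectorized path)
activity_loop_oracle <- function(prev, curr, t_rel = 0.1, d_abs = 20) {
  count <- 0L
  for (r in seq_len(nrow(prev))) for (c in seq_len(ncol(prev))) {
    d <- abs(curr[r, c] - prev[r, c])
    s <- curr[r, c] + prev[r, c]
    if (s > 0 && 2 * d / s > t_rel && d > d_abs) count <- count + 1L
  }
  count
}

# random non-negative integer stack
random_stack <- function(n_frames = 10, side = 8, maxval = 255) {
  toy_stack(lapply(seq_len(n_frames), function(i)
    matrix(sample.int(maxval + 1L, side * side, replace = TRUE) - 1L,
           side, side)))
}

# 500-frame track with planted cleaning violations:
# speed at frames 101 and 301, well-boundary at 201, COM-distance at 401
# (1-based frame indices). The base fish sits still at the well centre.
planted_violation_track <- function(seed = 42) {
  set.seed(seed)
  wc <- c(3.2, 3.2)
  pose <- straight_pose(head = wc + c(2, 0), heading_deg = 0)
  coords <- array(NA_real_, c(500, 8, 2))
  for (i in 1:500) coords[i, , ] <- pose
  coords <- coords + rnorm(length(coords), 0, 0.005)
  # speed: whole pose teleports 1.0 mm for one frame (160 mm/s at 160 fps)
  coords[101, , 1] <- coords[101, , 1] + 1.0
  coords[301, , 1] <- coords[301, , 1] + 1.0
  # well boundary: centre key-point alone jumps outside the well
  coords[201, 5, ] <- wc + c(3.19 + 0.3, 0)
  # COM distance: caudal fin alone teleports 4 mm
  coords[401, 8, 2] <- coords[401, 8, 2] + 4.0
  pose_track(coords, fps = 160, unit = "mm", well_center = wc,
             well_radius = 3.19)
}

# independent ordered re-check of the three gates (speed -> well -> COM),
# returning which frames each rule removes, for brute-force comparison
brute_force_gates <- function(track, speed_max = 120, com_factor = 0.7) {
  n <- dim(track$coords)[1]
  com <- t(vapply(seq_len(n), function(i)
    colMeans(track$coords[i, c(1, 4, 5, 6, 7, 8), ]), numeric(2)))
  valid <- track$valid
  sp_rm <- integer(0)
  prev <- NA
  for (i in seq_len(n)) {
    if (!valid[i]) next
    if (!is.na(prev)) {
      v <- sqrt(sum((com[i, ] - com[prev, ])^2)) / ((i - prev) / track$fps)
      if (v > speed_max) { valid[i] <- FALSE; sp_rm <- c(sp_rm, i); next }
    }
    prev <- i
  }
  well_rm <- integer(0)
  for (i in which(valid)) {
    d <- sqrt(sum((track$coords[i, 5, ] - track$well_center)^2))
    if (d > track$well_radius) { valid[i] <- FALSE; well_rm <- c(well_rm, i) }
  }
  lens <- vapply(which(valid), function(i) {
    p <- track$coords[i, c(1, 4, 5, 6, 7, 8), ]
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1))
  bl <- median(lens)
  com_rm <- integer(0)
  for (i in which(valid)) {
    d <- sqrt((track$coords[i, , 1] - com[i, 1])^2 +
              (track$coords[i, , 2] - com[i, 2])^2)
    if (any(d > com_factor * bl)) { valid[i] <- FALSE; com_rm <- c(com_rm, i) }
  }
  list(speed = sp_rm, well = well_rm, com = com_rm, valid = valid)
}

# random rigid motion (rotation + translation, no reflection)
random_rigid <- function() {
  phi <- runif(1, -pi, pi)
  list(R = matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2),
       t = runif(2, -5, 5))
}

apply_rigid <- function(coords, rig) {
  d <- dim(coords)
  flat <- matrix(coords, prod(d[1:2]), 2) %*% t(rig$R)
  flat <- sweep(flat, 2, -rig$t)
  array(flat, d)
}
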