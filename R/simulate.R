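#' Simulated well geometry
#'
#' @param radius_mm Well radius in mm; default 3.19 (a 0.32 cm^2 circular
#'   well).
#' @param fps Frame rate (default 160).
#' @param mm_per_px Spatial scale for rendering (default 0.0249).
#' @param frame_px Rendered frame side length in pixels (default 256).
#' @return Object of class `sim_well`; the well centre sits at the centre
#'   of the rendered frame.
#' @export
sim_well <- function(radius_mm = 3.19, fps = 160, mm_per_px = 0.0249,
                     frame_px = 256L) {
  stopifnot(radius_mm > 0, fps > 0)
  structure(list(radius_mm = radius_mm, fps = fps, mm_per_px = mm_per_px,
                 frame_px = as.integer(frame_px),
                 center = rep(frame_px * mm_per_px / 2, 2L)),
            class = "sim_well")
}

#' Behavior-motif parameters
#'
#' Class-specific defaults emulate the five behavior regimes: stationary
#' (no movement), normal swim (brief burst-and-glide forward movement,
#' speeds below 50 mm/s), whirlpool (sustained orbit along the well edge
#' above 50 mm/s), convulsion (fast sinusoidal whole-body movement with
#' large right-left tail bends and speed bursts toward 120 mm/s) and
#' posture loss (larva on its side, eyes collapsed, near-static).
#'
#' @param class One of [behavior_classes()].
#' @param duration_s Motif duration in seconds.
#' @param speed_mm_s Speed scale: burst peak (normal swim), tangential
#'   orbit speed (whirlpool), burst peak (convulsion), drift (posture
#'   loss).
#' @param tail_amp_deg Tail-bend amplitude in degrees (<= 180).
#' @param tail_freq_hz Tail oscillation frequency.
#' @param orbit_radius_mm Whirlpool orbit radius.
#' @param inter_eye_mm Upright inter-eye distance (default 0.2 mm);
#'   collapsed to `collapse_eye_mm` when `posture_collapse`.
#' @param posture_collapse Collapse the eye offset (posture-loss motifs).
#' @param collapse_eye_mm Residual eye offset when collapsed.
#' @param noise_sd_mm Isotropic Gaussian positional jitter per key-point
#'   coordinate (default 0.02 mm, below typical pose-estimation error).
#' @param body_length_mm Larval length (default 4 mm).
#' @return Object of class `motif_params`.
#' @export
motif_params <- function(class, duration_s = 2,
                         speed_mm_s = NULL, tail_amp_deg = NULL,
                         tail_freq_hz = NULL, orbit_radius_mm = 2.5,
                         inter_eye_mm = 0.2, posture_collapse = NULL,
                         collapse_eye_mm = 0.005, noise_sd_mm = 0.02,
                         body_length_mm = 4) {
  class <- match.arg(class, behavior_classes())
  defaults <- switch(class,
    stationary = list(speed = 0, amp = 0, freq = 0, collapse = FALSE),
    normal_swim = list(speed = 30, amp = 25, freq = 20, collapse = FALSE),
    whirlpool = list(speed = 70, amp = 25, freq = 0, collapse = FALSE),
    convulsion = list(speed = 120, amp = 150, freq = 10, collapse = FALSE),
    posture_loss = list(speed = 0.5, amp = 15, freq = 0, collapse = TRUE))
  p <- structure(list(
    class = class, duration_s = duration_s,
    speed_mm_s = speed_mm_s %||% defaults$speed,
    tail_amp_deg = tail_amp_deg %||% defaults$amp,
    tail_freq_hz = tail_freq_hz %||% defaults$freq,
    orbit_radius_mm = orbit_radius_mm,
    inter_eye_mm = inter_eye_mm,
    posture_collapse = posture_collapse %||% defaults$collapse,
    collapse_eye_mm = collapse_eye_mm,
    noise_sd_mm = noise_sd_mm,
    body_length_mm = body_length_mm), class = "motif_params")
  stopifnot(p$duration_s > 0, p$speed_mm_s >= 0, p$tail_amp_deg <= 180)
  p
}

# build one 8-key-point pose: COM at `com`, heading unit vector `u`
# (direction the fish faces), signed tail bend `theta` (deg). The rostral
# axis (snout..center) is straight; the three caudal segments are hinged at
# the center key-point by exactly `theta`, so the measured tail angle
# (snout->center axis vs center->caudal_fin chord) equals |theta|.
build_pose <- function(com, u, theta_deg, eye_half_mm, body_length_mm = 4) {
  seg <- body_length_mm / 5
  b <- -u                                  # backward along the body
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  tl <- as.vector(R %*% b)                 # tail direction
  snout <- c(0, 0)
  rostral <- snout + seg * b
  center <- snout + 2 * seg * b
  caudal_trunk <- center + seg * tl
  mid_tail <- center + 2 * seg * tl
  caudal_fin <- center + 3 * seg * tl
  nrm <- c(-u[2], u[1])                    # lateral unit
  eye_base <- snout + 0.3 * b
  eye_l <- eye_base + eye_half_mm * nrm
  eye_r <- eye_base - eye_half_mm * nrm
  pts <- rbind(snout, eye_l, eye_r, rostral, center, caudal_trunk,
               mid_tail, caudal_fin)
  mid6 <- colMeans(pts[c(1, 4, 5, 6, 7, 8), ])
  sweep(pts, 2L, mid6 - com, `-`)
}

# reflect a heading back toward the well centre (with jitter) when the
# next step would leave the safe interior
steer_inside <- function(pos, ang, step, well, margin = 0.6) {
  nxt <- pos + step * c(cos(ang), sin(ang))
  if (sqrt(sum((nxt - well$center)^2)) > well$radius_mm - margin) {
    back <- atan2(well$center[2] - pos[2], well$center[1] - pos[1])
    ang <- back + stats::runif(1, -0.6, 0.6)
  }
  ang
}

#' Simulate one behavior motif
#'
#' Generates an 8-key-point pose track realizing the programmed kinematic
#' regime of one behavior class, together with the ground-truth per-frame
#' kinematics (speed, tail angle, inter-eye distance) before positional
#' noise. The COM of the constructed pose follows the programmed
#' trajectory exactly; reproducible under `seed`.
#'
#' @param params A [motif_params()].
#' @param well A [sim_well()].
#' @param seed Integer seed.
#' @param init Optional list with `pos` (COM start, mm) and `heading_deg`
#'   for continuity across concatenated motifs.
#' @return List with `track` (a [pose_track()] in mm), `label` (the class)
#'   and `truth` (data frame `speed`, `tail_angle`, `inter_eye`,
#'   `com_x`, `com_y`).
#' @export
simulate_motif <- function(params, well = sim_well(), seed = 1L,
                           init = NULL) {
  if (params$class == "whirlpool" &&
      params$orbit_radius_mm > well$radius_mm)
    stop("orbit radius exceeds the well radius")
  set.seed(seed)
  fps <- well$fps
  dt <- 1 / fps
  n <- max(2L, round(params$duration_s * fps))
  pos0 <- if (!is.null(init$pos)) init$pos else
    well$center + stats::runif(2, -0.3, 0.3) * well$radius_mm
  ang0 <- if (!is.null(init$heading_deg)) init$heading_deg * pi / 180 else
    stats::runif(1, -pi, pi)
  com <- matrix(0, n, 2L)
  ang <- numeric(n)
  theta <- numeric(n)
  v_prog <- numeric(n)
  tgrid <- (seq_len(n) - 1L) * dt
  cl <- params$class
  if (cl == "whirlpool") {
    r <- params$orbit_radius_mm
    omega <- params$speed_mm_s / r           # rad/s
    dir <- sample(c(-1, 1), 1L)
    d0 <- sqrt(sum((pos0 - well$center)^2))
    psi0 <- if (d0 > 0) atan2(pos0[2] - well$center[2],
                              pos0[1] - well$center[1])
            else stats::runif(1, -pi, pi)
    # starting on the programmed orbit unless continuing a previous motif,
    # in which case the radius relaxes onto the orbit over ~0.2 s
    r0 <- if (!is.null(init$pos)) d0 else r
    rt <- r + (r0 - r) * exp(-tgrid / 0.2)
    psi <- psi0 + dir * omega * tgrid
    com[, 1] <- well$center[1] + rt * cos(psi)
    com[, 2] <- well$center[2] + rt * sin(psi)
    ang <- psi + dir * pi / 2                # tangential heading
    theta <- rep(params$tail_amp_deg * dir, n)
    v_prog <- rep(params$speed_mm_s, n)
  } else {
    pos <- pos0
    a <- ang0
    for (i in seq_len(n)) {
      t <- tgrid[i]
      if (cl == "stationary") {
        v <- 0
        theta[i] <- 0
      } else if (cl == "posture_loss") {
        v <- params$speed_mm_s
        a <- a + stats::rnorm(1, 0, 0.02)
        theta[i] <- params$tail_amp_deg
      } else if (cl == "normal_swim") {
        ph <- t %% 0.5                       # 150 ms burst + 350 ms glide
        if (ph < 0.15) {
          v <- params$speed_mm_s * sin(pi * ph / 0.15)
          theta[i] <- params$tail_amp_deg *
            sin(2 * pi * params$tail_freq_hz * t)
          a <- a + stats::rnorm(1, 0, 0.01)
        } else {
          v <- 5 * exp(-(ph - 0.15) / 0.1)
          theta[i] <- 0
          a <- a + stats::rnorm(1, 0, 0.005)
        }
        if (ph < dt) a <- a + stats::runif(1, -0.4, 0.4)  # new bout heading
      } else {                               # convulsion
        v <- params$speed_mm_s * abs(sin(2 * pi * 2.5 * t))
        theta[i] <- params$tail_amp_deg *
          sin(2 * pi * params$tail_freq_hz * t)
        a <- a + 1.2 * sin(2 * pi * 3 * t) * dt * 2 * pi +
          stats::rnorm(1, 0, 0.03)
      }
      # convulsing larvae fold the tail, swinging the trunk key-points up
      # to ~1.2 mm from the COM, so they steer wider of the wall
      if (v > 0) a <- steer_inside(pos, a, v * dt, well,
                                   margin = if (cl == "convulsion") 1.3 else 0.6)
      pos <- pos + v * dt * c(cos(a), sin(a))
      com[i, ] <- pos
      ang[i] <- a
      v_prog[i] <- v
    }
  }
  eye_half <- if (params$posture_collapse) params$collapse_eye_mm / 2
              else params$inter_eye_mm / 2
  coords <- array(NA_real_, c(n, 8L, 2L))
  for (i in seq_len(n)) {
    u <- c(cos(ang[i]), sin(ang[i]))
    coords[i, , ] <- build_pose(com[i, ], u, theta[i], eye_half,
                                params$body_length_mm)
  }
  if (params$noise_sd_mm > 0)
    coords <- coords + stats::rnorm(length(coords), 0, params$noise_sd_mm)
  track <- pose_track(coords, fps = fps, unit = "mm",
                      mm_per_px = well$mm_per_px,
                      well_id = paste0("sim_", cl),
                      well_center = well$center,
                      well_radius = well$radius_mm)
  truth <- data.frame(speed = v_prog, tail_angle = abs(theta),
                      inter_eye = 2 * eye_half,
                      com_x = com[, 1], com_y = com[, 2])
  list(track = track, label = cl, truth = truth,
       final = list(pos = com[n, ], heading_deg = ang[n] * 180 / pi))
}

#' Simulate a full recording epoch from a class schedule
#'
#' Concatenates motifs with a continuous COM and heading across
#' boundaries; per-frame true labels are retained. A 300 s schedule at
#' 160 fps yields 48,000 frames.
#'
#' @param schedule List of `list(class =, duration_s =)` entries (or a
#'   2-column data frame); total duration at most 300 s.
#' @param well A [sim_well()].
#' @param seed Integer seed.
#' @param noise_sd_mm Positional jitter forwarded to every motif.
#' @return List with `track`, `labels` (per-frame true classes) and
#'   `truth` (row-bound per-frame ground truth).
#' @export
simulate_epoch <- function(schedule, well = sim_well(), seed = 1L,
                           noise_sd_mm = 0.02) {
  if (is.data.frame(schedule))
    schedule <- lapply(seq_len(nrow(schedule)), function(i)
      list(class = schedule$class[i], duration_s = schedule$duration_s[i]))
  if (!length(schedule)) stop("empty schedule")
  tot <- sum(vapply(schedule, `[[`, numeric(1), "duration_s"))
  if (tot > 300) stop("schedule exceeds a 300 s epoch")
  coords <- NULL; labels <- character(0); truth <- NULL
  init <- NULL
  for (j in seq_along(schedule)) {
    sc <- schedule[[j]]
    mp <- motif_params(sc$class, duration_s = sc$duration_s,
                       noise_sd_mm = noise_sd_mm)
    m <- simulate_motif(mp, well, seed = seed + j, init = init)
    coords <- if (is.null(coords)) m$track$coords else
      abind3(coords, m$track$coords)
    labels <- c(labels, rep(sc$class, n_frames(m$track)))
    truth <- if (is.null(truth)) m$truth else rbind(truth, m$truth)
    init <- m$final
  }
  track <- pose_track(coords, fps = well$fps, unit = "mm",
                      mm_per_px = well$mm_per_px, well_id = "sim_epoch",
                      well_center = well$center,
                      well_radius = well$radius_mm)
  list(track = track, labels = labels, truth = truth)
}

# bind two T x 8 x 2 arrays along the frame axis
abind3 <- function(a, b) {
  out <- array(NA_real_, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' Build a balanced labelled training corpus of pose windows
#'
#' Cuts one 60-frame window from each of `n_per_class` independently
#' seeded motifs per class (random window phase within the motif), giving
#' a balanced labelled clip set for classifier training. Deterministic
#' under `seed`.
#'
#' @param n_per_class Windows per class (at least 10).
#' @param well A [sim_well()].
#' @param seed Integer seed.
#' @param window_len Window length in frames (default 60).
#' @param noise_sd_mm Positional jitter forwarded to the motifs.
#' @return List with `windows` (raw window list) and `labels` (character).
#' @export
make_training_corpus <- function(n_per_class = 100L, well = sim_well(),
                                 seed = 1L, window_len = 60L,
                                 noise_sd_mm = 0.02) {
  if (n_per_class < 10L) stop("need at least 10 windows per class")
  classes <- behavior_classes()
  windows <- list(); labels <- character(0)
  dur <- (window_len + 40L) / well$fps      # room for a random phase
  k <- 0L
  for (ci in seq_along(classes)) {
    for (r in seq_len(n_per_class)) {
      k <- k + 1L
      sd_i <- seed + 1000L * ci + r
      mp <- motif_params(classes[ci], duration_s = dur,
                         noise_sd_mm = noise_sd_mm)
      m <- simulate_motif(mp, well, seed = sd_i)
      set.seed(sd_i + 500000L)
      s <- sample.int(n_frames(m$track) - window_len + 1L, 1L) - 1L
      windows[[k]] <- list(start_frame = s,
                           coords = m$track$coords[(s + 1L):(s + window_len), , ,
                                                   drop = FALSE],
                           track_id = sprintf("%s_%03d", classes[ci], r))
      labels[k] <- classes[ci]
    }
  }
  list(windows = windows, labels = labels)
}
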