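test_that("a noise-free stationary motif is perfectly still", {
  m <- simulate_motif(motif_params("stationary", duration_s = 1,
                                   noise_sd_mm = 0), sim_well(), seed = 90)
  co <- m$track$coords
  for (i in 2:dim(co)[1]) expect_identical(co[i, , ], co[1, , ])
  expect_equal(speed_series(m$track)$total_distance_m, 0)
})

test_that("whirlpool tangential speed matches the r*omega closed form within 1%", {
  p <- motif_params("whirlpool", duration_s = 3, speed_mm_s = 70,
                    orbit_radius_mm = 2.5)
  m <- simulate_motif(p, sim_well(), seed = 91)
  v <- speed_series(m$track)$speed
  expect_lt(abs(median(v, na.rm = TRUE) - 70) / 70, 0.01)
  # a 40 deg-per-frame-equivalent rate: omega = 40*160 deg/s on r = 2.5
  omega <- 40 / 180 * pi * 160
  p2 <- motif_params("whirlpool", duration_s = 1,
                     speed_mm_s = 2.5 * omega, orbit_radius_mm = 2.5,
                     noise_sd_mm = 0)
  # chord sampling of a circle underestimates arc speed by sin(x)/x
  m2 <- simulate_motif(p2, sim_well(), seed = 92)
  v2 <- median(speed_series(m2$track)$speed, na.rm = TRUE)
  x <- omega / 160 / 2
  expect_equal(v2, 2.5 * omega * sin(x) / x, tolerance = 1e-6)
  expect_error(simulate_motif(motif_params("whirlpool",
                                           orbit_radius_mm = 10)),
               "orbit radius")
})

test_that("posture-loss motifs collapse the eyes, upright motifs do not", {
  pl <- simulate_motif(motif_params("posture_loss", duration_s = 2),
                       sim_well(), seed = 93)
  up <- simulate_motif(motif_params("normal_swim", duration_s = 2),
                       sim_well(), seed = 94)
  expect_lt(mean(inter_eye_distance(pl$track), na.rm = TRUE), 0.05)
  d_up <- mean(inter_eye_distance(up$track), na.rm = TRUE)
  expect_gt(d_up, 0.15); expect_lt(d_up, 0.25)
})

test_that("simulated COMs stay inside the well for every class", {
  well <- sim_well()
  for (cls in behavior_classes()) {
    m <- simulate_motif(motif_params(cls, duration_s = 2), well,
                        seed = 95 + match(cls, behavior_classes()))
    com <- t(vapply(seq_len(n_frames(m$track)), function(i)
      colMeans(m$track$coords[i, c(1, 4, 5, 6, 7, 8), ]), numeric(2)))
    dists <- sqrt(rowSums(sweep(com, 2, well$center)^2))
    expect_lt(max(dists), well$radius_mm)
  }
})

test_that("motifs are bitwise reproducible under a seed", {
  for (cls in c("normal_swim", "convulsion")) {
    a <- simulate_motif(motif_params(cls, duration_s = 1), sim_well(),
                        seed = 96)
    b <- simulate_motif(motif_params(cls, duration_s = 1), sim_well(),
                        seed = 96)
    expect_identical(a$track$coords, b$track$coords)
    expect_identical(a$truth, b$truth)
  }
})

test_that("epoch schedules concatenate with continuous COM and exact labels", {
  sched <- data.frame(class = c("stationary", "normal_swim", "whirlpool",
                                "convulsion", "posture_loss"),
                      duration_s = c(1, 1, 1, 1, 1))
  ep <- simulate_epoch(sched, sim_well(), seed = 97)
  expect_identical(n_frames(ep$track), 800L)
  expect_identical(ep$labels,
                   rep(as.character(sched$class), each = 160))
  # COM jump across every boundary stays small (continuity)
  com <- t(vapply(seq_len(800), function(i)
    colMeans(ep$track$coords[i, c(1, 4, 5, 6, 7, 8), ]), numeric(2)))
  steps <- sqrt(rowSums(diff(com)^2))
  expect_lt(max(steps[c(160, 320, 480, 640)]), 1.0)
  expect_error(simulate_epoch(list(), sim_well()), "empty schedule")
  expect_error(simulate_epoch(data.frame(class = "stationary",
                                         duration_s = 301), sim_well()),
               "300 s")
})

test_that("a 300 s epoch at 160 fps yields 48,000 frames", {
  sched <- data.frame(class = "whirlpool", duration_s = 300)
  ep <- simulate_epoch(sched, sim_well(), seed = 98)
  expect_identical(n_frames(ep$track), 48000L)
})

test_that("the training corpus is balanced, finite and reproducible", {
  corp <- make_training_corpus(10L, seed = 99)
  expect_length(corp$windows, 50L)
  expect_true(all(table(corp$labels) == 10L))
  for (w in corp$windows) {
    expect_identical(dim(w$coords), c(60L, 8L, 2L))
    expect_true(all(is.finite(w$coords)))
  }
  corp2 <- make_training_corpus(10L, seed = 99)
  expect_identical(corp$windows[[17]]$coords, corp2$windows[[17]]$coords)
  expect_error(make_training_corpus(5L), "at least 10")
})

test_that("rendered stationary larvae produce zero activity", {
  well <- sim_well(frame_px = 64L, mm_per_px = 0.1)
  m <- simulate_motif(motif_params("stationary", duration_s = 0.05,
                                   noise_sd_mm = 0), well, seed = 100)
  st <- render_frames(m$track, well)
  expect_identical(length(st$frames), n_frames(m$track))
  expect_identical(dim(st$frames[[1]]), c(64L, 64L))
  expect_identical(activity_trace(st)$total_activity, 0L)
})

test_that("rendered activity grows with per-frame displacement", {
  well <- sim_well(frame_px = 64L, mm_per_px = 0.1)
  totals <- vapply(c(0, 0.08, 0.2), function(step) {
    offs <- cbind(step * (0:4), 0)
    tr <- make_track(straight_pose(head = c(4, 3)), n = 5, offsets = offs)
    activity_trace(render_frames(tr, well),
                   activity_params(d_abs = 20))$total_activity
  }, numeric(1))
  expect_identical(totals[1], 0)
  expect_true(all(diff(totals) >= 0))
  expect_gt(totals[3], 0)
})

test_that("rendering honours the requested frame size", {
  well <- sim_well(frame_px = 256L)
  m <- simulate_motif(motif_params("stationary", duration_s = 0.02), well,
                      seed = 101)
  st <- render_frames(m$track, well)
  expect_identical(dim(st$frames[[1]]), c(256L, 256L))
})
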