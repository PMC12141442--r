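test_that("speed, distance and max speed follow the COM displacement", {
  # stationary: all zero
  tr <- make_track(straight_pose(), n = 50)
  sp <- speed_series(tr)
  expect_true(all(sp$speed[-1] == 0))
  expect_equal(sp$total_distance_m, 0)
  # 0.25 mm per frame at 160 fps = 40 mm/s; 48,000 frames cover 12 m
  n <- 48000
  offs <- cbind(0.25 * (seq_len(n) - 1), 0)
  # keep the fish inside a huge virtual well: geometry is irrelevant here
  tr2 <- make_track(straight_pose(head = c(1, 0)), n = n, offsets = offs,
                    well_center = c(0, 0), well_radius = 1e9)
  sp2 <- speed_series(tr2)
  expect_equal(unique(round(sp2$speed[-1], 9)), 40)
  expect_equal(sp2$total_distance_m, 0.25 * (n - 1) / 1000, tolerance = 1e-12)
  expect_equal(sp2$max_speed, 40)
  expect_error(speed_series(make_track(straight_pose(), n = 1)),
               "2 valid frames")
})

test_that("circular motion recovers the tangential speed within discretization error", {
  fps <- 160; r <- 2.5; omega <- 28  # rad/s -> r*omega = 70 mm/s
  n <- 400
  t <- (seq_len(n) - 1) / fps
  offs <- cbind(r * cos(omega * t), r * sin(omega * t))
  tr <- make_track(straight_pose(head = c(0, 0)), n = n, offsets = offs,
                   well_center = c(0, 0), well_radius = 1e9)
  sp <- speed_series(tr)
  v <- sp$speed[-1]
  expect_lt(abs(median(v) - r * omega) / (r * omega), 0.005)
})

test_that("tail angle anchors at 0 (extended), 90 (perpendicular) and 180 (folded)", {
  expect_equal(tail_angle(c(0, 0), c(0, 1), c(0, 2)), 0)
  expect_equal(tail_angle(c(0, 0), c(0, 1), c(1, 1)), 90)
  expect_equal(tail_angle(c(0, 0), c(0, 1), c(0, 0)), 180)
  expect_true(is.na(tail_angle(c(0, 0), c(0, 0), c(0, 1))))
})

test_that("heading change is signed, wrapped to (-180, 180], CCW-positive y-up", {
  sk <- skeleton_spec()
  mk_heading_track <- function(hvecs) {
    n <- nrow(hvecs)
    coords <- array(0, c(n, 8, 2))
    for (i in seq_len(n)) {
      coords[i, 5, ] <- c(0, 0)              # center
      coords[i, 1, ] <- hvecs[i, ]           # snout = center + heading
      coords[i, c(2:4, 6:8), 1] <- 0.5       # keep other points finite
    }
    pose_track(coords, fps = 160, unit = "mm")
  }
  # raster heading (1,0) then (0,-1) (image-up): +90
  hc <- heading_change(mk_heading_track(rbind(c(1, 0), c(0, -1))))
  expect_equal(hc[2], 90)
  # constant heading: 0
  hc2 <- heading_change(mk_heading_track(rbind(c(1, 0), c(1, 0), c(1, 0))))
  expect_equal(hc2[-1], c(0, 0))
  # exact reversal lands on the +180 wrap boundary
  hc3 <- heading_change(mk_heading_track(rbind(c(1, 0), c(-1, 0))))
  expect_equal(hc3[2], 180)
  # approaching the boundary from the CCW side stays positive
  hc4 <- heading_change(mk_heading_track(rbind(c(1, 0), c(-1, -1e-6))))
  expect_gt(hc4[2], 179.9)
  # degenerate heading vector masks the frame
  hc5 <- heading_change(mk_heading_track(rbind(c(1, 0), c(0, 0), c(1, 0))))
  expect_true(is.na(hc5[2]))
})

test_that("inter-eye distance reads 0.2 mm upright and 0 when collapsed", {
  tr <- make_track(straight_pose(eye_half = 0.1), n = 4)
  expect_equal(unique(round(inter_eye_distance(tr), 12)), 0.2)
  tr0 <- make_track(straight_pose(eye_half = 0), n = 4)
  expect_equal(unique(inter_eye_distance(tr0)), 0)
})

test_that("a synthetic upright larva shows the ~200 micron inter-eye scale", {
  m <- simulate_motif(motif_params("stationary", duration_s = 1),
                      sim_well(), seed = 30)
  d <- mean(inter_eye_distance(m$track), na.rm = TRUE)
  expect_gt(d, 0.15); expect_lt(d, 0.25)
})

test_that("kinematic metrics are invariant under global rigid motion", {
  set.seed(31)
  m <- simulate_motif(motif_params("normal_swim", duration_s = 1),
                      sim_well(), seed = 31)
  tr <- m$track
  k0 <- kinematic_series(tr)
  for (rep in 1:5) {
    rig <- random_rigid()
    tr2 <- tr
    tr2$coords <- apply_rigid(tr$coords, rig)
    k1 <- kinematic_series(tr2)
    expect_equal(k1$frames$tail_angle, k0$frames$tail_angle, tolerance = 1e-9)
    expect_equal(k1$frames$heading_change, k0$frames$heading_change,
                 tolerance = 1e-9)
    expect_equal(k1$frames$inter_eye, k0$frames$inter_eye, tolerance = 1e-9)
    expect_equal(k1$frames$speed, k0$frames$speed, tolerance = 1e-9)
  }
})

test_that("distances scale with the calibration while angles do not", {
  m <- simulate_motif(motif_params("normal_swim", duration_s = 1),
                      sim_well(), seed = 32)
  tr <- m$track
  k0 <- kinematic_series(tr)
  tr2 <- tr
  tr2$coords <- tr$coords * 2
  tr2$well_center <- tr$well_center * 2; tr2$well_radius <- tr$well_radius * 2
  k2 <- kinematic_series(tr2)
  expect_equal(k2$frames$speed, 2 * k0$frames$speed, tolerance = 1e-9)
  expect_equal(k2$summary$total_distance_m, 2 * k0$summary$total_distance_m)
  expect_equal(k2$frames$tail_angle, k0$frames$tail_angle, tolerance = 1e-7)
  expect_equal(k2$frames$heading_change, k0$frames$heading_change,
               tolerance = 1e-7)
})

test_that("no cleaned track exceeds the speed gate (gate consistency)", {
  for (cls in c("normal_swim", "whirlpool", "convulsion")) {
    m <- simulate_motif(motif_params(cls, duration_s = 2), sim_well(),
                        seed = 33)
    res <- clean_track(m$track)
    k <- kinematic_series(res$track)
    expect_lte(k$summary$max_speed, 120)
  }
})

test_that("a whirlpool fixture sustains > 50 mm/s and turns at the programmed rate", {
  m <- simulate_motif(motif_params("whirlpool", duration_s = 2,
                                   speed_mm_s = 70), sim_well(), seed = 34)
  k <- kinematic_series(m$track)
  v <- k$frames$speed
  expect_gt(quantile(v, 0.25, na.rm = TRUE), 50)
  # |heading change| per frame ~ omega * dt in degrees
  omega_dps <- 70 / 2.5 * 180 / pi
  expected <- omega_dps / 160
  expect_lt(abs(median(k$frames$heading_change_abs, na.rm = TRUE) - expected),
            0.2 * expected)
})

test_that("a convulsion fixture reaches the programmed tail-angle amplitude", {
  m <- simulate_motif(motif_params("convulsion", duration_s = 2,
                                   tail_amp_deg = 150), sim_well(), seed = 35)
  k <- kinematic_series(m$track)
  expect_lt(abs(max(k$frames$tail_angle, na.rm = TRUE) - 150), 5)
})

test_that("a stationary fixture yields flat kinematics", {
  m <- simulate_motif(motif_params("stationary", duration_s = 1,
                                   noise_sd_mm = 0), sim_well(), seed = 36)
  k <- kinematic_series(m$track)
  expect_equal(k$summary$total_distance_m, 0)
  expect_equal(max(k$frames$heading_change_abs, na.rm = TRUE), 0)
  expect_equal(sd(k$frames$inter_eye), 0)
})

test_that("kinematics export one row per frame with the expected columns", {
  m <- simulate_motif(motif_params("normal_swim", duration_s = 0.5),
                      sim_well(), seed = 37)
  k <- kinematic_series(m$track)
  path <- withr::local_tempfile(fileext = ".csv")
  write_kinematics(k, path)
  d <- read.csv(path)
  expect_identical(names(d), c("frame", "com_x", "com_y", "speed",
                               "dist_cum", "tail_angle", "heading_change",
                               "inter_eye"))
  expect_equal(nrow(d), n_frames(m$track))
})
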