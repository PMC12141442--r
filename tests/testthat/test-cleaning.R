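test_that("the COM is the mean of the six midline points, eyes excluded", {
  sk <- skeleton_spec()
  all_same <- matrix(1, 8, 2)
  expect_equal(compute_com(all_same, sk), c(1, 1), ignore_attr = TRUE)
  # eyes far away do not move the COM
  pts <- matrix(0, 8, 2)
  pts[c(2, 3), ] <- 10
  expect_equal(compute_com(pts, sk), c(0, 0), ignore_attr = TRUE)
  # midline x = 0..5: mean 2.5
  pts2 <- matrix(0, 8, 2)
  pts2[sk$midline, 1] <- 0:5
  pts2[c(2, 3), 1] <- 99
  expect_equal(compute_com(pts2, sk), c(2.5, 0), ignore_attr = TRUE)
  expect_error(compute_com(matrix(NA_real_, 8, 2), sk), "invalid frame")
})

test_that("the speed gate removes only implausibly fast frames, gap-aware", {
  # 0.1 mm per frame at 160 fps = 16 mm/s: no removals
  offs <- cbind(0.1 * (0:19), 0)
  tr <- make_track(straight_pose(head = c(1, 3)), n = 20, offsets = offs)
  g <- speed_gate(tr)
  expect_length(g$removed, 0L)
  # one frame teleports 1.0 mm (160 mm/s): exactly that frame goes
  tr2 <- make_track(straight_pose(), n = 10)
  tr2$coords[5, , 1] <- tr2$coords[5, , 1] + 1.0
  g2 <- speed_gate(tr2)
  expect_identical(g2$removed, 5L)
  # and the frame after it survives: the gap-aware speed spans 2 frames
  expect_true(g2$track$valid[6])
  # stationary track: nothing to remove
  g3 <- speed_gate(make_track(straight_pose(), n = 15))
  expect_length(g3$removed, 0L)
})

test_that("the well gate uses a closed-disk convention on the center key-point", {
  # geometry chosen exactly representable in binary so the boundary case
  # tests the convention, not floating round-off
  wc <- c(3, 3); R <- 0.5
  tr <- make_track(straight_pose(head = wc + c(2, 0)), n = 3,
                   well_center = wc, well_radius = R)
  # the base pose keeps the center key-point ~0.4 mm from the well centre
  expect_length(well_gate(tr)$removed, 0L)
  # center key-point exactly on the boundary: retained
  tr$coords[2, 5, ] <- wc + c(R, 0)
  expect_length(well_gate(tr)$removed, 0L)
  # just outside: removed
  tr$coords[2, 5, ] <- wc + c(R + 0.1, 0)
  expect_identical(well_gate(tr)$removed, 2L)
  tr$well_center <- NULL
  expect_error(well_gate(tr), "well_center")
})

test_that("the COM gate matches an exhaustive per-frame re-check", {
  cfg <- cleaning_config(body_length_mm = 4)
  # compact pose: max key-point-COM distance ~2.0 mm = 0.5 x L -> retained
  tr <- make_track(straight_pose(), n = 5)
  expect_length(com_gate(tr, cfg)$removed, 0L)
  # teleport the caudal fin on frames 2 and 4 to ~2 x L from the COM
  tr$coords[2, 8, 2] <- tr$coords[2, 8, 2] + 8
  tr$coords[4, 8, 2] <- tr$coords[4, 8, 2] + 8
  g <- com_gate(tr, cfg)
  expect_identical(g$removed, c(2L, 4L))
  # brute-force: recompute every frame's distances directly
  for (i in 1:5) {
    com_i <- colMeans(tr$coords[i, c(1, 4, 5, 6, 7, 8), ])
    d <- sqrt((tr$coords[i, , 1] - com_i[1])^2 +
              (tr$coords[i, , 2] - com_i[2])^2)
    expect_identical(i %in% g$removed, any(d > 0.7 * 4))
  }
})

test_that("clean_track removes exactly the planted violations with correct attribution", {
  tr <- planted_violation_track(seed = 42)
  res <- clean_track(tr)
  rep <- res$report
  expect_identical(sort(rep$removed_speed_frames), c(101L, 301L))
  expect_identical(rep$removed_well_frames, 201L)
  expect_identical(rep$removed_com_frames, 401L)
  expect_identical(rep$retained, 496L)
  # independent ordered brute-force re-check agrees
  bf <- brute_force_gates(tr)
  expect_identical(sort(bf$speed), sort(rep$removed_speed_frames))
  expect_identical(bf$well, rep$removed_well_frames)
  expect_identical(bf$com, rep$removed_com_frames)
  expect_identical(res$track$valid, bf$valid)
})

test_that("cleaning conserves frame counts and never resurrects frames", {
  tr <- planted_violation_track(seed = 43)
  pre <- tr$valid
  res <- clean_track(tr)
  rep <- res$report
  expect_identical(rep$pre_invalid + rep$removed_speed + rep$removed_well +
                   rep$removed_com + rep$retained, rep$n_frames)
  expect_true(all(res$track$valid <= pre))  # true -> false only
})

test_that("cleaning is idempotent: a second pass removes nothing", {
  tr <- planted_violation_track(seed = 44)
  once <- clean_track(tr)
  twice <- clean_track(once$track)
  expect_identical(twice$report$removed_speed, 0L)
  expect_identical(twice$report$removed_well, 0L)
  expect_identical(twice$report$removed_com, 0L)
  expect_identical(twice$track$valid, once$track$valid)
})

test_that("an already-clean track is untouched by the gates and barely moved by denoising", {
  set.seed(45)
  tr <- make_track(straight_pose(), n = 200, noise_sd = 0.01)
  res <- clean_track(tr)
  expect_identical(res$report$removed_speed + res$report$removed_well +
                   res$report$removed_com, 0L)
  expect_lt(max(abs(res$track$coords - tr$coords)), 0.1)
})

test_that("a track with no surviving frames is flagged unusable", {
  tr <- make_track(straight_pose(), n = 10)
  tr$valid[] <- FALSE
  tr$valid[1] <- TRUE  # one frame, then push it outside the well
  tr$coords[1, 5, ] <- tr$well_center + c(tr$well_radius + 1, 0)
  res <- clean_track(tr)
  expect_false(res$report$usable)
})

test_that("body length is estimated as the median midline polyline length", {
  tr <- make_track(straight_pose(length_mm = 4), n = 6)
  expect_equal(estimate_body_length(tr), 4, tolerance = 1e-9)
})

test_that("batched sigma averages the per-feature estimates across tracks", {
  set.seed(46)
  trs <- lapply(1:3, function(i) make_track(straight_pose(), n = 256,
                                            noise_sd = 0.05))
  s <- estimate_sigma_batch(trs)
  expect_length(s, 16L)
  expect_true(all(s > 0.03 & s < 0.07))
})
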