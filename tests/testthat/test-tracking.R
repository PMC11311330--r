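# Smooth trackable texture used by several tests.
texture_frame <- function(h = 64, w = 64, seed = 1) {
  set.seed(seed)
  f <- matrix(rnorm(h * w), h, w)
  f <- exhaleflow:::gauss_blur(f, 2)
  (f - min(f)) / (max(f) - min(f))
}

test_that("keypoint detection finds corners and ignores flat regions", {
  flat <- matrix(0.5, 40, 40)
  expect_equal(nrow(detect_keypoints(flat, roi(1, 1, 40, 40))), 0)
  # single bright pixel on dark background is a corner
  one <- matrix(0, 40, 40)
  one[20, 22] <- 1
  kp <- detect_keypoints(one, roi(1, 1, 40, 40), max_points = 5)
  expect_gt(nrow(kp), 0)
  expect_true(any(abs(kp[, 1] - 20) <= 1 & abs(kp[, 2] - 22) <= 1))
})

test_that("generator face yields keypoints on the face, none in background", {
  sim <- simulate_sequence(sim_config(duration_s = 0.2, seed = 4))
  np <- estimate_norm_params(sim$seq$frames[[1]], sim$truth$roi,
                             sim$truth$bg_roi)
  trk <- normalize_frame(sim$seq$frames[[1]], np$tracking, "tracking")
  kp <- detect_keypoints(trk, sim$truth$roi, 25)
  expect_gte(nrow(kp), 5)
  # all detections sit on warm (face) pixels, none in the ambient noise
  vals <- trk[cbind(kp[, 1], kp[, 2])]
  expect_true(all(vals > 0.05))
  # pure-noise background region yields nothing above the face responses
  bg <- detect_keypoints(trk, sim$truth$bg_roi, 25, margin = 2)
  if (nrow(bg) > 0) {
    bgvals <- trk[cbind(bg[, 1], bg[, 2])]
    expect_true(all(bgvals <= 0.05))  # clamped background
  }
  succeed()
})

test_that("estimate_shift recovers integer translations and rounds jitter", {
  f <- texture_frame(seed = 2)
  kp <- detect_keypoints(f, roi(9, 9, 48, 48), 15)
  expect_gte(nrow(kp), 3)
  # static
  es <- estimate_shift(f, f, kp)
  expect_identical(es$shift, c(0L, 0L))
  # translation by (0, +3): cur(x) = prev(x - 3 cols)
  g3 <- exhaleflow:::shift_bilinear(f, 0, 3)
  es3 <- estimate_shift(f, g3, kp)
  expect_identical(es3$shift, c(0L, 3L))
  expect_identical(oracle_ssd_shift(f, g3), c(0L, 3L))
  # sub-threshold translation absorbed by the dead-band
  g04 <- exhaleflow:::shift_bilinear(f, 0, 0.4)
  es04 <- estimate_shift(f, g04, kp)
  expect_identical(es04$shift, c(0L, 0L))
  expect_identical(oracle_ssd_shift(f, g04), c(0L, 0L))
  # no keypoints -> zero shift, low confidence
  none <- estimate_shift(f, g3, matrix(integer(0), 0, 2))
  expect_true(none$low_confidence)
  expect_identical(none$shift, c(0L, 0L))
})

test_that("static scenes keep the ROI fixed with all-zero shift history", {
  sim <- simulate_sequence(sim_config(duration_s = 2, seed = 6,
                                      drift_mode = "none",
                                      plume = list(emission_amplitude = 0)))
  np <- estimate_norm_params(sim$seq$frames[[1]], sim$truth$roi,
                             sim$truth$bg_roi)
  rois <- track_sequence(sim$seq, sim$truth$roi, np$tracking)
  expect_equal(nrow(attr(rois, "shift_history")), length(sim$seq$frames) - 1)
  expect_true(all(attr(rois, "shift_history") == 0))
  expect_true(all(vapply(rois, function(r) r$row0 == sim$truth$roi$row0 &&
                           r$col0 == sim$truth$roi$col0, logical(1))))
  # size invariant
  expect_true(all(vapply(rois, `[[`, integer(1), "height") == 64))
})

test_that("tracked ROI follows a linear rightward drift", {
  sim <- simulate_sequence(sim_config(duration_s = 0.44, seed = 5,
                                      drift_mode = "linear_right",
                                      drift_speed = 1))
  np <- estimate_norm_params(sim$seq$frames[[1]], sim$truth$roi,
                             sim$truth$bg_roi)
  rois <- track_sequence(sim$seq, sim$truth$roi, np$tracking)
  n <- length(rois)
  moved <- rois[[n]]$col0 - rois[[1]]$col0
  expect_lte(abs(moved - sim$truth$face_trajectory[n, 2]), 1)
})

test_that("ROI position error stays within 2 px over 200 drifting frames", {
  sim <- simulate_sequence(sim_config(h = 128, w = 256, duration_s = 8,
                                      seed = 7, drift_mode = "linear_right",
                                      drift_speed = 0.08))
  np <- estimate_norm_params(sim$seq$frames[[1]], sim$truth$roi,
                             sim$truth$bg_roi)
  rois <- track_sequence(sim$seq, sim$truth$roi, np$tracking)
  c0 <- vapply(rois, `[[`, integer(1), "col0")
  r0 <- vapply(rois, `[[`, integer(1), "row0")
  err <- sqrt((r0 - (sim$truth$roi$row0 + sim$truth$face_trajectory[, 1]))^2 +
              (c0 - (sim$truth$roi$col0 + sim$truth$face_trajectory[, 2]))^2)
  expect_lte(mean(err), 2)
})

test_that("a drift pushing the ROI past the frame edge clamps and flags", {
  frames <- lapply(1:3, function(i) matrix(6000L, 32, 32))
  seq <- thermal_sequence(frames)
  r <- roi(1, 30, 16, 16)  # would exceed: col0 + 16 - 1 = 45 > 32
  np <- norm_params(Fc = 6500, Ac = 6000, Imax = 7000)
  rois <- track_sequence(seq, r, np)
  expect_equal(rois[[1]]$col0, 32 - 16 + 1)
  expect_equal(attr(rois, "flags")[1], "clamped")
})

test_that("compensate_shift removes exactly the stated uniform motion", {
  f <- array(0, c(4, 4, 2))
  f[, , 1] <- 1  # uniform vx = 1
  out <- compensate_shift(f, c(0, 1))
  expect_true(all(out == 0))
  # identity at zero shift
  expect_identical(compensate_shift(f, c(0, 0)), f)
  # linearity: s then -s restores exactly
  set.seed(8)
  g <- random_field(6, 5)
  expect_equal(compensate_shift(compensate_shift(g, c(2, -3)), c(-2, 3)),
               g, tolerance = 1e-12)
})

test_that("holding the crop window fixed cancels static-scene motion", {
  # flow between crops taken at two different ROIs of a static textured
  # scene has large magnitude; the fixed-window crop pair is near zero
  f <- texture_frame(96, 96, seed = 9)
  r1 <- roi(17, 17, 48, 48)
  r2 <- roi(17, 20, 48, 48)   # ROI moved 3 px right
  moving <- horn_schunck(crop_roi(f, r1), crop_roi(f, r2), flow_params())
  fixed <- horn_schunck(crop_roi(f, r2), crop_roi(f, r2), flow_params())
  expect_lt(mean(sqrt(fixed[, , 1]^2 + fixed[, , 2]^2)),
            mean(sqrt(moving[, , 1]^2 + moving[, , 2]^2)))
  expect_true(all(fixed == 0))
})

test_that("face mask covers the face footprint and dilation grows it", {
  sim <- simulate_sequence(sim_config(duration_s = 0.2, seed = 4))
  np <- estimate_norm_params(sim$seq$frames[[1]], sim$truth$roi,
                             sim$truth$bg_roi)
  trk <- normalize_frame(sim$seq$frames[[1]], np$tracking, "tracking")
  crop <- crop_roi(trk, sim$truth$roi)
  m0 <- make_face_mask(crop, dilate = 0)
  m2 <- make_face_mask(crop, dilate = 2)
  expect_gt(sum(m0), 0.1 * length(m0))
  expect_lt(sum(m0), 0.8 * length(m0))
  expect_true(all(m2[m0]))
  expect_gt(sum(m2), sum(m0))
})
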