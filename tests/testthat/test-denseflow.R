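test_that("Sobel gradients match analytic ramps and the stencil oracle", {
  flat <- matrix(0.7, 5, 5)
  g <- spatial_gradients(flat)
  expect_lt(max(abs(g$Ix), abs(g$Iy)), 1e-14)
  ramp <- matrix(rep(1:6, each = 5), 5, 6)   # I(r,c) = c
  g <- spatial_gradients(ramp)
  expect_equal(g$Ix[2:4, 2:5], matrix(1, 3, 4))
  expect_equal(g$Iy[2:4, 2:5], matrix(0, 3, 4))
  set.seed(1)
  m <- matrix(runif(25), 5, 5)
  g <- spatial_gradients(m)
  expect_equal(g$Ix, oracle_sobel(m, "x"), tolerance = 1e-12)
  expect_equal(g$Iy, oracle_sobel(m, "y"), tolerance = 1e-12)
  expect_error(spatial_gradients(matrix(0, 2, 2)), "3x3")
})

test_that("identical frames give an exactly zero field for any n_iter", {
  set.seed(2)
  f <- matrix(runif(64), 8, 8)
  for (ni in c(1, 7, 64))
    expect_true(all(horn_schunck(f, f, flow_params(0.15, ni)) == 0))
})

test_that("the iterative solve equals the loop-based oracle on small inputs", {
  set.seed(3)
  for (case in list(c(4, 4, 3), c(6, 5, 5), c(8, 8, 10))) {
    f1 <- matrix(runif(case[1] * case[2]), case[1], case[2])
    f2 <- matrix(runif(case[1] * case[2]), case[1], case[2])
    got <- horn_schunck(f1, f2, flow_params(0.15, case[3]))
    ref <- oracle_horn_schunck(f1, f2, 0.15, case[3])
    expect_lt(max(abs(got - ref)), 1e-10)
  }
})

test_that("a translated Gaussian blob yields rightward unit-scale flow", {
  rr <- matrix(1:32, 32, 32)
  cc <- matrix(rep(1:32, each = 32), 32, 32)
  blob <- function(c0) exp(-((rr - 16)^2 + (cc - c0)^2) / 18)
  fl <- horn_schunck(blob(14), blob(15), flow_params(0.15, 200))
  supp <- blob(14) > 0.1
  expect_gte(mean(fl[, , 1][supp]), 0.5)
  expect_lte(mean(fl[, , 1][supp]), 1.5)
  expect_lte(abs(mean(fl[, , 2][supp])), 0.25)
})

test_that("flow is deterministic and max|v| decreases as alpha grows", {
  set.seed(4)
  f1 <- matrix(runif(256), 16, 16)
  f2 <- matrix(runif(256), 16, 16)
  a <- horn_schunck(f1, f2, flow_params())
  b <- horn_schunck(f1, f2, flow_params())
  expect_identical(a, b)
  maxv <- vapply(c(0.15, 1.5, 15, 150), function(al)
    max(abs(horn_schunck(f1, f2, flow_params(al, 32)))), numeric(1))
  expect_true(all(diff(maxv) < 0))
})

test_that("flow_sequence returns n-1 fields and zero flow for static input", {
  f <- matrix(0.5, 16, 16)
  frames <- list(f, f, f)
  rois <- rep(list(roi(1, 1, 16, 16)), 3)
  fl <- flow_sequence(frames, rois)
  expect_length(fl, 2)
  expect_true(all(vapply(fl, function(x) all(x == 0), logical(1))))
  expect_error(flow_sequence(frames[1], rois[1]), "at least 2")
})

test_that("exhale bursts dominate the inter-breath flow baseline", {
  sim <- simulate_sequence(sim_config(duration_s = 10.04, seed = 5,
                                      breaths_per_min = 12,
                                      drift_mode = "none"))
  np <- estimate_norm_params(sim$seq$frames[[1]], sim$truth$roi,
                             sim$truth$bg_roi)
  rois <- track_sequence(sim$seq, sim$truth$roi, np$tracking)
  frames <- lapply(sim$seq$frames, normalize_frame, params = np$exhale,
                   mode = "exhale")
  trk0 <- normalize_frame(sim$seq$frames[[1]], np$tracking, "tracking")
  mask <- make_face_mask(crop_roi(trk0, rois[[1]]))
  fields <- flow_sequence(frames, rois, flow_params(), mask = mask)
  mags <- vapply(fields, reduce_field, numeric(1))
  em <- sim$truth$emission[-1]
  # compare the strongest emission frames with the quiet late-gap frames
  # (the plume needs a moment to dissipate after each burst)
  k <- 0.92^(0:40)
  lingering <- as.numeric(stats::filter(em, k, method = "convolution",
                                        sides = 1))
  lingering[is.na(lingering)] <- 0
  peak <- mean(mags[em > 0.5 * max(em)])
  base <- mean(mags[lingering < 0.01 * max(lingering)])
  expect_gt(peak, 5 * base)
})
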