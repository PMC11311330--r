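test_that("raw sequence files round-trip bit-exactly", {
  set.seed(1)
  frames <- lapply(1:3, function(i)
    matrix(sample.int(65536, 4 * 5, replace = TRUE) - 1L, 4, 5))
  seq <- thermal_sequence(frames, fps = 25)
  p <- withr::local_tempfile(fileext = ".bin")
  write_sequence(seq, p)
  expect_identical(file.size(p), 3 * 4 * 5 * 2)
  back <- read_sequence(p, 4, 5)
  expect_identical(back$frames, seq$frames)
  # byte-identical re-write
  p2 <- withr::local_tempfile(fileext = ".bin")
  write_sequence(back, p2)
  expect_identical(readBin(p, "raw", file.size(p)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("frame count follows file size and zero bytes give zero counts", {
  p <- withr::local_tempfile(fileext = ".bin")
  writeBin(raw(2 * 4 * 4 * 2), p)
  seq <- read_sequence(p, 4, 4)
  expect_length(seq$frames, 2)
  expect_true(all(vapply(seq$frames, max, numeric(1)) == 0))
  expect_error(read_sequence(p, 3, 5), "malformed")
  expect_error(read_sequence(p, -4, 4), "positive")
})

test_that("big-endian reading honours the endian flag", {
  p <- withr::local_tempfile(fileext = ".bin")
  # one 1x1 frame with count 258 = 0x0102
  writeBin(as.raw(c(0x01, 0x02)), p)
  expect_equal(read_sequence(p, 1, 1, endian = "big")$frames[[1]][1, 1], 258)
  expect_equal(read_sequence(p, 1, 1, endian = "little")$frames[[1]][1, 1],
               513)
})

test_that("ambient estimation is a median, robust to hot pixels", {
  fr <- matrix(5000, 10, 10)
  r <- roi(1, 1, 10, 10)
  expect_equal(estimate_ambient(fr, r), 5000)
  fr[1, 1] <- 9000
  fr[2, 2] <- 9000
  expect_equal(estimate_ambient(fr, r), 5000)
  expect_equal(estimate_ambient(matrix(c(5000, 5000, 9000), 1, 3),
                                roi(1, 1, 1, 3)), 5000)
  expect_error(estimate_ambient(fr, roi(8, 8, 10, 10)), "inside")
})

test_that("ambient estimate recovers the generator's background level", {
  sim <- simulate_sequence(sim_config(duration_s = 0.5, seed = 2,
                                      plume = list(emission_amplitude = 0),
                                      noise_sd = 20))
  ac <- estimate_ambient(sim$seq$frames[[1]], sim$truth$bg_roi)
  expect_gte(ac, 5900)
  expect_lte(ac, 6100)
})

test_that("normalization maps the stated interval to [0,1] with clamping", {
  np <- norm_params(Fc = 9000, Ac = 5000, Imax = 20000)
  fr <- matrix(c(5000, 9000, 7000, 4000, 12000, 65535), 2, 3)
  ex <- normalize_frame(fr, np, "exhale")
  expect_equal(ex[1, 1], 0)
  expect_equal(ex[2, 1], 1)
  expect_equal(ex[1, 2], 0.5)
  expect_equal(ex[2, 2], 0)       # below Ac clamps to 0
  expect_equal(ex[1, 3], 1)       # above Fc clamps to 1
  tr <- normalize_frame(fr, np, "tracking")
  expect_equal(tr[1, 1], 0)       # below Fc clamps
  expect_equal(tr[2, 3], 1)       # at Imax... above clamps
  expect_equal(tr[1, 3], (12000 - 9000) / 11000)
})

test_that("normalization is monotone and bounded for both modes", {
  np <- norm_params(Fc = 8800, Ac = 6000, Imax = 10000)
  x <- matrix(sort(runif(64, 0, 65535)), 1)
  for (mode in c("exhale", "tracking")) {
    y <- normalize_frame(x, np, mode)
    expect_true(all(diff(as.numeric(y)) >= 0))
    expect_true(all(y >= 0 & y <= 1))
  }
})

test_that("degenerate normalization ranges are rejected", {
  expect_error(norm_params(Fc = 5000, Ac = 5000), "Ac < Fc")
  np <- norm_params(Fc = 9000, Ac = 5000, Imax = 9000)
  expect_error(normalize_frame(matrix(0, 2, 2), np, "tracking"),
               "degenerate")
})

test_that("estimate_face_count tracks the upper face quantile", {
  fr <- matrix(6000, 20, 20)
  fr[5:15, 5:15] <- 8800
  expect_equal(estimate_face_count(fr, roi(5, 5, 11, 11)), 8800)
  np <- estimate_norm_params(fr, roi(5, 5, 11, 11), roi(1, 1, 3, 20))
  expect_true(np$exhale$Ac < np$tracking$Fc)
  expect_true(np$tracking$Fc < np$exhale$Fc)
})
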