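raised_cosine_train <- function(n_pulses, period = 125, width = 40,
                                n = NULL, amp = 1) {
  if (is.null(n)) n <- n_pulses * period
  x <- numeric(n)
  for (k in seq_len(n_pulses)) {
    onset <- round((k - 0.7) * period)
    tt <- seq_len(width)
    idx <- onset + tt
    keep <- idx >= 1 & idx <= n
    x[idx[keep]] <- x[idx[keep]] + amp * 0.5 * (1 - cos(2 * pi * tt[keep] / width))
  }
  x
}

test_that("reduce_field sums magnitudes, equals the loop oracle", {
  expect_equal(reduce_field(array(0, c(4, 4, 2))), 0)
  f <- array(0, c(2, 2, 2)); f[1, 1, ] <- c(3, 4)
  expect_equal(reduce_field(f), 5)
  set.seed(1)
  for (i in 1:5) {
    g <- random_field(7, 5)
    expect_equal(reduce_field(g), oracle_reduce_field(g), tolerance = 1e-9)
  }
})

test_that("reduce_field is invariant under right-angle transforms", {
  set.seed(2)
  f <- random_field(6, 6)
  for (op in c("hflip", "vflip", "rot90", "rot180", "rot270"))
    expect_equal(reduce_field(exhaleflow:::transform_field2(f, op)),
                 reduce_field(f), tolerance = 1e-10)
})

test_that("build_waveform keeps one ordered sample per field", {
  fields <- lapply(1:4, function(i) {
    f <- array(0, c(3, 3, 2)); f[1, 1, 1] <- i; f })
  w <- build_waveform(fields, fps = 25)
  expect_length(w, 4)
  expect_equal(w$samples, 1:4)
  expect_error(build_waveform(list()), "at least one")
  z <- build_waveform(lapply(1:3, function(i) array(0, c(2, 2, 2))))
  expect_true(all(z$samples == 0))
})

test_that("filtering removes outlier spikes and min-max normalizes", {
  set.seed(3)
  base <- 10 + sin(seq(0, 4 * pi, length.out = 50)) + rnorm(50, sd = 0.05)
  spiked <- base
  spiked[25] <- 100
  w <- filter_waveform(exhale_waveform(spiked, fps = 25))
  expect_equal(min(w$samples), 0)
  expect_equal(max(w$samples), 1)
  expect_lt(w$samples[25], 0.5)
  expect_identical(w$processing,
                   c("outlier_removal", "savitzky_golay", "minmax"))
  # constant input degenerates to zeros with a flag
  cst <- filter_waveform(exhale_waveform(rep(2, 20)))
  expect_true(all(cst$samples == 0))
  expect_true(attr(cst, "degenerate"))
  expect_error(filter_waveform(exhale_waveform(1:5)), "at least")
})

test_that("segmentation counts raised-cosine pulses and resamples to 256", {
  x <- raised_cosine_train(8)
  w <- filter_waveform(exhale_waveform(x, fps = 25))
  segs <- segment_exhales(w)
  expect_length(segs, 8)
  expect_true(all(vapply(segs, function(s) length(s$values), numeric(1)) == 256))
  bounds <- t(vapply(segs, `[[`, integer(2), "source_bounds"))
  expect_true(all(diff(bounds[, 1]) > 0))
  expect_true(all(bounds[, 2] >= bounds[, 1]))
  # non-overlap: each segment ends where the next begins
  expect_true(all(bounds[-1, 1] == bounds[-nrow(bounds), 2]))
})

test_that("a monotone ramp contains no exhale", {
  w <- exhale_waveform(seq(0, 1, length.out = 100))
  w$processing <- "minmax"
  expect_length(segment_exhales(w), 0)
})

test_that("breathing rate is recovered within 1/min across the 6-18 range", {
  for (rate in c(6, 12, 18)) {
    period <- round(60 / rate * 25)
    n <- 60 * 25                     # one minute at 25 fps
    set.seed(rate)
    x <- raised_cosine_train(rate, period = period, width = round(period / 3),
                             n = n) + rnorm(n, sd = 0.02)
    w <- filter_waveform(exhale_waveform(x, fps = 25))
    segs <- segment_exhales(w)
    expect_lte(abs(breathing_rate(w, segs) - rate), 1)
  }
})

test_that("segment resampling is exact for linear signals", {
  v <- exhaleflow:::resample_segment(seq(0, 1, length.out = 100))
  expect_length(v, 256)
  expect_equal(v, seq(0, 1, length.out = 256), tolerance = 1e-12)
})
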