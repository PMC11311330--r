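test_that("the breathing schedule pulses at the configured rate", {
  cfg <- sim_config(duration_s = 60, breaths_per_min = 12, seed = 1)
  sch <- simulate_breathing_schedule(cfg)
  expect_length(sch$emission, 1500)
  expect_gte(length(sch$onsets), 11)
  expect_lte(length(sch$onsets), 13)
  expect_true(all(sch$labels == "normal"))
  # zero emission between pulses: a sizable fraction of samples is exactly 0
  expect_gt(mean(sch$emission == 0), 0.3)
  expect_true(all(sch$emission >= 0))
})

test_that("anomalous exhales are planted at the configured fraction", {
  cfg <- sim_config(duration_s = 60, breaths_per_min = 12,
                    anomaly_fraction = 0.5, seed = 2)
  sch <- simulate_breathing_schedule(cfg)
  expect_equal(sum(sch$labels == "anomalous"),
               round(0.5 * length(sch$labels)))
})

test_that("simulation is bitwise deterministic per seed", {
  cfg <- sim_config(duration_s = 0.4, seed = 33)
  a <- simulate_sequence(cfg)
  b <- simulate_sequence(cfg)
  expect_identical(a$seq$frames, b$seq$frames)
  expect_identical(a$truth$emission, b$truth$emission)
  c2 <- simulate_sequence(sim_config(duration_s = 0.4, seed = 34))
  expect_false(identical(a$seq$frames[[1]], c2$seq$frames[[1]]))
})

test_that("frame count and count levels respect the configuration", {
  cfg <- sim_config(duration_s = 1.2, seed = 3,
                    plume = list(emission_amplitude = 0))
  sim <- simulate_sequence(cfg)
  expect_length(sim$seq$frames, round(1.2 * 25))
  f <- sim$seq$frames[[10]]
  bg <- crop_roi(f, sim$truth$bg_roi)
  # ambient region sits at ambient_count within the noise band
  expect_lt(abs(mean(bg) - 6000), 6 * 15)
  expect_true(all(abs(bg - 6000) < 8 * 15))
  # face region is warmer than ambient
  face <- crop_roi(f, sim$truth$roi)
  expect_gt(max(face), 8000)
})

test_that("zero emission leaves the scene at ambient outside the face", {
  # with room-air shimmer disabled, only sensor noise remains
  cfg <- sim_config(duration_s = 0.4, seed = 5, drift_mode = "none",
                    plume = list(emission_amplitude = 0),
                    ambient_air = list(amplitude = 0))
  sim <- simulate_sequence(cfg)
  tmpl_mask <- sim$seq$frames[[1]] > 6000 + 6 * 15
  for (f in sim$seq$frames[c(1, 5, 10)]) {
    out <- f[!tmpl_mask]
    expect_true(all(abs(out - 6000) <= 8 * 15))
  }
  # with shimmer on, deviations stay within the combined fluctuation band
  cfg2 <- sim_config(duration_s = 0.2, seed = 5, drift_mode = "none",
                     plume = list(emission_amplitude = 0))
  sim2 <- simulate_sequence(cfg2)
  out2 <- sim2$seq$frames[[3]][!tmpl_mask]
  expect_lt(max(abs(out2 - 6000)), 8 * sqrt(15^2 + 20^2))
  expect_lt(abs(mean(out2) - 6000), 30)
})

test_that("cohorts draw distinct per-subject parameters and waveforms", {
  cfg <- sim_config(duration_s = 2, seed = 11)
  cohort <- make_cohort(cfg, n_subjects = 3)
  expect_length(cohort, 3)
  rates <- vapply(cohort, function(s) s$subject$rate, numeric(1))
  expect_gt(max(rates) - min(rates), 0)
  f1 <- cohort[[1]]$seq$frames[[1]]
  f2 <- cohort[[2]]$seq$frames[[1]]
  expect_false(identical(f1, f2))
})

test_that("the visible plume lags the emission schedule by dissipation", {
  sim <- simulate_sequence(sim_config(duration_s = 20.04, seed = 9,
                                      drift_mode = "none"))
  em <- sim$truth$emission
  resp <- sim$truth$plume_response
  # the response is the decay-accumulated emission ...
  expect_equal(resp, as.numeric(stats::filter(em, 0.92, method = "recursive")),
               tolerance = 1e-12)
  # ... and the lingering tail decorrelates it from the raw schedule, which
  # is why waveforms are validated against the response series
  expect_lt(cor(em, resp), 0.8)
  expect_gt(cor(em, resp), 0.3)
})

test_that("reference segments are clean templates, anomalies perturbed", {
  refs <- make_reference_segments(5, seed = 1)
  expect_true(all(vapply(refs, function(s) length(s$values), numeric(1)) == 256))
  expect_true(all(vapply(refs, function(s) all(s$values >= 0 & s$values <= 1),
                         logical(1))))
  anom <- make_reference_segments(5, seed = 1, anomalous = TRUE)
  # anomalies have higher peaks (amplitude x U(1.3, 1.8))
  expect_gt(mean(vapply(anom, function(s) max(s$values), numeric(1))),
            mean(vapply(refs, function(s) max(s$values), numeric(1))))
  # determinism
  expect_identical(make_reference_segments(3, seed = 2)[[1]]$values,
                   make_reference_segments(3, seed = 2)[[1]]$values)
})
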