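#' Simulation configuration for synthetic thermal sequences
#'
#' The simulator emulates the statistical structure the pipeline assumes
#' from clinical recordings: ambient background counts with sensor noise, a
#' warmer face region with trackable texture and slow drift on the left of
#' the frame, and a turbulent exhale plume emitted rightward in episodes
#' that decay by dissipation. Default counts follow the typical indoor
#' 5000-9000 range; the default desk-scale frame is 128x160 (full-size
#' 512x640 generation is available by overriding `h`, `w`).
#'
#' @param h,w frame size in pixels.
#' @param fps frame rate (default 25).
#' @param duration_s recording length in seconds.
#' @param ambient_count mean background count (default 6000).
#' @param face_count face-region count level (default 8800).
#' @param noise_sd per-pixel Gaussian count noise SD (default 15).
#' @param breaths_per_min exhale rate (default 12).
#' @param drift_speed RMS face drift in px/frame (default 0.15).
#' @param drift_mode `"walk"` (seeded smooth random walk), `"linear_right"`
#'   (constant rightward drift at `drift_speed`), or `"none"`.
#' @param plume list: `emission_amplitude`, `diffusion` (Gaussian sigma in
#'   px/frame), `advection` (`c(drow, dcol)` px/frame), `decay`
#'   (multiplicative per frame), `turbulence` (RMS of the per-frame
#'   divergence-free curl-noise velocity perturbation, px/frame) and
#'   `turbulence_scale` (its spatial correlation scale in px).
#' @param ambient_air list describing general room-air movement -- the
#'   faint drifting warm-air shimmer open environments always carry, which
#'   the pipeline must separate exhale flow from: `amplitude` (RMS count
#'   contrast of the shimmer texture), `scale` (spatial correlation, px),
#'   `speed` (RMS drift, px/frame). Set `amplitude = 0` to disable.
#' @param anomaly_fraction fraction of exhales given anomalous
#'   amplitude/duration perturbations.
#' @param seed integer seed; every stage is deterministic per seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(h = 128, w = 160, fps = 25, duration_s = 20,
                       ambient_count = 6000, face_count = 8800,
                       noise_sd = 15, breaths_per_min = 12,
                       drift_speed = 0.15, drift_mode = "walk",
                       plume = list(), ambient_air = list(),
                       anomaly_fraction = 0, seed = 1) {
  if (anomaly_fraction < 0 || anomaly_fraction > 1)
    stop("anomaly_fraction must be in [0, 1]")
  if (ambient_count >= face_count)
    stop("ambient_count must be below face_count")
  pl <- utils::modifyList(
    list(emission_amplitude = 1, diffusion = 0.7, advection = c(0, 1.5),
         decay = 0.92, turbulence = 0.4, turbulence_scale = 8), plume)
  air <- utils::modifyList(
    list(amplitude = 20, scale = 5, speed = 0.8), ambient_air)
  structure(list(h = as.integer(h), w = as.integer(w), fps = fps,
                 duration_s = duration_s, ambient_count = ambient_count,
                 face_count = face_count, noise_sd = noise_sd,
                 breaths_per_min = breaths_per_min,
                 drift_speed = drift_speed, drift_mode = drift_mode,
                 plume = pl, ambient_air = air,
                 anomaly_fraction = anomaly_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the exhale emission schedule
#'
#' Episodic pulses at the configured rate: raised-cosine rise followed by an
#' exponential decay, with jittered onsets and amplitudes, and exactly zero
#' emission between exhales. A seeded subset of exhales (per
#' `anomaly_fraction`) is perturbed with amplitude x U(1.3, 1.8) and
#' duration x U(0.5, 0.7).
#'
#' @param config a [sim_config()].
#' @return list with `emission` (per-frame emission rate, length =
#'   `round(duration_s * fps)`), `labels` (per-exhale `"normal"` /
#'   `"anomalous"`) and `onsets` (frame index of each exhale start).
#' @export
simulate_breathing_schedule <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$breaths_per_min <= 0) stop("breaths_per_min must be > 0")
  n <- round(config$duration_s * config$fps)
  with_seed(config$seed + 17L, {
    period <- 60 / config$breaths_per_min * config$fps   # frames
    n_breaths <- floor(n / period)
    emission <- numeric(n)
    onsets <- integer(0)
    labels <- character(0)
    n_anom <- round(config$anomaly_fraction * n_breaths)
    anom_idx <- if (n_anom > 0) sample.int(n_breaths, n_anom) else integer(0)
    for (k in seq_len(n_breaths)) {
      onset <- round((k - 1) * period + 0.08 * period +
                     stats::runif(1, -0.08, 0.08) * period) + 1L
      amp <- config$plume$emission_amplitude * stats::runif(1, 0.85, 1.15)
      rise <- 0.4 * config$fps
      tau <- 0.4 * config$fps
      dur <- min(1.6 * config$fps, 0.85 * period)
      if (k %in% anom_idx) {
        amp <- amp * stats::runif(1, 1.3, 1.8)
        scale <- stats::runif(1, 0.5, 0.7)
        rise <- rise * scale; tau <- tau * scale; dur <- dur * scale
      }
      tt <- seq_len(round(dur))
      pulse <- ifelse(tt <= rise,
                      0.5 * (1 - cos(pi * tt / rise)),
                      exp(-(tt - rise) / tau))
      idx <- onset + tt - 1L
      keep <- idx >= 1L & idx <= n
      emission[idx[keep]] <- emission[idx[keep]] + amp * pulse[keep]
      if (any(keep)) {
        onsets <- c(onsets, onset)
        labels <- c(labels, if (k %in% anom_idx) "anomalous" else "normal")
      }
    }
    list(emission = emission, labels = labels, onsets = onsets)
  })
}

# Smooth seeded random series: white noise smoothed with a Gaussian kernel
# and rescaled to the requested RMS.
smooth_noise_series <- function(n, rms, smooth_sd = 12) {
  if (rms <= 0 || n < 2) return(numeric(n))
  r3 <- 3L * ceiling(smooth_sd)
  x <- stats::rnorm(n + 2L * r3 + 2L)
  k <- exp(-((-r3):r3)^2 / (2 * smooth_sd^2))
  k <- k / sum(k)
  s <- stats::filter(x, k, sides = 2)
  s <- s[!is.na(s)]
  s <- s[seq_len(n)]
  s <- s - mean(s)
  r <- sqrt(mean(s^2))
  if (r == 0) numeric(n) else s * (rms / r)
}

# Static face template: profile view -- an elliptical head with a warm
# nose/mouth protrusion toward the nozzle, smooth skin texture and hot
# spots (nostril/lip features), in counts above ambient.
face_template <- function(config) {
  h <- config$h; w <- config$w
  rc <- h / 2; cc <- 0.28 * w
  rr <- matrix(seq_len(h), h, w)
  cw <- matrix(rep(seq_len(w), each = h), h, w)
  d2 <- ((rr - rc) / (0.34 * h))^2 + ((cw - cc) / (0.20 * w))^2
  body <- pmax(0, 1 - d2)
  d2p <- ((rr - rc) / (0.13 * h))^2 + ((cw - (cc + 0.14 * w)) / (0.10 * w))^2
  body <- pmax(body, pmax(0, 1 - d2p))      # nose/mouth protrusion
  mask <- body > 0
  level <- config$face_count - config$ambient_count
  tex <- gauss_blur(matrix(stats::rnorm(h * w), h, w), 1.4)
  tex <- tex / max(abs(tex)) * 0.08 * level
  face <- (0.90 * level + tex) * sqrt(body)
  # hot spots over the face with a cluster on the nose/mouth protrusion:
  # corner-like features the tracker locks onto
  bumps <- rbind(
    cbind(stats::runif(8, -0.26, 0.26) * h + rc,
          stats::runif(8, -0.02, 0.10) * w + cc),
    cbind(stats::runif(6, -0.09, 0.09) * h + rc,
          stats::runif(6, 0.10, 0.21) * w + cc))
  for (i in seq_len(nrow(bumps))) {
    amp <- stats::runif(1, 0.06, 0.13) * level
    face <- face + amp *
      exp(-(((rr - bumps[i, 1L]) / 2.2)^2 + ((cw - bumps[i, 2L]) / 2.2)^2) / 2) * mask
  }
  list(face = face, mask = mask,
       nozzle = c(round(rc), round(cc + 0.23 * w)))
}

#' Simulate a thermal exhale sequence with ground truth
#'
#' Per frame the plume scalar field is advected semi-Lagrangian along the
#' configured velocity plus a seeded smooth turbulent perturbation, diffused
#' with a Gaussian kernel, multiplied by the dissipation decay, and fed by
#' emission injected at a nozzle on the face's right (mouth) edge. Counts
#' are rendered as ambient + plume + drifting face + Gaussian sensor noise,
#' clipped to the 16-bit range. Identical seeds give bitwise-identical
#' output.
#'
#' @param config a [sim_config()].
#' @return list with `seq` (a [thermal_sequence]) and `truth`: ground-truth
#'   `emission` series, `plume_response` (emission accumulated under the
#'   dissipation decay: the series the imaged flow should track, since the
#'   camera sees the lingering plume rather than the instantaneous emission
#'   rate), per-exhale `labels` and `onsets`, `face_trajectory`
#'   (n x 2 sub-pixel face offsets), `roi` (suggested nose-mouth tracking
#'   [roi()]), `bg_roi` (clean background region), `nozzle` (base position),
#'   and `plume_velocity` (per-frame mean advection actually applied).
#' @export
simulate_sequence <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  sched <- simulate_breathing_schedule(config)
  n <- length(sched$emission)
  h <- config$h; w <- config$w
  with_seed(config$seed, {
    tmpl <- face_template(config)
    # face drift
    drift <- switch(config$drift_mode,
      none = matrix(0, n, 2),
      linear_right = cbind(rep(0, n), (seq_len(n) - 1L) * config$drift_speed),
      walk = {
        sr <- cumsum(smooth_noise_series(n, config$drift_speed))
        sc <- cumsum(smooth_noise_series(n, config$drift_speed))
        cbind(sr - sr[1L], sc - sc[1L])
      },
      stop("unknown drift_mode: ", config$drift_mode))
    max_dr <- 0.08 * h; max_dc <- 0.08 * w
    drift[, 1L] <- pmin(pmax(drift[, 1L], -max_dr), max_dr)
    drift[, 2L] <- pmin(pmax(drift[, 2L], -max_dc), max_dc)
    pl <- config$plume
    air <- config$ambient_air
    plume <- matrix(0, h, w)
    rr <- matrix(seq_len(h), h, w)
    cw <- matrix(rep(seq_len(w), each = h), h, w)
    level <- config$face_count - config$ambient_count
    # room-air shimmer: a large periodic-ish texture translated by a
    # bounded random walk, so general air movement is always present
    air_margin <- 40L
    if (air$amplitude > 0) {
      air_tex <- gauss_blur(matrix(stats::rnorm((h + 2L * air_margin) *
                                                  (w + 2L * air_margin)),
                                   h + 2L * air_margin, w + 2L * air_margin),
                            air$scale)
      air_tex <- air_tex / sqrt(mean(air_tex^2)) * air$amplitude
      air_vr <- smooth_noise_series(n, air$speed, smooth_sd = 3)
      air_vc <- smooth_noise_series(n, air$speed, smooth_sd = 3)
      air_or <- pmin(pmax(cumsum(air_vr), -air_margin + 1), air_margin - 1)
      air_oc <- pmin(pmax(cumsum(air_vc), -air_margin + 1), air_margin - 1)
    }
    frames <- vector("list", n)
    vel_hist <- matrix(0, n, 2)
    for (t in seq_len(n)) {
      turb <- curl_noise_field(h, w, pl$turbulence, pl$turbulence_scale)
      vr <- pl$advection[1L] + turb$vr
      vc <- pl$advection[2L] + turb$vc
      vel_hist[t, ] <- c(mean(vr), mean(vc))
      plume <- advect_field(plume, vr, vc)
      plume <- gauss_blur(plume, pl$diffusion)
      plume <- plume * pl$decay
      if (sched$emission[t] > 0) {
        nz <- tmpl$nozzle + drift[t, ]
        blob <- exp(-(((rr - nz[1L]) / 1.8)^2 + ((cw - nz[2L]) / 1.8)^2) / 2)
        plume <- plume + sched$emission[t] * blob
      }
      face_t <- shift_bilinear(tmpl$face, drift[t, 1L], drift[t, 2L])
      counts <- config$ambient_count + face_t +
        0.55 * level * pmin(plume, 1.5) +
        matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w)
      if (air$amplitude > 0) {
        sl_r <- (air_margin + 1L):(air_margin + h) - air_or[t]
        sl_c <- (air_margin + 1L):(air_margin + w) - air_oc[t]
        counts <- counts +
          matrix(bilinear_sample(air_tex,
                                 matrix(sl_r, h, w),
                                 matrix(rep(sl_c, each = h), h, w)), h, w)
      }
      counts <- round(pmin(pmax(counts, 0), 65535))
      frames[[t]] <- matrix(as.integer(counts), h, w)
    }
    # expected visible-plume series: emission accumulated under the
    # per-frame dissipation decay (the camera sees the lingering plume,
    # not the instantaneous emission rate)
    resp <- as.numeric(stats::filter(sched$emission, pl$decay,
                                     method = "recursive"))
    nz <- tmpl$nozzle
    roi_size <- 64L
    r0 <- as.integer(max(1, min(nz[1L] - roi_size / 2, h - roi_size + 1)))
    c0 <- as.integer(max(1, min(nz[2L] - round(0.45 * roi_size), w - roi_size + 1)))
    truth <- list(emission = sched$emission, plume_response = resp,
                  labels = sched$labels,
                  onsets = sched$onsets, face_trajectory = drift,
                  roi = roi(r0, c0, roi_size, roi_size),
                  bg_roi = roi(2L, as.integer(round(0.62 * w)), 14L, 30L),
                  nozzle = nz, plume_velocity = vel_hist)
    list(seq = thermal_sequence(frames, fps = config$fps), truth = truth)
  })
}

#' Simulate a cohort of subjects
#'
#' Per-subject parameters (breathing rate, emission amplitude, advection,
#' drift) are drawn from seeded distributions so waveform signatures differ
#' across subjects; each subject gets a distinct seed derived from the
#' cohort seed.
#'
#' @param config base [sim_config()].
#' @param n_subjects number of subjects, >= 1.
#' @return list of `n_subjects` results of [simulate_sequence()], each with
#'   an added `subject` element recording the drawn parameters.
#' @export
make_cohort <- function(config = sim_config(), n_subjects = 5) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  draws <- with_seed(config$seed + 99L, {
    data.frame(rate = stats::runif(n_subjects, 9, 15),
               amp = stats::runif(n_subjects, 0.85, 1.25),
               adv = stats::runif(n_subjects, 1.1, 1.9),
               drift = stats::runif(n_subjects, 0.05, 0.25))
  })
  out <- vector("list", n_subjects)
  for (k in seq_len(n_subjects)) {
    cfg <- config
    cfg$breaths_per_min <- draws$rate[k]
    cfg$plume$emission_amplitude <- config$plume$emission_amplitude * draws$amp[k]
    cfg$plume$advection <- c(config$plume$advection[1L], draws$adv[k])
    cfg$drift_speed <- draws$drift[k]
    cfg$seed <- config$seed + 1000L * k
    out[[k]] <- simulate_sequence(cfg)
    out[[k]]$subject <- as.list(draws[k, ])
  }
  out
}

#' Clean and perturbed template exhale segments
#'
#' Generates idealized length-256 exhale shapes (raised-cosine rise, then
#' exponential decay) with mild seeded jitter; `anomalous = TRUE` applies
#' the same amplitude x U(1.3, 1.8) and duration x U(0.5, 0.7) perturbations
#' the simulator plants, plus the same additive noise. Used as the
#' synthetic reference/input sets of the anomaly model.
#'
#' @param n number of segments.
#' @param seed integer seed.
#' @param anomalous generate perturbed segments.
#' @param noise_sd additive Gaussian noise SD (default 0.02).
#' @return list of [exhale_segment()]s.
#' @export
make_reference_segments <- function(n, seed = 1, anomalous = FALSE,
                                    noise_sd = 0.02) {
  with_seed(seed + 7L * anomalous, {
    lapply(seq_len(n), function(i) {
      amp <- stats::runif(1, 0.55, 0.7)
      rise_frac <- stats::runif(1, 0.24, 0.3)
      tau_frac <- stats::runif(1, 0.22, 0.28)
      dur <- 1
      if (anomalous) {
        amp <- amp * stats::runif(1, 1.3, 1.8)
        dur <- stats::runif(1, 0.5, 0.7)
      }
      tt <- seq(0, 1, length.out = 256L) / dur
      rise <- rise_frac
      v <- ifelse(tt <= rise, 0.5 * (1 - cos(pi * tt / rise)),
                  exp(-(tt - rise) / tau_frac))
      v[tt > 1] <- 0
      v <- amp * v + stats::rnorm(256L, 0, noise_sd)
      exhale_segment(pmin(pmax(v, 0), 1))
    })
  })
}
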