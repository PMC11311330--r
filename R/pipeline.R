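#' Pipeline configuration
#'
#' Builds the nested configuration consumed by [run_pipeline()]. Values are
#' merged over defaults; a YAML file with the same nesting can be loaded
#' with `pipeline_config(yaml = "config.yml")`. All randomness flows from
#' the single root `seed`, split per stage.
#'
#' @param yaml optional path to a YAML file whose entries override defaults.
#' @param ... named overrides (e.g. `simulate = list(duration_s = 30)`).
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(yaml = NULL, ...) {
  defaults <- list(
    outdir = "exhaleflow_out",
    seed = 1,
    raw = list(path = NULL, height = 128, width = 160, endian = "little",
               fps = 25),
    simulate = list(duration_s = 20, breaths_per_min = 12,
                    anomaly_fraction = 0.25),
    roi = NULL,                       # c(row0, col0, height, width)
    bg_roi = NULL,
    flow = list(alpha = 0.15, n_iter = 64),
    mask = list(threshold = 0.05, dilate = 4),
    fieldnet = list(base_channels = 16, epochs = 4, batch_size = 8,
                    learning_rate = 1e-3, dropout = 0.025,
                    train_fraction = 0.9, max_items = NULL,
                    augment_ops = c("hflip", "vflip", "rot180")),
    segment = list(min_separation = 2, min_prominence = 0.1),
    anomaly = list(epochs = 30, autoencoder_epochs = 30, n_refs = 20,
                   use_autoencoder = TRUE)
  )
  cfg <- defaults
  if (!is.null(yaml)) cfg <- utils::modifyList(cfg, yaml::read_yaml(yaml))
  cfg <- utils::modifyList(cfg, list(...))
  class(cfg) <- "pipeline_config"
  cfg
}

stage_path <- function(cfg, name) file.path(cfg$outdir, name)

need_artifact <- function(cfg, name, producer) {
  p <- stage_path(cfg, name)
  if (!file.exists(p))
    stop(sprintf("missing artifact '%s': run the '%s' subcommand first",
                 name, producer))
  p
}

write_manifest <- function(cfg, command) {
  man <- list(command = command, seed = cfg$seed,
              config = unclass(cfg),
              r_version = as.character(getRversion()),
              package_version = as.character(utils::packageVersion("exhaleflow")),
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(man, stage_path(cfg, paste0("manifest_", command, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run a pipeline stage
#'
#' Subcommands mirror the processing chain: `simulate` writes a synthetic
#' raw recording; `track` tracks the nose-mouth ROI; `flow` computes masked,
#' shift-compensated flow fields; `collate` builds the interleaved encoded
#' dataset; `train-fieldnet` fits the interpolation model; `predict` runs it
#' over the sequence; `waveform` reduces raw and predicted fields to
#' filtered waveforms; `segment` extracts fixed-length exhale episodes;
#' `train-anomaly` fits the denoiser and anomaly scorer on synthetic
#' reference shapes plus the recording's own segments; `score` scores every
#' segment; `all` chains every stage in order. Each stage writes its
#' artifacts plus a manifest (config, seed, versions) into `cfg$outdir`.
#'
#' @param command one of `"simulate"`, `"track"`, `"flow"`, `"collate"`,
#'   `"train-fieldnet"`, `"predict"`, `"waveform"`, `"segment"`,
#'   `"train-anomaly"`, `"score"`, `"all"`.
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list of the stage's main outputs.
#' @export
run_pipeline <- function(command, cfg = pipeline_config()) {
  command <- match.arg(command, c("simulate", "track", "flow", "collate",
                                  "train-fieldnet", "predict", "waveform",
                                  "segment", "train-anomaly", "score", "all"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  if (command == "all") {
    for (cmd in c("simulate", "track", "flow", "collate", "train-fieldnet",
                  "predict", "waveform", "segment", "train-anomaly", "score"))
      run_pipeline(cmd, cfg)
    return(invisible(NULL))
  }
  out <- switch(command,
    simulate = stage_simulate(cfg),
    track = stage_track(cfg),
    flow = stage_flow(cfg),
    collate = stage_collate(cfg),
    `train-fieldnet` = stage_train_fieldnet(cfg),
    predict = stage_predict(cfg),
    waveform = stage_waveform(cfg),
    segment = stage_segment(cfg),
    `train-anomaly` = stage_train_anomaly(cfg),
    score = stage_score(cfg))
  write_manifest(cfg, command)
  invisible(out)
}

stage_simulate <- function(cfg) {
  sc <- do.call(sim_config, c(cfg$simulate,
                              list(h = cfg$raw$height, w = cfg$raw$width,
                                   fps = cfg$raw$fps, seed = cfg$seed)))
  sim <- simulate_sequence(sc)
  write_sequence(sim$seq, stage_path(cfg, "sequence.bin"),
                 endian = cfg$raw$endian)
  tr <- sim$truth
  jsonlite::write_json(
    list(emission = tr$emission, labels = tr$labels, onsets = tr$onsets,
         face_trajectory = tr$face_trajectory, nozzle = tr$nozzle,
         roi = unclass(tr$roi), bg_roi = unclass(tr$bg_roi)),
    stage_path(cfg, "truth.json"), auto_unbox = FALSE, digits = NA)
  sim
}

read_input_sequence <- function(cfg) {
  path <- if (!is.null(cfg$raw$path)) cfg$raw$path
          else need_artifact(cfg, "sequence.bin", "simulate")
  read_sequence(path, cfg$raw$height, cfg$raw$width,
                endian = cfg$raw$endian, fps = cfg$raw$fps)
}

pipeline_rois <- function(cfg) {
  if (!is.null(cfg$roi)) {
    r <- cfg$roi
    list(roi = roi(r[1], r[2], r[3], r[4]),
         bg = if (!is.null(cfg$bg_roi))
                roi(cfg$bg_roi[1], cfg$bg_roi[2], cfg$bg_roi[3], cfg$bg_roi[4])
              else NULL)
  } else {
    tj <- jsonlite::read_json(need_artifact(cfg, "truth.json", "simulate"),
                              simplifyVector = TRUE)
    list(roi = roi(tj$roi$row0, tj$roi$col0, tj$roi$height, tj$roi$width),
         bg = roi(tj$bg_roi$row0, tj$bg_roi$col0, tj$bg_roi$height,
                  tj$bg_roi$width))
  }
}

stage_track <- function(cfg) {
  seq <- read_input_sequence(cfg)
  rr <- pipeline_rois(cfg)
  np <- estimate_norm_params(seq$frames[[1L]], rr$roi, rr$bg)
  rois <- track_sequence(seq, rr$roi, np$tracking)
  traj <- data.frame(frame_index = seq_along(rois) - 1L,
                     row0 = vapply(rois, `[[`, integer(1), "row0"),
                     col0 = vapply(rois, `[[`, integer(1), "col0"),
                     height = rr$roi$height, width = rr$roi$width,
                     flag = attr(rois, "flags"))
  utils::write.csv(traj, stage_path(cfg, "trajectory.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(np, unclass), stage_path(cfg, "norm_params.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(rois, stage_path(cfg, "rois.rds"))
  list(rois = rois, params = np)
}

stage_flow <- function(cfg) {
  seq <- read_input_sequence(cfg)
  rois <- readRDS(need_artifact(cfg, "rois.rds", "track"))
  pj <- jsonlite::read_json(need_artifact(cfg, "norm_params.json", "track"),
                            simplifyVector = TRUE)
  params <- norm_params(pj$exhale$Fc, pj$exhale$Ac, pj$exhale$Imax)
  tparams <- norm_params(pj$tracking$Fc, pj$tracking$Ac, pj$tracking$Imax)
  frames <- lapply(seq$frames, normalize_frame, params = params,
                   mode = "exhale")
  trk0 <- normalize_frame(seq$frames[[1L]], tparams, "tracking")
  mask <- make_face_mask(crop_roi(trk0, rois[[1L]]),
                         threshold = cfg$mask$threshold,
                         dilate = cfg$mask$dilate)
  fields <- flow_sequence(frames, rois,
                          flow_params(cfg$flow$alpha, cfg$flow$n_iter),
                          mask = mask)
  saveRDS(list(fields = fields, mask = mask, fps = seq$fps,
               alpha = cfg$flow$alpha, n_iter = cfg$flow$n_iter),
          stage_path(cfg, "fields.rds"))
  list(fields = fields, mask = mask)
}

load_encoded_fields <- function(cfg) {
  fl <- readRDS(need_artifact(cfg, "fields.rds", "flow"))
  n_max <- max(vapply(fl$fields, function(f) max(field_magnitudes(f)),
                      numeric(1)))
  list(encoded = lapply(fl$fields, encode_field, n_max = n_max),
       n_max = n_max, fps = fl$fps, fields = fl$fields)
}

stage_collate <- function(cfg) {
  enc <- load_encoded_fields(cfg)
  ds <- collate_interleaved(enc$encoded)
  saveRDS(list(ds = ds, n_max = enc$n_max), stage_path(cfg, "dataset.rds"))
  list(ds = ds)
}

stage_train_fieldnet <- function(cfg) {
  st <- readRDS(need_artifact(cfg, "dataset.rds", "collate"))
  d <- dim(st$ds$x[[1L]])
  fc <- fieldnet_config(height = d[1L], width = d[2L],
                        base_channels = cfg$fieldnet$base_channels,
                        dropout = cfg$fieldnet$dropout,
                        learning_rate = cfg$fieldnet$learning_rate,
                        batch_size = cfg$fieldnet$batch_size,
                        epochs = cfg$fieldnet$epochs, seed = cfg$seed)
  ds <- st$ds
  mi <- cfg$fieldnet$max_items
  if (!is.null(mi) && length(ds) > mi) {
    keep <- sort(with_seed(cfg$seed + 5L, sample.int(length(ds), mi)))
    ds <- interleaved_dataset(ds$x[keep], ds$y[keep])
  }
  sp <- split_dataset(ds, cfg$fieldnet$train_fraction, seed = cfg$seed)
  # augment after splitting: transformed copies stay on their source's side
  if (length(cfg$fieldnet$augment_ops))
    sp$train <- augment(sp$train, cfg$fieldnet$augment_ops)
  model <- train_fieldnet(build_fieldnet(fc), sp$train, sp$val)
  saveRDS(model, stage_path(cfg, "fieldnet.rds"))
  utils::write.csv(model$history, stage_path(cfg, "fieldnet_history.csv"),
                   row.names = FALSE)
  list(model = model)
}

stage_predict <- function(cfg) {
  model <- readRDS(need_artifact(cfg, "fieldnet.rds", "train-fieldnet"))
  enc <- load_encoded_fields(cfg)
  preds <- predict_sequence(model, enc$encoded)
  saveRDS(list(preds = preds, fps = enc$fps),
          stage_path(cfg, "predicted_fields.rds"))
  list(preds = preds)
}

stage_waveform <- function(cfg) {
  enc <- load_encoded_fields(cfg)
  raw_w <- filter_waveform(build_waveform(enc$fields, fps = enc$fps,
                                          provenance = "raw_optical_flow"))
  out <- data.frame(index = seq_along(raw_w$samples) - 1L,
                    raw = raw_w$samples)
  pred_w <- NULL
  pp <- stage_path(cfg, "predicted_fields.rds")
  if (file.exists(pp)) {
    pr <- readRDS(pp)
    pred_fields <- lapply(pr$preds, decode_field)
    pred_w <- filter_waveform(build_waveform(pred_fields, fps = pr$fps,
                                             provenance = "fieldnet_predicted"))
    # predicted fields cover interior time steps 2..n-1 of the field list
    out$predicted <- c(NA, pred_w$samples, NA)
  }
  utils::write.csv(out, stage_path(cfg, "waveform.csv"), row.names = FALSE)
  saveRDS(list(raw = raw_w, predicted = pred_w),
          stage_path(cfg, "waveforms.rds"))
  list(raw = raw_w, predicted = pred_w)
}

stage_segment <- function(cfg) {
  wf <- readRDS(need_artifact(cfg, "waveforms.rds", "waveform"))
  w <- if (!is.null(wf$predicted)) wf$predicted else wf$raw
  segs <- segment_exhales(w, cfg$segment$min_separation,
                          cfg$segment$min_prominence)
  if (length(segs)) {
    bounds <- t(vapply(segs, `[[`, integer(2), "source_bounds"))
    utils::write.csv(data.frame(segment = seq_along(segs),
                                start = bounds[, 1L], end = bounds[, 2L]),
                     stage_path(cfg, "segments.csv"), row.names = FALSE)
  }
  saveRDS(list(segments = segs, rate = breathing_rate(w, segs)),
          stage_path(cfg, "segments.rds"))
  list(segments = segs)
}

stage_train_anomaly <- function(cfg) {
  st <- readRDS(need_artifact(cfg, "segments.rds", "segment"))
  refs <- make_reference_segments(cfg$anomaly$n_refs, seed = cfg$seed)
  inputs <- c(st$segments,
              make_reference_segments(max(3, length(st$segments) %/% 2),
                                      seed = cfg$seed + 1L, anomalous = TRUE))
  denoiser <- train_autoencoder(c(refs, inputs), seed = cfg$seed,
                                epochs = cfg$anomaly$autoencoder_epochs)
  if (isTRUE(cfg$anomaly$use_autoencoder))
    inputs <- lapply(inputs, function(s) predict(denoiser, s))
  pairs <- build_anomaly_training_set(refs, inputs)
  scorer <- train_anomaly_model(pairs, seed = cfg$seed,
                                epochs = cfg$anomaly$epochs)
  saveRDS(list(denoiser = denoiser, scorer = scorer),
          stage_path(cfg, "anomaly_models.rds"))
  list(denoiser = denoiser, scorer = scorer)
}

stage_score <- function(cfg) {
  models <- readRDS(need_artifact(cfg, "anomaly_models.rds", "train-anomaly"))
  st <- readRDS(need_artifact(cfg, "segments.rds", "segment"))
  segs <- st$segments
  if (isTRUE(cfg$anomaly$use_autoencoder))
    segs <- lapply(segs, function(s) predict(models$denoiser, s))
  scores <- lapply(segs, function(s) score_segment(models$scorer, s))
  df <- data.frame(segment_id = seq_along(scores),
                   summary = vapply(scores, `[[`, numeric(1), "summary"),
                   max_error = vapply(scores, `[[`, numeric(1), "max_error"))
  utils::write.csv(df, stage_path(cfg, "scores.csv"), row.names = FALSE)
  if (length(scores))
    utils::write.csv(
      data.frame(segment_id = rep(seq_along(scores), each = 256L),
                 t = rep(seq_len(256L), length(scores)),
                 error = unlist(lapply(scores, `[[`, "error_waveform"))),
      stage_path(cfg, "score_waveforms.csv"), row.names = FALSE)
  list(scores = df)
}
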