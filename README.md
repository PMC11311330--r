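# exhaleflow

Non-contact expiratory flow measurement from thermal image sequences.

Exhaled air is warm and CO2-rich, so in the mid-wave infrared band (3–5 µm)
every breath is directly visible as a turbulent plume leaving the nose and
mouth. `exhaleflow` turns raw 16-bit thermal *count* recordings of a seated
subject in profile into per-breath expiratory measurements, for researchers
prototyping vision-based respiratory diagnostics: breathing rate, per-exhale
flow waveforms, and reference-based anomaly scores — without tubes,
wearables, or subject effort.

The pipeline:

1. **Raw I/O + dual normalization** — headerless 16-bit binary sequences;
   `[Fc, Imax] → [0,1]` for tracking, `[Ac, Fc] → [0,1]` for exhale
   contrast (`Ac` ambient count, `Fc` face-temperature count).
2. **Nose–mouth ROI tracking** — Shi–Tomasi corners + iterative
   Lucas–Kanade key-point flow against a periodically refreshed anchor
   frame; face masking so facial motion never contaminates the signal.
3. **Dense optical flow** — the Horn–Schunck iterative scheme
   (Sobel derivatives, smoothness weight `α = 0.15`, update denominator
   `α + Ix² + Iy²`), one `(h, w, 2)` field per frame pair.
4. **FieldNet** — a U-Net-style encoder–decoder (tanh everywhere, two skip
   connections) trained to predict the intermediate encoded flow field at
   `t+1` from the fields at `t` and `t+2`; run over a sequence it acts as a
   learned noise filter for the flow. The full-size reference configuration
   has 18.7 million trainable parameters.
5. **Waveform** — each field reduces to `f(t) = Σᵢⱼ |F⃗(i,j)|`; the series
   is outlier-filtered, Savitzky–Golay smoothed (window 9), min–max
   normalized, and segmented into per-exhale episodes resampled to length
   256.
6. **Anomaly model** — a 1-D convolutional autoencoder denoises segments
   and a second 1-D conv net, trained on the full cross product of
   reference and input segments with target `e(t) = |ref(t) − input(t)|`,
   predicts each new exhale's anomaly error waveform.

All neural components run on a small self-contained base-R engine (im2col
convolutions over BLAS, Adam, gradient-checked backprop) — no external
deep-learning framework is needed. A seeded thermal-plume simulator
(drifting warm face, episodic advected–diffused plume, sensor noise)
provides ground-truth-labelled recordings, so the whole chain is testable
without clinical data.

## Worked example

Simulate a 20-second recording at 12 breaths/min, track it, compute flow
fields, and read off the breathing rate:

```r
library(exhaleflow)

sim <- simulate_sequence(sim_config(duration_s = 20.04, seed = 3,
                                    breaths_per_min = 12))
sim$seq
#> <thermal_sequence> 501 frames of 128x160 @ 25 fps
#>   count range: [5889, 9531]

np   <- estimate_norm_params(sim$seq$frames[[1]], sim$truth$roi, sim$truth$bg_roi)
rois <- track_sequence(sim$seq, sim$truth$roi, np$tracking)
mask <- make_face_mask(crop_roi(
          normalize_frame(sim$seq$frames[[1]], np$tracking, "tracking"),
          rois[[1]]))
frames <- lapply(sim$seq$frames, normalize_frame, params = np$exhale,
                 mode = "exhale")
fields <- flow_sequence(frames, rois, flow_params(), mask = mask)

w  <- filter_waveform(build_waveform(fields, fps = 25))
segs <- segment_exhales(w, min_separation = 2)
length(segs)
#> [1] 4
breathing_rate(w, segs)
#> [1] 12
```

Four exhale episodes are found in the 20-s window — 12 breaths/min
against the simulated 12/min. Each element of `segs` is one exhale
resampled to 256 samples in `[0, 1]`, ready for the anomaly scorer:

```r
refs   <- make_reference_segments(20, seed = 1)
inputs <- c(make_reference_segments(20, seed = 2),
            make_reference_segments(20, seed = 3, anomalous = TRUE))
scorer <- train_anomaly_model(build_anomaly_training_set(refs, inputs),
                              seed = 2, epochs = 20)
score_segment(scorer, segs[[1]])
#> <anomaly_score> mean 0.1129, max 0.6175
```

The scalar is the mean predicted error against the reference exhale set —
larger means more anomalous. The same chain, FieldNet training included, is
scriptable end to end:

```r
cfg <- pipeline_config(outdir = "out", seed = 1)
run_pipeline("all", cfg)   # simulate → track → flow → collate →
                           # train-fieldnet → predict → waveform →
                           # segment → train-anomaly → score
```

or from a shell via the thin CLI at `inst/cli/exhaleflow.R`
(`Rscript exhaleflow.R all --outdir out --seed 1`).

## Limitations

The simulator emulates the statistical structure the pipeline assumes —
not radiometric physics, occlusion, or background clutter. Waveforms are
uncalibrated flow proxies (pixel magnitudes per frame); conversion to L/s
or clinical PFT measures is out of scope. See the methods vignette
(`vignettes/exhaleflow-methods.Rmd`) for the model details and design
decisions.
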