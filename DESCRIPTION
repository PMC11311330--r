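Package: exhaleflow
Title: Non-Contact Expiratory Flow Measurement from Thermal Image Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for measuring natural exhale behaviour from mid-wave
    infrared image sequences in which exhaled CO2 plumes are directly visible.
    Reads raw 16-bit count sequences, tracks a fixed nose-mouth region with
    sparse Lucas-Kanade key-point flow, computes dense Horn-Schunck flow
    fields between consecutive frames, trains a U-Net style flow-field
    interpolation network (FieldNet) that predicts the intermediate flow
    state of two encoded fields, reduces field sequences to one-dimensional
    exhale waveforms, segments individual exhale episodes, and scores them
    against a reference set with a one-dimensional convolutional anomaly
    model. Includes a seeded synthetic thermal-plume simulator (drifting warm
    face, episodic advected-diffused plume, sensor noise) so every stage is
    testable without clinical recordings. All neural components run on a
    small self-contained base-R engine (im2col convolutions, Adam).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
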