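---
title: "Measuring expiratory flow from thermal image sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring expiratory flow from thermal image sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exhaleflow)
```

## The measurement problem

Exhaled air is warm and CO2-rich; in the mid-wave infrared band (3–5 µm) the
plume is directly visible against an indoor background, so a thermal camera
pointed at a seated subject in profile records each breath as a transient,
rightward-advecting turbulent plume leaving the nose and mouth. `exhaleflow`
turns such a recording — raw 16-bit *count* images (sensor activations prior
to radiometric calibration, typically 5000–9000 counts indoors) — into a
per-breath expiratory flow measurement:

1. **Dual normalization** (`normalize_frame`): the same raw frame is mapped
   twice: `[Fc, Imax] -> [0, 1]` for tracking (face texture contrast) and
   `[Ac, Fc] -> [0, 1]` for exhale measurement, where `Ac` is the ambient
   background count, `Fc` the face-temperature count, and plume intensities
   fall between them. Out-of-interval values clamp: the maps deliberately
   target a sub-range of the observed counts.
2. **ROI tracking** (`track_sequence`): a fixed-size nose–mouth window is
   tracked with Shi–Tomasi corner detection plus iterative Lucas–Kanade
   key-point flow, so subject movement does not contaminate the flow field.
3. **Dense optical flow** (`horn_schunck`): the Horn–Schunck iterative
   scheme with Sobel spatial derivatives produces an `(h, w, 2)` flow field
   per consecutive frame pair.
4. **Field encoding and interpolation** (`encode_field`, `train_fieldnet`):
   fields are component-normalized into `[-1, 1]` and a U-Net-style network
   (*FieldNet*) is trained to predict the intermediate field at `t + 1` from
   the fields at `t` and `t + 2`. Run over a whole sequence, the model acts
   as a learned filter that keeps coherent exhale flow and discards sensor
   noise.
5. **Waveform reduction** (`build_waveform`): each field collapses to the
   scalar `f(t) = sum of all vector magnitudes`, yielding a 1-D exhale
   waveform, which is filtered (outlier interpolation, Savitzky–Golay,
   min–max) and split into per-exhale segments of fixed length 256.
6. **Anomaly scoring** (`train_anomaly_model`): a 1-D convolutional model is
   trained on reference–input segment pairs to predict the error waveform
   `e(t) = |ref(t) - input(t)|`, giving each new exhale a reference-relative
   anomaly scale.

No clinical recordings ship with the package; a seeded simulator
(`simulate_sequence`) generates thermal sequences with known ground truth so
that every stage is testable end to end.

## Flow model and its numerics

The flow between normalized frames $I_t$ and $I_{t+1}$ minimizes the usual
brightness-constancy plus smoothness energy

$$\min \iint (\nabla I \cdot v + I_t)^2
  + \alpha\,(\lVert\nabla v_x\rVert^2 + \lVert\nabla v_y\rVert^2)\,dx\,dy$$

via the fixed-point iteration that alternates a neighbourhood average
$\bar v$ with a correction along the image gradient, with denominator
$\alpha + I_x^2 + I_y^2$. Note the *un-squared* $\alpha$: the classical
Horn–Schunck update uses $\alpha^2$ in that denominator; this implementation
follows the stated form, and since $\alpha$ is a free parameter either
behaviour is reachable. Numerical choices:

* $\alpha = 0.15$ by default — small, so that intensity shifts near the
  sensor noise floor still register as flow, which is what makes a
  dissipating plume measurable at all.
* Sobel derivatives normalized by 1/8 (a unit ramp has unit gradient),
  reflective borders; spatial derivatives are taken on the first frame and
  $\partial I/\partial t = I_{t+1} - I_t$ pointwise.
* $\bar v$ uses the standard 3×3 stencil (1/6 cardinal, 1/12 diagonal).
* 64 iterations by default, no early stop, so identical inputs give
  bitwise-identical fields; two identical frames give an exactly zero field
  because zero flow is a fixed point of the update.

### Shift compensation and face masking

The tracked ROI moves in integer steps. Cropping each frame of a pair at its
own ROI superimposes the negated ROI shift on everything static — and the
solver can only *measure* (and hence a post-hoc `compensate_shift` can only
cancel) that motion where the image has gradients. Over a textureless
background the solved field stays near zero and subtracting the induced
motion would inject the full shift as spurious flow across thousands of
pixels. `flow_sequence` therefore applies the exact inverse of the ROI
transformation instead: both frames of a pair are cropped at the *later*
frame's ROI, so the static background cancels identically.
`compensate_shift` remains available for fields computed across differing
crops.

Facial flow is removed with a mask computed from the tracking-normalized
first frame: with the tracking anchor placed partway between ambient and
face level, the background clamps to exactly 0 and any stable value above
the noise floor marks the face footprint (threshold 0.05, about four noise
standard deviations; both threshold and dilation are configurable). The
dilation radius of 4 px exists to absorb the face's sub-threshold skirt and
the tracker's position error bound: any warm edge left outside the mask
drifts sub-pixel with the face and produces flow humps on the scale of a
real exhale. The mask is applied to the *input* crops as well as to
the output field: masking only the output lets the moving face texture bleed
flow into unmasked pixels through the smoothness term, which at 64
iterations propagates tens of pixels.

## Field encoding

Fields are encoded for the network by dividing both components by the
maximum vector magnitude `n_max`, mapping into `[-1, 1]`; per-sequence
`n_max` is the default so that magnitudes remain comparable over time and
the waveform of decoded predictions is meaningful. The angle/magnitude
alternative — $(\sin\theta, \cos\theta)\cdot n/m$ — is implemented in
`encode_angular` purely to verify its equivalence: for every field it equals
the direct normalization with the two channel slices interchanged, which is
why the cheaper direct normalization is the one the pipeline uses.

The training set interleaves a field sequence into stride-1 triples (inputs
`t` and `t+2` stacked as `(h, w, 4)`, target `t+1`), and is augmented with
mirrored and rotated copies — the acquisition geometry always places the
subject left, breathing rightward, a bias augmentation corrects. Spatial
transforms act on grid *and* vector components together (`hflip` negates
$v_x$, `rot90` maps $(v_x, v_y) \to (-v_y, v_x)$, …), so per-field magnitude
histograms are preserved exactly; right-angle rotations are restricted to
square fields because anything else changes the tensor shape. Augmented
copies inherit their source's train/validation tag, preventing leakage.

## FieldNet

FieldNet is an encoder–decoder with two skip connections: two conv–conv–pool
encoder blocks, a bottleneck, two upsample–concat–conv–conv decoder blocks,
and a final 1×1 convolution to 2 channels — tanh on every layer, matching
the `[-1, 1]` encoding. Channel widths follow the usual doubling
$(C, 2C, 4C)$. The design fixes the input shape, the two skip levels, the
activation, a dropout rate of 0.025, Adam at $10^{-3}$ with MSE loss, and a
total of 18.7 million trainable parameters — the layer widths are free.
With the doubling scheme the parameter count is
$459C^2 + 58C + 2$, and $C = 202$ gives 18,740,754 ≈ 18.7 M; that width is
frozen as `fieldnet_reference_config()` and used for the parameter-count
check only.

All training in this package runs on a self-contained base-R engine
(im2col convolutions backed by BLAS matrix products, max-pooling, nearest
upsampling, Adam); backpropagation is validated against central-difference
gradients in the test suite. The desk-scale configuration used by the tests
and the default pipeline is 64×64 fields, base width 16, 4 epochs on a
~500-field sequence. At that dataset size a batch of 64 would give the
optimizer only ~30 steps, so the desk-scale batch size is 8 (~230 steps);
batch 64 is retained in the full-size configuration, whose schedule (16
epochs over the augmented 2500-field pool) takes on the order of a few
thousand steps. The Adam rate decays linearly to 10% of its base value
over the run, so the final batches settle the weights instead of
oscillating — without decay the validation MSE fluctuates by a factor of
two between epochs at small batch sizes. Dropout sits after each encoder
block; inference disables it, so prediction is deterministic.

Interpolation inference feeds the encoded fields at $t-1$ and $t+1$ and
takes the predicted intermediate field at $t$, assigning it the mean of the
two inputs' `n_max` for decoding. Because sensor noise is unpredictable
from neighbouring fields while plume structure is not, the prediction acts
as a filter, and the waveform built from predicted fields has a quieter
inter-breath baseline than the raw optical-flow waveform — the property the
tests assert.

## Waveform processing

`filter_waveform` applies, in order: replacement of samples beyond 1.5 SD
by linear interpolation of their neighbours (replacement rather than
deletion keeps samples aligned with the frame clock), Savitzky–Golay
smoothing with window 9 and polynomial order 3 (the window is stated, the
order is this package's choice), and min–max normalization to `[0, 1]`.
A constant signal cannot be min–max normalized and returns zeros with a
`degenerate` flag.

Exhale segmentation detects waveform peaks subject to a topographic
prominence threshold (0.1 of the normalized range) and a minimum
separation, places boundaries at the minima between consecutive peaks, and
linearly resamples each span to the fixed model input length of 256.
`segment_exhales` defaults to 0.5 s separation; the *pipeline* uses 2 s for
breath counting, because turbulent exhales carry sub-peaks more than 0.5 s
apart within a single episode and the physiological ceiling near
30 breaths/min makes 2 s a safe lower bound between true breaths.

## Anomaly model

The denoising autoencoder (two stride-2 convolutions to a 32-channel
latent of length 64, two transposed convolutions back, kernel 7, relu,
identity target) removes turbulent per-sample variance from segments. The
scorer is a three-layer kernel-7 convolutional map (widths 32-32-1, relu)
from a segment to its predicted error waveform, trained on the full cross
product of `n` reference and `m` mixed input segments (`n*m` pairs, each
target `|ref - input|`). Denoised segments feed the scorer by default; a
bypass flag exists. The scalar anomaly score is the mean of the clamped
predicted error waveform (the maximum is also reported). Width choices for
both 1-D models are this package's (the source figures give none); epoch
defaults are 50.

## The synthetic world

`simulate_sequence` emulates what the pipeline assumes about clinical
recordings, with defaults chosen once as plausible for the instrument
class:

* ambient 6000 counts, face 8800 counts (inside the typical indoor
  5000–9000 range), Gaussian sensor noise with SD 15 counts (a NETD of a
  few tens of mK at this scene contrast);
* a profile face on the left — elliptical head plus a warm nose/mouth
  protrusion with smooth texture and hot spots, giving the tracker genuine
  corner features — drifting along a seeded smooth random walk
  (0.15 px/frame RMS by default; linear drift and static modes exist for
  ground-truth tests);
* episodic exhales at `breaths_per_min` (default 12): raised-cosine rise
  (0.4 s), exponential decay (0.4 s), jittered onsets and amplitudes,
  exactly zero emission between episodes; anomalous episodes get amplitude
  ×U(1.3, 1.8) and duration ×U(0.5, 0.7);
* a plume advected semi-Lagrangian (unconditionally stable at desk scale)
  rightward at 1.5 px/frame plus a divergence-free curl-noise turbulence
  field redrawn every frame (RMS 0.4 px/frame, correlation scale 8 px), with
  Gaussian diffusion and multiplicative dissipation decay 0.92/frame,
  injected at a nozzle on the face's right edge;
* general room-air movement — a faint warm-air shimmer texture (RMS 20
  counts, ~1.3× the sensor noise, correlation scale 5 px) drifting along a
  seeded bounded random walk (RMS 0.8 px/frame), the background air motion
  open environments always carry and the pipeline must separate exhale
  flow from;
* default desk-scale frames of 128×160 at 25 fps (roughly a quarter of the
  512×640 full size, which remains available).

The ground truth includes, besides the emission schedule, the
*plume response*: the emission accumulated under the per-frame dissipation
decay. The camera sees the lingering plume, not the instantaneous emission
rate, so waveforms are validated against the response series: the
dissipation tail decorrelates the visible plume appreciably from the raw
schedule (the response–schedule correlation sits in the 0.55–0.75 range
across seeds), while measured waveforms track the response series at
r > 0.8.

Every stage is deterministic per seed. What the simulator does *not*
emulate: radiometric physics, occlusion, posture change, background clutter
with its own motion, and real turbulence spectra. Passing tests therefore
demonstrate that the pipeline recovers what this model world encodes —
rates, episode boundaries, planted anomalies — not clinical performance.

## Problem sizes used by the test suite

The suite runs the full chain at desk scale: one 501-frame sequence
(128×160, 64×64 ROI) for the end-to-end checks, a five-subject cohort of
500 fields each for the training-pool check, FieldNet at 64×64/base 16 for
4 epochs, and the 1-D models at a few hundred pairs for a few dozen epochs.
Small gradient-check configurations (8×8 fields, length-256 segments) make
backpropagation errors fail loudly rather than as vague quality loss.

## Known limitations

* The Horn–Schunck solver is plain array arithmetic; it is fast enough for
  desk-scale work but is not the real-time parallel implementation the
  measurement setting would use.
* `Fc`/`Imax` estimation from a single frame assumes the face is the
  warmest large structure and the first frame is exhale-free; recordings
  that start mid-exhale would fold plume pixels into the face mask.
* The waveform is an uncalibrated flow proxy (pixel magnitudes summed over
  the ROI); conversion to L/s or clinical PFT measures is out of scope.
* The anomaly labels on synthetic data encode amplitude/duration
  perturbations; real pathology is not a generator parameter.
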