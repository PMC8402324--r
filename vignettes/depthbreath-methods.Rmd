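---
title: "Contactless respiratory monitoring from depth video: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless respiratory monitoring from depth video: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthbreath)
```

## The measurement principle

Breathing moves the body surface: during inhalation the chest and abdominal
walls expand toward an observer placed in front of the subject, during
exhalation they recede. An RGB-D camera registers, besides the usual color
image, a per-pixel depth map in millimetres. Pointing such a camera at a
seated subject about 1 m away therefore turns respiration into a small
periodic modulation — a few millimetres — of the depth values over the trunk.
`depthbreath` estimates the respiratory signal, and from it breath-by-breath
breathing rates, from nothing but the *mean depth* of automatically placed
regions of interest (ROIs). Averaging over the few thousand pixels of an ROI
is what makes the principle work: single-pixel depth noise of a consumer
structured-light module at 1 m is on the order of 2.5 mm — the same magnitude
as the motion — but the mean over an ROI suppresses it by two orders of
magnitude. Because each ROI contributes one arithmetic mean per frame, the
per-sample cost is constant and many regions (thorax and abdomen here; up to
ten are supported by the extraction stage) can be acquired synchronously in
real time.

## Stage by stage

### Background masking and face detection

Pixels deeper than 1.5 m are masked, as are null-depth pixels (value 0, no
sensor return), leaving the subject alone in the scene. The unmasked region
is then refined by a morphological closing (dilate then erode, 7×7 square
kernel by default) which absorbs speckle holes — isolated invalid patches
inside the silhouette — while restoring the outer contour. No kernel size is
canonical here; 7 px closes typical speckle at 640×480 without bridging
between body and background.

The face is located on the masked color stream. Detection is behind a
two-function interface (`(color, mask) -> box or NULL`), with two
implementations: an *oracle* detector that returns the annotated box of a
synthetic sequence, and a color-segmentation *blob* detector that labels
skin-like connected components and returns the largest one's bounding box.
The oracle exists so every downstream stage can be tested independently of
detection quality; the blob detector exercises the full masked-detection
path on synthetic scenes. On real footage one would drop a trained detector
(Viola–Jones cascade, CNN) behind the same interface. If no face is found in
a frame, the search moves to the next frame, up to a configurable budget
(150 frames by default — an unbounded retry loop is deliberately rejected).

### ROI placement

With the face box at $(x, y)$, size $w \times h$, in a frame of height $H$,
the regions are placed at fixed multiples of the face height above the
bottom edge of the frame:

$$\text{thorax} = [x,\, x+w) \times [H - 2h,\; H - \tfrac{3h}{2}), \qquad
  \text{abdomen} = [x,\, x+w) \times [H - \tfrac{5h}{6},\; H - \tfrac{h}{3})$$

Both regions have width $w$ and height $h/2$ (area $wh/2$) and scale with
the apparent face size, so the placement adapts to the subject's distance
and build without any fixed-size assumption. Coordinates are 0-based,
half-open (inclusive upper-left, exclusive lower-right) — this makes pixel
counting unambiguous — and fractional values are rounded to the nearest
integer, ties away from zero. Regions partly outside the frame are clipped
with a warning; a region entirely outside is a geometry error. Once placed,
the ROIs stay fixed for the whole recording; moving subjects are out of
scope.

### Signal conditioning

Per frame, the mean depth over each ROI (masked and null pixels excluded) is
stored with the frame timestamp. Frames in which *every* ROI pixel is
invalid become missing samples, filled by linear interpolation so the series
stays on a usable grid; an ROI invalid in more than half the frames aborts
the acquisition, mirroring how saturated or occluded recordings must be
discarded in practice.

The raw series is then conditioned in three steps:

1. **Normalization** to zero mean and unit scale (population SD). Rate
   estimation is scale-invariant; the fixed convention exists for
   reproducibility, and zero mean reduces filter start-up transients.
2. **Causal moving average**, $y(n) = \frac{1}{ws}\sum_{k=0}^{ws-1} x(n-k)$
   with $ws = 8$ samples, an expanding window over the first $ws-1$ samples.
   At 15 fps this suppresses frame-to-frame noise while leaving the
   breathing band (gain ≥ 0.9 up to 0.5 Hz) essentially untouched. Being
   causal, it delays the signal by a constant $(ws-1)/2 = 3.5$ samples
   (0.23 s); a constant delay shifts every peak equally and cancels exactly
   in all breath-interval quantities, so it is not compensated.
3. **Zero-phase Butterworth band-pass**, 0.08–0.5 Hz (4.8–30 breaths/min),
   order-4 prototype, applied forward and backward (`signal::filtfilt`) so
   the net phase response is zero and peak/trough locations are preserved.
   Before filtering, the series is resampled by linear interpolation onto a
   uniform grid at the nominal frame rate (recorded timestamps jitter around
   the nominal interval, and IIR design assumes uniform sampling), its mean
   is removed exactly, and the ends are extended by odd reflection
   (about three low-band time constants) to suppress the forward-backward
   start-up transient — without the padding, the outermost one or two breath
   peaks shift visibly.

The choice of *batch* zero-phase filtering over a causal (streaming) filter
is deliberate: a causal IIR would trade peak-time fidelity for bounded
latency. The real-time character of the method lives in the acquisition
(constant work per frame), not in the offline conditioning; a streaming mode
would substitute a linear-phase FIR and is future work.

### Breath detection and rates

Inhalation brings the chest wall toward the camera, i.e. *decreases* depth,
so the conditioned series is negated before peak picking: inhalation events
are then signal maxima. Peaks are local maxima with

* minimum spacing 2 s (= one breath at the 30 breaths/min band edge),
  enforced with one sample of slack so breathing exactly at the band edge,
  whose peak spacing quantizes to the sample grid, is not suppressed;
* topographic prominence at least 0.3 × SD of the signal, rejecting ripple
  left by waveform harmonics;
* plateau-aware candidate selection (runs of equal samples count once, at
  the run centre), needed because integer-millimetre quantization can
  produce flat-topped maxima;
* sub-sample refinement by a parabola through the three samples around each
  maximum.

Fewer than two peaks is treated as a period of no acquisition (an error
condition, not a zero rate). Troughs are detected identically on the negated
signal and kept as secondary information; all rates are computed from
peak-to-peak intervals. Each interval yields one tachogram entry
$br = 60/\Delta t$ breaths/min, stamped at the later peak — the moment the
value becomes available in a live display. A sliding window of $n$ cycles
(default 5), advanced by 1 cycle and stamped at the window's last peak,
trades update latency for dispersion: at a stable 16 breaths/min,
breath-by-breath updates arrive every 3.75 s, 2-cycle windows every 7.5 s.

### Agreement statistics

Estimated and reference tachograms are compared after pairing breaths
greedily by nearest timestamps (closest pairs first, each entry used at most
once) within a tolerance of half the median reference breath interval;
unmatched breaths are counted and excluded. On the paired differences the
Bland–Altman bias and limits of agreement $\text{bias} \pm 1.96\,s_d$
(sample SD) are computed — the multiplier is a parameter, 1.96 being the
conventional 95% normal quantile — plus the RMSE
$\sqrt{\tfrac{1}{N}\sum_n (\widehat{BR}_n - BR_n)^2}$, available at breath
level and at experiment level (one mean rate per recording). No rejection of
physiologically implausible single intervals is applied before averaging.

## The synthetic scene generator

No public RGB-D breathing corpus is available to this package, so the
generator in `synthesize_sequence()` is a first-class, tested component: it
renders a background plane at 2.5 m, a body silhouette (head ellipse plus
torso rectangle) at 1 m, and, within each ROI footprint (placed from the
oracle face box by the same equations the pipeline uses), a depth of
$\text{subject distance} - d(t)$, where $d(t)$ is the displacement model:
a sinusoid of configurable rate and amplitude, optionally with a second
harmonic (20% is a realistic inhale/exhale asymmetry), breath-to-breath
interval jitter (each cycle duration drawn uniformly within ±3% by default
when enabled), and central/obstructive apnea episodes (damped, respectively
amplified and phase-shifted motion). Per-pixel Gaussian depth noise
(σ = 2.5 mm, the expected sensitivity of a structured-light module at 1 m),
integer-millimetre quantization, 1% null-depth dropout, and 5% frame-timing
jitter complete the measurement model. Defaults — 640×480 at 15 fps, 60-s
recordings — are the recording conditions the method targets.

Choices worth recording:

* **Displacement amplitude 4 mm** is an assumption: chest-wall excursion is
  not a published constant of the method; 4 mm sits comfortably above the
  sensor sensitivity while staying in the "few millimetres" regime of quiet
  breathing. Recovery is amplitude-invariant over at least 2–10 mm (tested).
* **Quantization is kept** (frames are integer millimetres, as on disk).
  The staircase harmonics of the breathing fundamental fall above the
  0.5 Hz band edge and are removed by the band-pass, so peak timing is
  unaffected; tests confirm this.
* **Ground truth is exact**: the analytic inhalation peak times of the
  waveform are stored in the annotation sidecar, so agreement statistics
  compare against truth, not against a second estimator.
* **Determinism**: one seed fixes everything; per-frame noise uses a seed
  derived from (sequence seed, frame index), so lazily rendered frames are
  bit-identical regardless of access order, and long sequences never need
  to be held in memory.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: clothing texture and its interaction with
structured-light depth, posture changes and involuntary motion, multi-path
and saturation artifacts of real sensors, faces a cartoon-free detector
could find, and the waveform deviations of a real piezoelectric reference
belt. Results on synthetic batches characterize the *algorithm* under its
stated measurement model, not clinical performance.

## Study-scale checks

Two replication-style batches ship with the package (and are what
`scripts/acceptance.R` runs):

* `simulate_forced_rate_study()`: 17 recordings of 60 s at forced rates
  spanning 12–25 breaths/min (metronome-style schedule, several rates
  repeated), full pipeline, experiment-level RMSE of estimated mean rate vs
  forced rate.
* `simulate_two_roi_study()`: 20 two-ROI recordings of 60 s at base rates
  spread evenly over 8–29 breaths/min with ±3% interval jitter; thorax and
  abdomen share the breath timing (one subject, one respiratory drive).
  Estimated breaths are paired with ground-truth events; per-recording
  paired means are compared by RMSE, breath-by-breath and after 5-cycle
  windowing of both tachograms.

The problem sizes (17 and 20 recordings of 60 s, one per seed derived from
the batch seed) keep a full run in the minutes range on one CPU while still
averaging over enough breaths (~400 per batch) for stable error estimates.

## Numerical and degenerate-input conventions

* Rounding of ROI coordinates: nearest integer, ties away from zero (base
  R's `round()` rounds ties to even, which would break scale equivariance).
* A constant raw series normalizes to all zeros; peak detection on it
  reports "no breaths" rather than inventing a rate.
* Recordings shorter than three low-band periods (37.5 s) are filtered with
  a warning: the output is transient-dominated.
* Depth is stored on disk as 16-bit integer millimetres (lossless roundtrip,
  enforced); all in-memory computation is in double precision.
* The pairing tolerance defaults to half the median reference interval so
  that a uniform small timing offset (e.g. the uncompensated moving-average
  delay) can never flip a pairing.

## Known limitations

* No motion/tracking: the ROIs are frozen after the first detection; a
  subject who shifts invalidates the geometry silently (only the mean-depth
  plausibility checks would notice).
* The blob face detector is only meant for the synthetic scenes; no trained
  appearance-based detector ships with the package.
* Apnea episodes can be synthesized but are not classified; detection of
  central vs obstructive events from thoraco-abdominal phase is out of
  scope.
* Batch (not streaming) filtering, as discussed above.
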