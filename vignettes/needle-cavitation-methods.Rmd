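---
title: "Methods: quantifying biopsy-needle cavitation from video and audio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying biopsy-needle cavitation from video and audio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needlecav)
```

## The measurement problem

A spring-loaded core needle biopsy device stores elastic energy and
releases it to fire a coaxial needle (inner stylet + outer cutting
cannula for side-cut designs; a single Franseen-tipped cutting cannula
for front-cut designs) through tissue, ending in an abrupt far-end stop.
The firing excites lateral flexural oscillation of the tip at several
m/s. In water or compliant hydrogel this behaves like a bluff body moved
rapidly through fluid at rest: pressure drops in the wake, and transient
cavitation bubble clouds can nucleate at the sharp tip geometry.

`needlecav` quantifies this from two co-registered streams:

* high-speed shadowgraphy video (backlit: needle and bubbles are dark on
  a bright background), 384×288 px at 100 000 frames/s, 25 µm/pixel;
* a hydrophone pressure trace at 100 kHz, trigger-aligned with the video
  (the oscilloscope trigger defines t = 0 on both axes).

All time axes in the package are trigger-aligned; frame *k* maps to
`time_offset + (k−1)/frame_rate` and sample *j* to
`(j − trigger_sample)/fs` (`coregister()`).

## Projected bubble area

Each frame is binarized; the cavitation area is the dark-pixel count in
excess of the needle-at-rest count, times the pixel area:

$$A_k = \max(0,\; N_{\text{dark},k} - N_{\text{rest}}) \cdot p^2,
\qquad p = 25\ \mu\text{m/px}.$$

Choices the estimator's definition leaves open, and how they are fixed
here:

* **Threshold.** The binarization method is Otsu's criterion computed on
  the rest frames and then *held fixed* for the whole sequence, so that
  the appearance of bubbles cannot drift the threshold; a fixed-level
  override exists. Constant-intensity frames make Otsu undefined and
  raise an error pointing to the fixed mode.
* **Rest reference.** `build_rest_reference()` takes the pixelwise
  majority vote of several binarized rest frames, which removes salt
  noise. The pipeline default takes the *closing* frames of the recording
  (`rest_from = "last"`): a recording of a firing covers the far-end
  stop, so the needle occupies its final rest position, bubble-free, at
  the end. With that convention, pre-firing frames (needle retracted,
  fewer dark pixels than the reference) give negative differences, which
  are clamped to zero and counted in a QC field (`n_clamped`).
* **Moving-needle bias.** The subtraction uses the rest count even while
  the needle moves; displaced-needle pixels therefore inflate the
  estimate. We implement exactly this rule — fidelity to the established
  procedure first — and additionally expose `exclude_needle = TRUE`,
  which masks out the rest silhouette instead; it is labelled an
  extension and is not used by default.
* **Duration.** The duration of a cavitation episode is the total time
  the area exceeds a threshold; no published start/stop criterion
  exists, so the default threshold is 0 mm² (any nonzero area counts),
  configurable. On real-like noisy sequences a small threshold (e.g.
  0.05 mm², ≈ 80 px) suppresses rasterization jitter of the oscillating
  needle boundary; the worked example in the README uses it.

Replicate pooling (`aggregate_replicates`) is the pointwise mean and
sample standard deviation (denominator N−1) over series sharing a time
grid, as used for N = 9 recordings (3 devices × 3 technical replicates);
mismatched grids are an error rather than being silently resampled.

## Tip kinematics

Features are detected by the minimum-eigenvalue (Shi–Tomasi) criterion:
the score is the smaller eigenvalue of the gradient structure tensor
summed over a (2w+1)² window (default w = 3 px), with 3×3 non-maximum
suppression and a deterministic ordering (score desc, then row, then
column). Tracking is pyramidal Kanade–Lucas–Tomasi: iterative local
least-squares displacement per pyramid level, coarse to fine. Defaults —
3 levels, 15×15 px window, 30 iterations, 0.01 px convergence — are
standard practice values and are recorded in the trajectory object. A
feature whose patch leaves the frame or whose final RMS intensity
residual exceeds 25 (on the 0–255 scale) is invalidated; loss is a
flagged outcome, not an error, and valid segments are contiguous from
the first frame. The tracker is fully deterministic.

Displacement (y = +columns, z = −rows, converted to mm by the pixel
pitch, relative to the first tracked frame) is differentiated with
second-order central differences, one-sided second-order stencils at the
ends — once for velocity, twice for acceleration. Position uncertainty
is about one pixel (25 µm), which double differentiation at 100 kHz
amplifies enormously; the default therefore smooths displacement with a
5-frame centered moving average before differencing (recorded in the
output descriptor; `smoothing = 1` gives the raw mode). The moving
average shrinks symmetrically at the series ends so linear trends pass
through exactly. Known attenuation: a sinusoidal displacement at
frequency f is attenuated by `sin(5πf/fs)/(5 sin(πf/fs))` — about 1.6 %
at 2 kHz, 6 % at 4 kHz — so velocities of fast oscillations are mild
underestimates; tests budget for this within their 5 % recovery bands.

`detect_motion_events()` lists every crossing of a per-axis velocity
magnitude threshold (default 7 m/s, the level above which cavitation
onset is observed; below 5.5 m/s no activity occurs) and estimates the
stop time as the maximum deceleration magnitude after peak speed.

## Calibrated SPL spectrograms

The hydrophone trace (pressure in Pa; WAV files store float Pa with unit
sensitivity, because no hydrophone calibration chain is published) is
transformed with a short-time Fourier transform using a 2560-sample
window with 2500 samples of overlap — 39.06 Hz resolution and a 0.6 ms
hop at 100 kHz. Two conventions are offered:

* **band** (default): one-sided amplitude spectrum with the window's
  coherent gain compensated, so a *pure tone's peak bin reads the tone's
  true band SPL*, `20·log₁₀(p_rms/1 µPa)`. This makes the printed peak
  levels directly reproducible: a 56.23 Pa RMS tone reads 155.0 dB, a
  14.13 Pa tone 143.0 dB. An off-bin tone additionally suffers Hann
  scalloping (up to −1.4 dB at half a bin); calibration statements refer
  to bin-centered tones.
* **density**: `10·log₁₀(PSD/1 µPa²/Hz)`; the two differ by
  `10·log₁₀(ENBW·Δf)`.

The window is Hann by default (rectangular available; with rectangular
windows the per-bin band powers sum exactly to the frame's time-domain
power — the Parseval check used in the tests). Silence maps to a −20 dB
re 1 µPa sentinel floor, below any physical level here. Time bins are
window centres; the trigger sample falls within half a hop of the t = 0
bin.

**Bursts.** A time bin qualifies when ≥ 50 % of frequency bins exceed
their per-frequency running median (along time) by 12 dB; adjacent
qualifying bins merge into one event timed at peak SPL. These thresholds
are artifact choices validated on synthetic fixtures (the original
identification was visual). Because the 2560-sample display window is
25.6 ms long, bursts a few ms apart smear into one plateau at that
resolution; the pipeline therefore runs the burst detector on a
short-window spectrogram (256/192 by default, 2.56 ms window, 0.64 ms
hop), which resolves the three-burst side-cut signature
(0.015/0.020/0.025 s) and the two-burst front-cut signature to ±1 ms.

**Tone ridges.** Within the 10–30 kHz band, a frequency bin belongs to a
ridge while it exceeds the band's per-time median by 8 dB for at least
20 ms of consecutive bins. Successive windows share 97.6 % of their
samples, so noise excursions are correlated across ~40 time bins and can
graze the threshold for long runs; a ridge must therefore also clear the
rise threshold by 3 dB *on average* over its run. Ridges that persist
after the bubbles have optically vanished identify structural
eigenfrequencies of the needle rather than bubble ringing.

## Hydrodynamic characterization

$$Ca = \frac{p - p_v}{\tfrac12 \rho u^2}, \qquad Re = \frac{u L \rho}{\mu}$$

with defaults for water at 20 °C (ρ = 998 kg/m³, μ = 1 mPa·s,
p_v = 2339 Pa, p = 101 325 Pa) and L = 2.109 mm (14 G shaft outer
diameter); all overridable. The agarose media use ν = 5×10⁻⁶ m²/s (the
literature value for a 0.9 % w/v gel) as an order of magnitude for both
gel concentrations — a documented simplification. Wake regimes: Re < 49
laminar, 49 ≤ Re ≤ 190 vortex transition (both boundaries implemented as
closed, since the published upper bound is approximate), Re > 190
turbulent. The pipeline evaluates Ca and Re at the measured peak
*lateral* tip velocity, the implicit usage in the source analysis.

## The synthetic-data generator

The generator emulates the statistical and physical structure of the
recordings so every stage is testable without the original data:

* **Video.** 8-bit frames, background ≈ 220, needle and bubbles ≈ 30,
  Gaussian noise SD 5 — a 38-SD dark/bright margin, so Otsu binarization
  is unambiguous (the constructor rejects intensity models violating a
  5-SD margin). The needle is a filled silhouette hanging from the top
  edge: a slanted bevel with the sharp point at the right shaft edge
  (side cut) or a symmetric vee crown (front cut); exact CAD fidelity is
  deliberately not attempted and downstream stages do not depend on it.
  The axis leans 1.5° from vertical by default — a realistic mounting
  misalignment which also decorrelates boundary rasterization across
  rows (a perfectly axis-aligned edge flips a whole ~280-row column of
  pixels at once as the sub-pixel phase drifts, which would put
  ±0.15 mm² steps into the area series).
* **Bubbles** are prescribed ellipses (optionally with time-varying
  semi-axes for growth/collapse), alive on [birth, death); the ground
  truth is the analytic (frame-clipped) area πab. Rasterization is
  *area-exact*: pixels are ranked by sub-sampled coverage and included
  until the rendered count matches the analytic area, so the binary
  silhouette carries the prescribed area to within half a pixel and
  lattice artifacts do not contaminate estimator benchmarks. Bubbles
  overlapping the needle silhouette are rejected by default (the
  estimator cannot separate them); a flag permits overlap for robustness
  experiments. Events fully outside the frame are a validation error
  naming the event.
* **Motion.** `firing_motion_profile()` composes a smoothstep
  longitudinal stroke ending in an abrupt stop with an exponentially
  decaying lateral sinusoid after the stop. The demo scenes use a 3 mm
  stroke over 4 ms ending at t = 0.025 s; the side-cut scene oscillates
  at 2 kHz × 0.7 mm (peak tip velocity ≈ 8 m/s, inside the observed
  7–10 m/s range), the front-cut at 0.05 mm (negligible lateral motion,
  consistent with its sub-mm lateral displacement).
* **Audio.** Gaussian noise floor, band-limited Hann-enveloped noise
  bursts with prescribed per-burst RMS at prescribed times (side cut:
  0.015/0.020/0.025 s with the stop loudest; front cut: 0.020/0.025 s),
  and decaying ringing tones in the 10–30 kHz band starting at the last
  burst. The default trace is 0.06 s at 100 kHz — long enough that a
  20 ms ridge persistence is measurable past the 25.6 ms analysis
  window.
* **Determinism.** One integer seed drives all draws through a single
  generator; identical scene + seed reproduces bit-identical frames and
  samples, and the seed is recorded in the fixture manifest.
  `write_fixture_bundle()` emits a multi-page TIFF, a float-Pa WAV, a
  ground-truth JSON and a manifest with MD5 checksums.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: bubble nucleation/collapse dynamics are
prescribed, not emergent (no Rayleigh–Plesset physics); bubble clouds
are disjoint ellipses rather than ragged overlapping clusters; the
needle silhouette is rigid (no flexural bending along the shaft); video
noise is i.i.d. Gaussian without illumination drift or motion blur; and
the acoustic propagation path (reflections, hydrophone directivity) is
absent. Results on real recordings additionally inherit the
moving-needle bias of the literal subtraction rule discussed above.

## Problem sizes and runtime

The demonstration experiments run the full chain at the native
resolution (288×384 px, 100 000 frames/s): 650 frames covering
t = 0.022–0.0285 s plus a 6 000-sample audio trace; one complete run
(generation + pipeline) takes well under a minute on a single CPU. Unit
tests use smaller 96×128 px static-needle scenes and a few hundred
frames so the whole suite stays fast; the end-to-end recovery tests use
192×256 px scenes with smooth lateral motion profiles and zero-decay
ringing tones, for which peak velocity and peak SPL have closed-form
ground truth.

## Known limitations

* The subtraction estimator cannot separate bubbles that overlap the
  (displaced) needle silhouette, and inherits the moving-needle bias of
  the published rule; the exclusion mode trades that bias for blindness
  to bubbles inside the rest silhouette.
* Velocities of oscillations faster than ~4 kHz are visibly attenuated
  by the default 5-frame smoothing; use `smoothing = 1` plus external
  filtering if that band matters.
* SPL calibration is exact for bin-centered tones; broadband levels
  depend on the chosen spectral convention (band vs density), which is
  recorded in the spectrogram object.
* Ca/Re use a single characteristic dimension (shaft diameter) and the
  peak lateral velocity; they characterize the shaft flow, not the
  detailed tip geometry.
* The CLI reads YAML configs (`yaml` package) rather than INI-style
  sections; it is a thin veneer over the exported functions, which
  remain the primary interface.
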