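---
title: "Receive-mode ultrasonic tracking of a fiber-optic sensor: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receive-mode ultrasonic tracking of a fiber-optic sensor: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foustrack)
```

## The problem

A fiber-optic ultrasound sensor (FOUS) — a Fabry-Pérot (F-P) cavity on the
tip of a single-mode fiber — rides on an interventional device such as a
steerable cardiac catheter. A clinical imaging array sweeps its transmit
beams across the field of view; the FOUS *receives* each transmission.
Because the sensor is a receiver and not an echo target, the time of flight
from the line trigger to reception maps one-way to distance, `d = c t`
(no pulse-echo factor of ½). Concatenating the envelope-detected per-line
time series of one frame gives a 2D *tracking image* in which the sensor
appears as a bright focal spot; its centre of mass (CoM) is the device-tip
coordinate overlaid on the B-mode display.

Two physical questions drive the design: how well the tip can be localized
from such images, and how sensor sensitivity survives the tight fiber
bends a deflectable catheter imposes. `foustrack` implements both as a
seeded simulation-plus-analysis pipeline so that the entire chain runs
from code alone.

## Sensor model

### Interference transfer function

The F-P cavity's reflected power versus round-trip phase $\phi$ is the
Airy reflectance of a lossless two-mirror cavity,

$$R(\phi) = \frac{(\sqrt{R_1}-\sqrt{R_2})^2 + 4\sqrt{R_1R_2}\,\sin^2(\phi/2)}
                {(1-\sqrt{R_1R_2})^2 + 4\sqrt{R_1R_2}\,\sin^2(\phi/2)},$$

2π-periodic with a null at resonance for matched mirrors. Acoustic
pressure modulates $\phi$; operating at the phase of maximum $|dR/d\phi|$
(the standard bias point for F-P interrogation) makes acoustic
sensitivity proportional to that slope times the optical power delivered
to the cavity. The default mirror reflectivities (0.8/0.8) produce a
clearly resolved high-finesse fringe; they are a display/shape choice
only, since the normalized sensitivity used throughout is independent of
them once the bias point is fixed.

### Macrobend loss

Bending a fiber leaks power from the core; the loss per full turn follows
the standard macrobend phenomenology

$$L(r) = a\,e^{-b r}\ \text{dB/turn},$$

with $(a, b)$ fitted per fiber type from two published anchor points
each:

* **standard SMF** — round-trip reflectivity (180° bend) of 50% at
  r = 10 mm and 2% at r = 5 mm, giving $a \approx 95.9$ dB/turn,
  $b \approx 0.346\ \mathrm{mm^{-1}}$. Extrapolated to r = 2.5 mm this
  predicts ≈ 40 dB round trip — consistent with a signal below any
  realistic detection threshold;
* **bend-insensitive (ITU-T G.657.B3 class)** — 0.2 dB/turn one-way at
  r = 5 mm and 95% round-trip reflectivity for a 180° bend at
  r = 2.5 mm, giving $a \approx 0.248$ dB/turn,
  $b \approx 0.043\ \mathrm{mm^{-1}}$.

Interrogation light crosses each bend twice, so received power scales as
$10^{-2L/10}$; partial turns scale linearly in dB and segments add.
Sensitivity scales linearly with delivered power, so the *relative*
sensitivity of a bent fiber equals its round-trip transmission.

A known tension: ultrasonically measured SNR pairs for the
bend-insensitive fiber (≈ 47.7 straight vs ≈ 36.8 bent one turn at 3 mm)
imply ≈ 1.1 dB of round-trip loss, more than the ≈ 0.44 dB the optical
anchors predict at that geometry. The two measurements come from
different bend geometries and are not reconcilable from published
numbers; this package calibrates to the optical (ITF) anchors only and
reports its own simulated SNR contrasts.

### Directivity

The tip sensor is close to omnidirectional: gain 1 within ±165° of the
fiber axis with a raised-cosine roll-off to 0 at ±180°, where the fiber
shadows the cavity. Published directivity information is figure-level
only, so no finer numeric fidelity is claimed, and frequency dependence
is out of scope.

## Acoustic simulation

Each transmit event fires its aperture with focusing delays toward the
electronic focus (5.5 cm by default) along the beam: sector beams pivot
at the aperture centre across the 90° field of view (one line per degree,
91 lines); linear-array beams run parallel to the depth axis from
sub-aperture centres (16 elements by default) stepping across the
aperture, one line per element (128). Delays are referenced so the
earliest element fires at zero, keeping all delays non-negative.

The sensor series for a line is a sum over firing elements of a
Gaussian-enveloped sinusoid (fractional bandwidth 0.6 — a typical
imaging-pulse value; no waveform is published) delayed by the one-way
arrival time and scaled by sensitivity × directivity × 1/r spreading ×
medium attenuation (0 dB/(cm·MHz) by default — deionized water), plus
i.i.d. Gaussian detector noise. `noise_std` is a free parameter: no
physical-unit noise floor is published, so each experiment states its
own signal-to-noise ratio instead.

Deliberate simplifications: no tissue speckle or reverberation, no
elevational physics, no near-field diffraction correction, no motion.
Passing tests therefore demonstrate correctness of the geometry,
bookkeeping and estimators — not robustness to in-vivo clutter, which
real recordings would add on top.

Defaults chosen once and fixed: sample rate 40 MHz (comfortably above
Nyquist for both probes); record length 1.3× the latest possible arrival
over all events and elements, which both covers the full field of view
and guarantees that the deepest 20% of every line is signal-free;
speed of sound 1500 m/s; 100 frames per phantom-style sequence.
Sub-seeds for per-frame noise derive deterministically from one master
seed, so every record is reproducible bit for bit.

## Tracking pipeline

Envelope detection is the magnitude of the FFT analytic signal. One frame
becomes an axial-sample × scanline image; background subtraction removes
the per-image median (clamping at zero) or a recorded reference frame.
Localization then:

1. finds the global maximum (ties break to smallest row, then column);
2. extracts a 100 × 100-pixel region of interest centred there, clipped —
   not padded — at borders;
3. zeroes pixels below 0.70 of the ROI maximum (the published "~70%" is
   implemented as exactly 0.70 and left configurable);
4. returns the intensity-weighted mean pixel coordinate of the
   survivors.

The ROI-local maximum (not the global-frame maximum) is the thresholding
reference, because thresholding follows ROI extraction in the described
processing order; with background subtraction applied first the two
references coincide in practice. Localization runs in
(sample × beam) space and converts to cartesian display coordinates
afterwards — `(x, z) = (r sinθ, r cosθ)` for sector probes, beam origin
and depth for linear ones — with linear interpolation of the beam table
at fractional columns. Sector images can also be fully scan-converted
(bilinear in (r, θ), out-of-sector pixels zero; nearest-neighbour by
flag).

Indexing is R-native (1-based, column-major); physical coordinates never
depend on the convention because row r maps to depth `(r − 1)·c/fs`.

A small, known bias: referencing transmit delays to zero minimum shifts
every arrival by the aperture's focusing path difference, ≈ 52 µm
(≈ 1.4 axial pixels at 40 MHz) for a 16-element, 0.3 mm-pitch aperture
focused at 5.5 cm. Pose-recovery accuracy is therefore assessed against
the combined bound of one axial pixel plus one beam spacing, which the
noiseless pipeline meets with a wide margin for both probe geometries
(50 random poses each in the test suite).

## SNR estimation

SNR (linear scale) is the peak signal over the standard deviation of a
signal-free noise region. Conventions:

* **bench traces** — the peak is the maximum of the envelope of an
  n-repeat average (100 averages by default) inside a ±1 µs gate around
  the predicted arrival; the noise floor is the RF sample std over the
  trailing 20% of the trace, pooled across repeats. Pooling matters: a
  single 160-sample window estimates σ with ≈ 5.6% sampling error, which
  would dominate any bent/straight contrast.
* **tracking images** — the image exists only post-envelope, so the noise
  std is measured on envelope pixels (as the phantom protocol does). The
  automatic noise region is the deepest 20% of rows over all columns at
  least a quarter image-width from the peak column. A single far column
  was considered and rejected at design time: its ≈ 400 samples give the
  noise σ a ≈ 3.5% sampling error, the same order as the 10%
  frame-variation bound being measured; pooling far columns makes the
  noise floor a measurement rather than a noise source. A manual pixel
  rectangle always takes precedence.

Estimator calibration (in the test suite): at true amplitude-to-noise
ratios of 50 and 200 the mean estimate over 1000 seeds is unbiased within
three standard errors. At a ratio of 5 the max-over-gate peak pick has a
small positive bias (Rice mean shift ≈ σ/(2·SNR) plus max statistics,
≈ 0.1–0.3 SNR units here); the tests assert it is positive and below
0.4. Averaging 100 repeats shrinks the peak-estimate spread by ≈ √100.

The bench comparison (`static_bend_snr_experiment`) runs all four
fiber-type × bend-state conditions with common random numbers, so the
noise-floor estimate cancels in contrasts and the bent/straight SNR ratio
converges to the model's round-trip transmission as noise vanishes. A
condition is reported "not detected" when the gated peak stays below five
noise standard deviations — the fate of the standard fiber at tight bend
radii.

The phantom-style experiment (`phantom_frame_experiment`) fixes the
sensor at the focus of the 128-element linear probe, sets the noise so
the noiseless image peak is 200× the noise std, and measures per-frame
SNR over 100 frames; the maximum relative deviation from the mean stays
within the published 10% bound (typically ≈ 2% here, where detector noise
is the only variation source — real acquisitions add motion and
interference variation).

## Problem sizes and numerics

The test suite and acceptance script use: 100-frame sequences at 128
lines × ≈ 2000 samples; 50 random poses per probe geometry for recovery;
1000 seeds per calibration point; 1000 random 20 × 20 images for the CoM
oracle; 150–200 seeds for the averaging law. These sizes put Monte-Carlo
standard errors well inside the asserted tolerances while keeping a full
run around a minute.

Numerical choices: bilinear interpolation for scan conversion (round-trip
relative L2 ≈ 0.2% on a smooth blob, asserted < 2%); pulses evaluated
over a ±5σ support window; a 1 µm distance guard when a pose coincides
with an element; `max(|dR/dφ|)` taken on a 20 001-point phase grid over
one free-spectral range.

## Interfaces and containers

Simulation configs are YAML; ITF scans and tip tables are CSV; images
export to PNG with a JSON geometry sidecar. The multi-frame FOUS record
is a plain R list (per-frame scanline matrix, sample rate, frame/line
trigger indices, full configuration metadata) persisted with R's native
serialization via `write_record()`/`read_record()`. The
`inst/cli/foustrack.R` script exposes `simulate`, `track`, `snr`, `itf`
and `bendloss` subcommands over these functions; every run logs its seed
and a configuration digest.

## Known limitations

* The loss law is a two-anchor exponential per fiber type; it reproduces
  the anchors exactly and interpolates sensibly on 2.5–12.5 mm, but it is
  not a waveguide solution and should not be extrapolated far outside
  that range.
* Element pitch and scanlines-per-frame of the 16-element sector probe
  are not published; 0.3 mm and one line per degree are package defaults.
* The ~30° probe-to-catheter angle of the phantom geometry only enters
  through the directivity gain, which is flat in that range; its effect
  on recorded amplitudes is therefore not modelled beyond that.
* Simulated SNR magnitudes are in arbitrary units tied to the chosen
  `noise_std`; only ratios, variations and localization errors are
  quantitatively meaningful.
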