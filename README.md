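# foustrack

Ultrasonic tracking of a fiber-optic ultrasound sensor (FOUS) — a
Fabry-Pérot cavity on a single-mode fiber tip carried by an
interventional device (e.g. a steerable cardiac catheter) — using a
clinical imaging array in *receive-only* mode. The package is for people
studying fiber-sensor-based device tracking: it simulates the bench and
phantom experiments end to end and implements the analysis that turns raw
per-scanline sensor recordings into tip coordinates and SNR statistics.

## What it computes

**Tracking.** For each transmit event (A-line) of a linear or
phased-sector probe, the sensor receives the pulse after a one-way time
of flight; since the sensor does not echo, depth is `d = c·t` with no
factor ½. The envelope-detected series of all scanlines of one frame are
concatenated into a 2D tracking image, and the tip is localized by a
thresholded, intensity-weighted centre of mass:

- take a 100 × 100-pixel region of interest around the image maximum,
- zero pixels below 70% of the ROI maximum,
- CoM = Σ Iᵢ·(rᵢ, cᵢ) / Σ Iᵢ over the survivors,

then map (sample, beam) to cartesian display coordinates
(`(r sin θ, r cos θ)` for a 90° sector, beam origin and depth for a
linear array). Sector images can also be fully scan-converted.

**Fiber bending.** Sensor sensitivity scales linearly with the optical
power reaching the cavity. Macrobend loss follows
`L(r) = a·e^(−b·r)` dB/turn, calibrated per fiber type from published
reflectivity anchors (standard SMF: 50% round trip at 10 mm, 2% at 5 mm;
bend-insensitive G.657.B3-class: 0.2 dB/turn at 5 mm, 95% round trip at
2.5 mm); interrogation light crosses each bend twice, so received power
goes as `10^(−2L/10)`.

**SNR.** Peak signal over the standard deviation of a signal-free noise
region (linear scale), with n-average peak estimation for bench traces
and per-frame statistics (mean, maximum relative variation) for tracking
sequences.

## Worked example

Track a sensor on a catheter with a bend-insensitive fiber wound one full
turn at 5 mm radius, imaged by a 16-element 90°-sector probe focused at
5.5 cm:

```r
library(foustrack)

fiber <- fiber_spec("bend_insensitive", bend_profile(radius = 5e-3, turns = 1))
bend_loss_db(fiber)            # 0.2  (dB, one-way)
roundtrip_transmission(fiber)  # 0.9120108

probe <- make_probe("phased_sector", n_elements = 16, pitch = 0.3e-3,
                    center_frequency = 6e6, fov_angle = 90,
                    focus_depth = 0.055)
rec <- generate_sequence(5, probe, sensor_pose(x = 0.0326, z = 0.0544),
                         make_medium(), pulse_spec(6e6),
                         noise_std = 0.5, seed = 42, fiber = fiber)
track_sequence(rec)
#>   frame      row     col    x_m    z_m  flag
#> 1     1 1723.984 76.9901 0.0333 0.0554 FALSE
#> 2     2 1723.986 76.9908 0.0333 0.0554 FALSE
#> ...
frame_statistics(sequence_snr(rec))
#> mean SNR 704.2 over 5 frames, max variation 1.2%
```

The tip placed at (3.26, 5.44) cm is recovered at (3.33, 5.54) cm —
within one beam spacing laterally (the 91 beams are 1° apart, ≈ 1.1 mm at
this range) plus the small axial offset of the transmit-focusing delays;
the per-frame SNR varies by ≈ 1% because detector noise is the only
frame-to-frame variation in this simulation. The bend costs 0.2 dB
one-way, i.e. the bent sensor keeps 91.2% of its straight-fiber
sensitivity.

A command-line wrapper covers the same flow
(`inst/cli/foustrack.R simulate|track|snr|itf|bendloss`), e.g.

```sh
Rscript inst/cli/foustrack.R bendloss --fiber bi --radius-mm 5 --turns 1
#> bend_insensitive, 1 turn(s) at 5 mm: 0.2 dB one-way, round-trip transmission 0.912
```

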