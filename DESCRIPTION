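Package: foustrack
Title: Receive-Mode Ultrasonic Tracking of a Fiber-Optic Ultrasound Sensor
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis pipeline for ultrasonic tracking of a
    fiber-optic ultrasound sensor (FOUS) carried on an interventional device
    and localized with a clinical imaging array operating in receive-only
    mode. Models the Fabry-Perot interference transfer function of the
    sensor, macrobend loss in standard and bend-insensitive single-mode
    fiber, linear and phased-sector probe geometries with transmit focusing,
    one-way time-of-flight propagation to a point receiver, tracking-image
    formation by envelope detection and scanline concatenation,
    centre-of-mass tip localization with intensity thresholding, sector scan
    conversion, and peak/noise-floor SNR estimation with per-frame
    statistics. A seeded synthetic-data generator emulates the bench and
    phantom experiments so every stage runs without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
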