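#' Transmit pulse description
#'
#' A Gaussian-enveloped sinusoid: envelope standard deviation in time is
#' set from the fractional bandwidth via the Fourier pair
#' `sigma_f = f0 * bw / (2 sqrt(2 ln 2))`, `sigma_t = 1 / (2 pi sigma_f)`
#' (FWHM convention in the spectral domain).
#'
#' @param center_frequency Hz.
#' @param fractional_bandwidth Dimensionless, in (0, 2).
#' @param amplitude Peak envelope amplitude, arbitrary pressure units.
#' @return An object of class `fous_pulse`.
#' @export
pulse_spec <- function(center_frequency = 3.5e6, fractional_bandwidth = 0.6,
                       amplitude = 1) {
  if (amplitude < 0) stop("'amplitude' must be >= 0")
  if (fractional_bandwidth <= 0 || fractional_bandwidth >= 2)
    stop("'fractional_bandwidth' must lie in (0, 2)")
  sigma_f <- center_frequency * fractional_bandwidth / (2 * sqrt(2 * log(2)))
  structure(list(center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth,
                 amplitude = amplitude,
                 sigma_t = 1 / (2 * pi * sigma_f)),
            class = "fous_pulse")
}

#' @rdname pulse_spec
#' @param pulse A `fous_pulse`.
#' @param t Times in seconds, centred so the envelope peaks at `t = 0`.
#' @export
pulse_waveform <- function(pulse, t) {
  pulse$amplitude * exp(-t^2 / (2 * pulse$sigma_t^2)) *
    cos(2 * pi * pulse$center_frequency * t)
}

# Add a delayed pulse into series `y` (sample rate fs, sample 1 at t = 0),
# evaluating only over the +/- 5 sigma support.
.add_pulse <- function(y, pulse, t0, amp, fs) {
  half <- 5 * pulse$sigma_t
  i0 <- max(1L, floor((t0 - half) * fs) + 1L)
  i1 <- min(length(y), ceiling((t0 + half) * fs) + 1L)
  if (i1 < i0) return(y)
  idx <- i0:i1
  t <- (idx - 1) / fs
  y[idx] <- y[idx] + amp * pulse_waveform(pulse, t - t0)
  y
}

# Amplitude scale for one element -> sensor path: spherical spreading,
# medium attenuation at f0, and sensor directivity for the incidence angle
# between the incoming wave and the fiber axis.
.element_amplitude <- function(ep, sensor, medium, pulse_f0, directivity) {
  dx <- sensor$position["x"] - ep[1]
  dz <- sensor$position["z"] - ep[2]
  d <- sqrt(dx^2 + dz^2)
  d <- max(d, 1e-6)                       # guard: sensor on the element
  wave_angle <- atan2(dx, dz) * 180 / pi  # incoming propagation, from +z
  inc <- wave_angle - sensor$orientation
  inc <- ((inc + 180) %% 360) - 180
  att <- 10^(-medium$attenuation_coeff * (pulse_f0 / 1e6) * (d * 100) / 20)
  g <- directivity_gain(directivity, inc)
  list(amp = g * att / d, dist = d)
}

#' Simulate one tracking frame of FOUS receive data
#'
#' For each transmit event of the probe, the sensor time series is the sum
#' over firing elements of the transmit pulse delayed by the one-way
#' arrival time and scaled by sensor sensitivity (after bend loss),
#' directivity, 1/r spreading and medium attenuation, plus i.i.d. zero-mean
#' Gaussian detector noise. Records one line trigger per scanline and a
#' frame trigger at the start.
#'
#' The record length covers 1.3 x the latest possible arrival so that the
#' deepest part of every scanline is signal-free.
#'
#' @param probe A `fous_probe`.
#' @param sensor A `fous_pose` (z >= 0; an error otherwise).
#' @param medium A `fous_medium`.
#' @param pulse A `fous_pulse`.
#' @param noise_std Detector noise standard deviation, amplitude units.
#' @param seed Integer seed; the same seed reproduces the frame bit for
#'   bit.
#' @param fiber Optional `fous_fiber`; `NULL` means a straight fiber
#'   (transmission 1).
#' @param itf Optional `fous_itf` for sensitivity normalization.
#' @param bend_model A `fous_bend_model`.
#' @param directivity A `fous_directivity`.
#' @param fs Sample rate, Hz.
#' @param subaperture Passed to [enumerate_events()] for linear probes.
#' @return A `fous_record` with one frame: `frames[[1]]$lines` is a
#'   samples x scanlines matrix, with `fs`, `frame_trigger_index` and
#'   0-based `line_trigger_indices` into the concatenated frame stream.
#' @export
generate_frame <- function(probe, sensor, medium, pulse,
                           noise_std = 0, seed = 1L,
                           fiber = NULL, itf = NULL,
                           bend_model = bend_loss_model(),
                           directivity = directivity_model(),
                           fs = 40e6, subaperture = 16L) {
  if (sensor$position["z"] < 0) stop("sensor must be at z >= 0")
  if (noise_std < 0) stop("'noise_std' must be >= 0")
  events <- enumerate_events(probe, medium$speed_of_sound, subaperture)

  transmission <- if (is.null(fiber)) 1 else roundtrip_transmission(fiber, bend_model)
  sens <- if (is.null(itf)) transmission
          else sensor_sensitivity(itf, transmission)

  t_latest <- max(vapply(events, function(ev)
    max(arrival_times(ev, sensor, medium)), numeric(1)))
  n <- as.integer(ceiling(1.3 * (t_latest + 5 * pulse$sigma_t) * fs))

  set.seed(seed)
  lines <- matrix(0, nrow = n, ncol = length(events))
  for (j in seq_along(events)) {
    ev <- events[[j]]
    tt <- arrival_times(ev, sensor, medium)
    y <- numeric(n)
    for (i in seq_along(tt)) {
      ea <- .element_amplitude(ev$element_positions[i, ], sensor, medium,
                               pulse$center_frequency, directivity)
      y <- .add_pulse(y, pulse, tt[i], sens * ea$amp, fs)
    }
    if (noise_std > 0) y <- y + stats::rnorm(n, 0, noise_std)
    lines[, j] <- y
  }

  frame <- list(lines = lines, fs = fs,
                frame_trigger_index = 0L,
                line_trigger_indices = as.integer((seq_along(events) - 1) * n))
  structure(list(frames = list(frame),
                 metadata = list(probe = probe, medium = medium,
                                 sensor = sensor, pulse = pulse,
                                 noise_std = noise_std, seed = seed,
                                 transmission = transmission,
                                 subaperture = subaperture)),
            class = "fous_record")
}

#' Simulate a multi-frame tracking sequence
#'
#' Repeats [generate_frame()] with fresh, deterministically derived noise
#' per frame (sub-seeds drawn from the master seed) and, optionally, small
#' Gaussian jitter of the sensor position between frames.
#'
#' @inheritParams generate_frame
#' @param n_frames Number of frames (>= 1).
#' @param jitter_sd Per-frame standard deviation of sensor position jitter
#'   in metres (0 = rigidly fixed pose).
#' @param ... Passed to [generate_frame()].
#' @return A `fous_record` with `n_frames` frames.
#' @export
generate_sequence <- function(n_frames, probe, sensor, medium, pulse,
                              noise_std = 0, seed = 1L, jitter_sd = 0, ...) {
  if (n_frames < 1) stop("'n_frames' must be >= 1")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_frames)
  jit <- if (jitter_sd > 0)
    matrix(stats::rnorm(2 * n_frames, 0, jitter_sd), ncol = 2)
  else matrix(0, n_frames, 2)

  frames <- vector("list", n_frames)
  meta <- NULL
  for (k in seq_len(n_frames)) {
    pk <- sensor
    pk$position <- pk$position + c(jit[k, 1], jit[k, 2])
    rec <- generate_frame(probe, pk, medium, pulse, noise_std,
                          seed = sub_seeds[k], ...)
    frames[[k]] <- rec$frames[[1]]
    if (is.null(meta)) meta <- rec$metadata
  }
  meta$seed <- seed
  meta$n_frames <- n_frames
  structure(list(frames = frames, metadata = meta), class = "fous_record")
}

#' Simulate the water-tank static-bend bench experiment
#'
#' A planar transducer insonifies the sensor tip at a fixed stand-off in
#' water; the plane-wave arrival appears at `distance / c`. Each repeat is
#' the same deterministic arrival, with amplitude proportional to the
#' sensor sensitivity after bend loss, plus fresh Gaussian noise; repeats
#' can be averaged before peak estimation.
#'
#' @param fiber A `fous_fiber` (its bend profile sets the attenuation).
#' @param itf A `fous_itf`.
#' @param pulse A `fous_pulse` (3.5 MHz bench transducer by default).
#' @param distance Transducer-to-sensor stand-off in metres (> 0).
#' @param medium A `fous_medium`.
#' @param noise_std Noise standard deviation.
#' @param n_repeats Number of repeated traces.
#' @param seed Integer seed.
#' @param bend_model A `fous_bend_model`.
#' @param fs Sample rate, Hz.
#' @return A list of class `fous_bench`: `traces` (samples x repeats),
#'   `fs`, `arrival_time`, `amplitude` (noise-free peak amplitude) and the
#'   configuration.
#' @export
generate_static_bend_experiment <- function(fiber, itf,
                                            pulse = pulse_spec(3.5e6),
                                            distance = 0.022,
                                            medium = make_medium(),
                                            noise_std = 0,
                                            n_repeats = 100,
                                            seed = 1L,
                                            bend_model = bend_loss_model(),
                                            fs = 40e6) {
  if (distance <= 0) stop("'distance' must be > 0")
  t_arr <- distance / medium$speed_of_sound
  n <- as.integer(ceiling(1.3 * (t_arr + 5 * pulse$sigma_t) * fs))
  transmission <- roundtrip_transmission(fiber, bend_model)
  sens <- sensor_sensitivity(itf, transmission)
  clean <- .add_pulse(numeric(n), pulse, t_arr, sens, fs)

  set.seed(seed)
  traces <- matrix(clean, nrow = n, ncol = n_repeats)
  if (noise_std > 0)
    traces <- traces + matrix(stats::rnorm(n * n_repeats, 0, noise_std), n)
  structure(list(traces = traces, fs = fs, arrival_time = t_arr,
                 amplitude = sens * pulse$amplitude,
                 transmission = transmission,
                 fiber = fiber, noise_std = noise_std, seed = seed),
            class = "fous_bench")
}

#' Simulate a wavelength-scan ITF measurement across bend radii
#'
#' Emulates winding the fiber through a 180 degree bend at each radius of
#' the bench protocol (12.5 mm down to 2.5 mm in 2.5 mm steps) and scanning
#' the interrogation wavelength across at least one fringe: each curve is
#' the straight-fiber ITF scaled by the round-trip transmission of that
#' bend.
#'
#' @param fiber_type `"standard_smf"` or `"bend_insensitive"`.
#' @param itf A `fous_itf`.
#' @param wavelength_grid Wavelengths in metres; the default spans > 1
#'   free-spectral range around 1550 nm. Round-trip phase is
#'   `4 pi L_opt / lambda`.
#' @param radii_m Bend radii in metres.
#' @param turns Turns per bend (0.5 = 180 degrees).
#' @param bend_model A `fous_bend_model`.
#' @param include_straight Include the straight-fiber reference curve
#'   (reported with `radius_mm = Inf`).
#' @return Data frame with columns `radius_mm`, `wavelength_nm`,
#'   `phase_rad`, `reflected_power_norm`, `transmission`.
#' @export
generate_itf_scan <- function(fiber_type = c("standard_smf", "bend_insensitive"),
                              itf = itf_model(),
                              wavelength_grid = NULL,
                              radii_m = c(12.5, 10, 7.5, 5, 2.5) * 1e-3,
                              turns = 0.5,
                              bend_model = bend_loss_model(),
                              include_straight = TRUE) {
  fiber_type <- match.arg(fiber_type)
  if (is.null(wavelength_grid)) {
    fsr <- itf$bias_wavelength^2 / (2 * itf$cavity_optical_thickness)
    wavelength_grid <- seq(itf$bias_wavelength - 0.75 * fsr,
                           itf$bias_wavelength + 0.75 * fsr,
                           length.out = 401)
  }
  phase <- 4 * pi * itf$cavity_optical_thickness / wavelength_grid
  if (diff(range(phase)) < 2 * pi)
    stop("wavelength grid must span at least one fringe (2 pi of phase)")
  base <- itf_reflectance(itf, phase)

  radii <- if (include_straight) c(Inf, radii_m) else radii_m
  out <- do.call(rbind, lapply(radii, function(r) {
    tr <- if (is.infinite(r)) 1
          else roundtrip_transmission(
            fiber_spec(fiber_type, bend_profile(radius = r, turns = turns)),
            bend_model)
    data.frame(radius_mm = r * 1e3,
               wavelength_nm = wavelength_grid * 1e9,
               phase_rad = phase,
               reflected_power_norm = base * tr,
               transmission = tr)
  }))
  rownames(out) <- NULL
  out
}
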