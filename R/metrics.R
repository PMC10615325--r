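#' Estimate peak/noise-floor SNR
#'
#' SNR on a linear scale: the peak signal divided by the standard
#' deviation of a signal-free noise region. For repeated bench traces the
#' peak may be taken from the envelope of an n-trace average; the noise
#' floor is always measured on unaveraged data so the reported SNR refers
#' to a single acquisition.
#'
#' For a trace the noise std is measured on the raw (RF) samples of the
#' noise window; for a tracking image, which exists only post-envelope,
#' it is the sample std of the envelope pixels in the noise region.
#'
#' @param x A numeric trace, a samples-x-repeats matrix of traces, a
#'   `fous_bench` bench experiment, or a `fous_tracking_image`.
#' @param noise_roi For traces: integer sample indices of the noise
#'   window (default: the deepest 20% of samples). For images: a list
#'   `list(rows =, cols =)` of pixel indices, or `"auto"` (default) for
#'   the deepest 20% of rows over columns at least a quarter image-width
#'   from the peak column.
#' @param n_averages Number of repeat traces averaged before peak
#'   estimation (1 = no averaging).
#' @param gate Integer sample indices to search for the peak (traces
#'   only); default: the whole trace for plain inputs, +/- 1 us around the
#'   predicted arrival for a `fous_bench`.
#' @param ... Passed between methods.
#' @return A list of class `fous_snr`: `snr`, `peak_value`, `noise_std`,
#'   `noise_roi`, `n_averages`.
#' @export
estimate_snr <- function(x, ...) UseMethod("estimate_snr")

#' @rdname estimate_snr
#' @export
estimate_snr.default <- function(x, noise_roi = NULL, n_averages = 1,
                                 gate = NULL, ...) {
  if (is.matrix(x)) {
    if (n_averages > ncol(x))
      stop("'n_averages' exceeds the number of repeat traces")
    avg <- rowMeans(x[, seq_len(n_averages), drop = FALSE])
    ref <- x
  } else {
    if (n_averages != 1) stop("'n_averages' > 1 needs repeated traces")
    avg <- x
    ref <- x
  }
  n <- length(avg)
  if (is.null(gate)) gate <- seq_len(n)
  if (is.null(noise_roi)) noise_roi <- seq.int(ceiling(0.8 * n) + 1L, n)
  if (length(noise_roi) < 2) stop("noise window is empty or too short")
  if (length(intersect(gate, noise_roi)) > 0)
    stop("noise window overlaps the peak search gate")
  peak <- max(envelope(avg)[gate])
  # noise floor of a single acquisition; pooled over repeats when available
  noise_std <- if (is.matrix(ref))
    stats::sd(as.vector(ref[noise_roi, , drop = FALSE]))
  else stats::sd(ref[noise_roi])
  if (noise_std <= 0) stop("zero noise standard deviation")
  structure(list(snr = peak / noise_std, peak_value = peak,
                 noise_std = noise_std, noise_roi = range(noise_roi),
                 n_averages = n_averages),
            class = "fous_snr")
}

#' @rdname estimate_snr
#' @export
estimate_snr.fous_bench <- function(x, noise_roi = NULL, n_averages = 1,
                                    gate = NULL, gate_halfwidth = 1e-6, ...) {
  if (is.null(gate)) {
    i0 <- max(1L, floor((x$arrival_time - gate_halfwidth) * x$fs) + 1L)
    i1 <- min(nrow(x$traces),
              ceiling((x$arrival_time + gate_halfwidth) * x$fs) + 1L)
    gate <- i0:i1
  }
  estimate_snr.default(x$traces, noise_roi = noise_roi,
                       n_averages = n_averages, gate = gate)
}

#' @rdname estimate_snr
#' @export
estimate_snr.fous_tracking_image <- function(x, noise_roi = "auto", ...) {
  img <- unclass(x)
  peak <- max(img)
  hits <- which(img == peak, arr.ind = TRUE)
  pr <- hits[1, 1]; pc <- hits[1, 2]
  if (identical(noise_roi, "auto")) noise_roi <- auto_noise_roi(x)
  stopifnot(is.list(noise_roi), all(c("rows", "cols") %in% names(noise_roi)))
  # peak ROI: the tracker's default 100x100 neighbourhood of the maximum
  if (any(abs(noise_roi$rows - pr) <= 50) && any(abs(noise_roi$cols - pc) <= 50))
    stop("noise region overlaps the peak region of interest")
  noise_std <- stats::sd(img[noise_roi$rows, noise_roi$cols])
  if (noise_std <= 0) stop("zero noise standard deviation")
  structure(list(snr = peak / noise_std, peak_value = peak,
                 noise_std = noise_std,
                 noise_roi = noise_roi, n_averages = 1L),
            class = "fous_snr")
}

#' Automatic signal-free noise region of a tracking image
#'
#' Deepest `depth_fraction` of rows, restricted to columns at least
#' `guard_fraction` of the image width away from the peak column. The
#' simulator sizes records past the latest possible arrival, so these deep
#' rows carry noise only; pooling many far columns keeps the sampling
#' error of the noise-floor std well below the frame-to-frame SNR
#' variation being measured.
#'
#' @param image Tracking image (matrix).
#' @param depth_fraction Fraction of deepest rows used.
#' @param guard_fraction Minimum peak-to-column distance as a fraction of
#'   image width.
#' @return `list(rows =, cols =)` of pixel indices.
#' @export
auto_noise_roi <- function(image, depth_fraction = 0.2,
                           guard_fraction = 0.25) {
  img <- unclass(image)
  pc <- which(img == max(img), arr.ind = TRUE)[1, 2]
  nr <- nrow(img); nc <- ncol(img)
  rows <- seq.int(ceiling((1 - depth_fraction) * nr) + 1L, nr)
  cols <- which(abs(seq_len(nc) - pc) >= guard_fraction * nc)
  if (length(cols) == 0) cols <- setdiff(seq_len(nc), pc)
  list(rows = rows, cols = cols)
}

#' Per-frame SNR of a tracking sequence
#'
#' @param record A `fous_record`.
#' @param noise_roi Passed to [estimate_snr()] (default `"auto"`).
#' @return Numeric vector, one SNR per frame.
#' @export
sequence_snr <- function(record, noise_roi = "auto") {
  vapply(seq_along(record$frames), function(k) {
    img <- build_tracking_image(record, k)
    estimate_snr(img, noise_roi = noise_roi)$snr
  }, numeric(1))
}

#' Summary statistics over per-frame SNR values
#'
#' @param snr Numeric vector of per-frame SNR values (>= 1 value).
#' @return A list of class `fous_frame_stats`: `mean_snr`,
#'   `max_relative_variation` (`max |SNR_i - mean| / mean`), `n_frames`.
#' @export
frame_statistics <- function(snr) {
  if (length(snr) == 0) stop("need at least one SNR value")
  m <- mean(snr)
  structure(list(mean_snr = m,
                 max_relative_variation = max(abs(snr - m)) / m,
                 n_frames = length(snr)),
            class = "fous_frame_stats")
}

#' @export
print.fous_frame_stats <- function(x, ...) {
  cat(sprintf("mean SNR %.1f over %d frames, max variation %.1f%%\n",
              x$mean_snr, x$n_frames, 100 * x$max_relative_variation))
  invisible(x)
}

#' Run the static-bend SNR comparison
#'
#' Simulates the water-tank bench protocol for both fiber types in the
#' straight and bent states (default: wound one full turn at 3 mm radius,
#' the bench's 6 mm post), estimates the SNR of each with the
#' configured number of averages, and reports whether a signal was
#' detected at all (peak above `detect_factor` times the noise floor).
#' In the noiseless limit the bent/straight SNR ratio equals the model's
#' round-trip transmission exactly.
#'
#' @param noise_std Detector noise std (amplitude units; the default puts
#'   the straight-fiber SNR near the bench scale of ~50).
#' @param bend Bend profile of the bent state.
#' @param n_repeats,n_averages Repeats simulated / averaged for the peak.
#' @param seed Master seed.
#' @param itf,pulse,medium,bend_model Component models.
#' @param distance Transducer stand-off (m).
#' @param detect_factor Peak-to-noise-std ratio below which the state is
#'   reported as not detected.
#' @return Data frame: `fiber_type`, `bend_state`, `snr`, `peak`,
#'   `noise_std`, `transmission`, `detected`.
#' @export
static_bend_snr_experiment <- function(noise_std = 0.02,
                                       bend = bend_profile(radius = 3e-3,
                                                           turns = 1),
                                       n_repeats = 100, n_averages = 100,
                                       seed = 1L,
                                       itf = itf_model(),
                                       pulse = pulse_spec(3.5e6),
                                       medium = make_medium(),
                                       distance = 0.022,
                                       bend_model = bend_loss_model(),
                                       detect_factor = 5) {
  grid <- expand.grid(fiber_type = c("standard_smf", "bend_insensitive"),
                      bend_state = c("straight", "bent"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ft <- grid$fiber_type[i]
    bp <- if (grid$bend_state[i] == "bent") bend else NULL
    fiber <- fiber_spec(ft, bp)
    # common random numbers across conditions: the noise-floor estimate
    # cancels in bent/straight contrasts, so the ratio converges to the
    # model transmission in the low-noise limit
    bench <- generate_static_bend_experiment(
      fiber, itf, pulse, distance, medium, noise_std,
      n_repeats = n_repeats, seed = seed, bend_model = bend_model)
    rep <- estimate_snr(bench, n_averages = min(n_averages, n_repeats))
    data.frame(fiber_type = ft, bend_state = grid$bend_state[i],
               snr = rep$snr, peak = rep$peak_value,
               noise_std = rep$noise_std,
               transmission = bench$transmission,
               detected = rep$peak_value > detect_factor * rep$noise_std)
  })
  do.call(rbind, rows)
}

#' Phantom-style frame-to-frame SNR variation experiment
#'
#' Emulates the cardiac-phantom tracking acquisition: a fixed sensor pose
#' at the probe focus, `n_frames` frames with fresh detector noise, noise
#' level set so the noiseless tracking-image peak is `target_snr` times
#' the noise std. Frames are simulated one at a time (sub-seeds drawn
#' from the master seed, matching [generate_sequence()]) and reduced to a
#' per-frame SNR with the automatic noise region.
#'
#' @param seed Master seed.
#' @param n_frames Number of frames (100 in the phantom protocol).
#' @param probe A `fous_probe`; defaults to the 128-element linear array.
#' @param sensor Fixed pose; defaults to the focus depth on a central
#'   beam.
#' @param target_snr Ratio of noiseless peak amplitude to noise std.
#' @param pulse,medium Component models.
#' @return A list: `snr` (per-frame vector), `stats`
#'   (a `fous_frame_stats`), `noise_std`.
#' @export
phantom_frame_experiment <- function(seed = 1L, n_frames = 100,
                                     probe = NULL, sensor = NULL,
                                     target_snr = 200,
                                     pulse = pulse_spec(6e6),
                                     medium = make_medium()) {
  if (is.null(probe))
    probe <- make_probe("linear", 128, 0.3e-3, 6e6, focus_depth = 0.055)
  if (is.null(sensor)) sensor <- sensor_pose(x = 0, z = probe$focus_depth)

  clean <- generate_frame(probe, sensor, medium, pulse, noise_std = 0,
                          seed = 1L)
  peak0 <- max(build_tracking_image(clean))
  noise_std <- peak0 / target_snr

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_frames)
  snr <- vapply(seq_len(n_frames), function(k) {
    rec <- generate_frame(probe, sensor, medium, pulse,
                          noise_std = noise_std, seed = sub_seeds[k])
    estimate_snr(build_tracking_image(rec))$snr
  }, numeric(1))
  list(snr = snr, stats = frame_statistics(snr), noise_std = noise_std)
}
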