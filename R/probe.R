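#' Define an imaging-probe model
#'
#' Constructs a validated description of a clinical imaging array. Two
#' geometries are supported: a linear array whose beams run parallel to the
#' depth axis, one beam per scanline origin across the aperture, and a
#' phased sector array whose beams pivot at the aperture centre and fan out
#' over `fov_angle`.
#'
#' The coordinate frame has its origin at the aperture centre on the probe
#' face, `x` lateral and `z` increasing with depth; beam angles are measured
#' from the +z axis. Element positions span `(n_elements - 1) * pitch`
#' centred on the origin.
#'
#' @param kind `"linear"` or `"phased_sector"`.
#' @param n_elements Number of array elements (>= 1).
#' @param pitch Element centre-to-centre spacing in metres.
#' @param center_frequency Transmit centre frequency in Hz.
#' @param fractional_bandwidth Pulse fractional bandwidth (dimensionless).
#' @param fov_angle Sector field-of-view in degrees, in (0, 180]. Required
#'   for (and only meaningful for) sector probes.
#' @param focus_depth Electronic transmit focus depth in metres.
#' @param n_scanlines Scanlines per frame. Defaults to `n_elements` for a
#'   linear probe (one line per element) and to one line per degree of
#'   field of view (91 for a 90 degree sector).
#' @return An object of class `fous_probe`.
#' @examples
#' tee <- make_probe("phased_sector", n_elements = 16, pitch = 0.3e-3,
#'                   center_frequency = 6e6, fov_angle = 90,
#'                   focus_depth = 0.055)
#' lap <- make_probe("linear", n_elements = 128, pitch = 0.3e-3,
#'                   center_frequency = 6e6, focus_depth = 0.055)
#' @export
make_probe <- function(kind = c("linear", "phased_sector"),
                       n_elements,
                       pitch,
                       center_frequency,
                       fractional_bandwidth = 0.6,
                       fov_angle = NULL,
                       focus_depth = 0.055,
                       n_scanlines = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(n_elements) || n_elements < 1 || n_elements != round(n_elements))
    stop("'n_elements' must be a positive integer")
  if (!is.numeric(pitch) || pitch <= 0)
    stop("'pitch' must be > 0")
  if (!is.numeric(center_frequency) || center_frequency <= 0)
    stop("'center_frequency' must be > 0")
  if (!is.numeric(focus_depth) || focus_depth <= 0)
    stop("'focus_depth' must be > 0")
  if (!is.numeric(fractional_bandwidth) || fractional_bandwidth <= 0 ||
      fractional_bandwidth >= 2)
    stop("'fractional_bandwidth' must lie in (0, 2)")
  if (kind == "phased_sector") {
    if (is.null(fov_angle))
      stop("'fov_angle' is required for a phased_sector probe")
    if (fov_angle <= 0 || fov_angle > 180)
      stop("'fov_angle' must lie in (0, 180]")
  } else {
    fov_angle <- NULL
  }
  if (is.null(n_scanlines)) {
    n_scanlines <- if (kind == "linear") as.integer(n_elements)
                   else as.integer(round(fov_angle)) + 1L
  }
  if (n_scanlines < 1) stop("'n_scanlines' must be >= 1")

  n_elements <- as.integer(n_elements)
  x <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch
  structure(
    list(kind = kind,
         n_elements = n_elements,
         pitch = pitch,
         center_frequency = center_frequency,
         fractional_bandwidth = fractional_bandwidth,
         fov_angle = fov_angle,
         focus_depth = focus_depth,
         n_scanlines = as.integer(n_scanlines),
         element_x = x),
    class = "fous_probe")
}

#' @export
print.fous_probe <- function(x, ...) {
  cat(sprintf("<fous_probe> %s, %d elements, pitch %.3g mm, f0 %.3g MHz\n",
              x$kind, x$n_elements, x$pitch * 1e3, x$center_frequency / 1e6))
  if (!is.null(x$fov_angle))
    cat(sprintf("  fov %g deg, ", x$fov_angle))
  cat(sprintf("  focus %.3g cm, %d scanlines/frame\n",
              x$focus_depth * 1e2, x$n_scanlines))
  invisible(x)
}

#' Define an acoustic medium
#'
#' @param speed_of_sound Speed of sound in m/s (> 0). 1500 m/s is the
#'   conventional value for water / soft-tissue phantoms.
#' @param attenuation_coeff Amplitude attenuation in dB/(cm MHz); 0 for
#'   deionized water.
#' @return An object of class `fous_medium`.
#' @export
make_medium <- function(speed_of_sound = 1500, attenuation_coeff = 0) {
  if (!is.numeric(speed_of_sound) || speed_of_sound <= 0)
    stop("'speed_of_sound' must be > 0")
  if (attenuation_coeff < 0) stop("'attenuation_coeff' must be >= 0")
  structure(list(speed_of_sound = speed_of_sound,
                 attenuation_coeff = attenuation_coeff),
            class = "fous_medium")
}

#' Define the pose of the point sensor in the probe frame
#'
#' @param x,z Sensor position in metres; `z >= 0` is depth away from the
#'   probe face.
#' @param orientation Angle (degrees) of the fiber axis relative to the +z
#'   axis; sets the incidence angle used by the directivity model.
#' @param in_plane Whether the sensor lies in the imaging plane.
#' @return An object of class `fous_pose`.
#' @export
sensor_pose <- function(x = 0, z = 0.055, orientation = 0, in_plane = TRUE) {
  if (z < 0) stop("sensor 'z' must be >= 0 (behind the probe face)")
  structure(list(position = c(x = x, z = z), orientation = orientation,
                 in_plane = in_plane),
            class = "fous_pose")
}

# Transmit-focusing delays for element x-positions `ex` (on the probe face,
# z = 0) and focal point `fp`, referenced so the minimum delay is zero.
.focus_delays <- function(ex, fp, c0) {
  d <- sqrt((ex - fp[1])^2 + fp[2]^2)
  (max(d) - d) / c0
}

#' Enumerate the transmit events of one imaging frame
#'
#' One event per scanline. Sector beams originate at the aperture centre at
#' angles evenly spaced across the field of view; linear-probe beams run
#' parallel to the depth axis from per-line sub-aperture centres stepping
#' across the aperture. Element delays implement transmit focusing at the
#' probe focus depth along each beam, referenced so the earliest element
#' fires at delay 0.
#'
#' @param probe A `fous_probe`.
#' @param speed_of_sound Speed of sound (m/s) used to convert focusing path
#'   differences to delays.
#' @param subaperture For linear probes, number of elements fired per line
#'   (clipped at the array ends). Sector probes always fire the full array.
#' @return List of `n_scanlines` events; each has `line_index` (0-based),
#'   `origin`, `direction`, `angle` (degrees from +z), `element_positions`
#'   (k x 2 matrix) and `element_delays` (seconds, min 0).
#' @export
enumerate_events <- function(probe, speed_of_sound = 1500, subaperture = 16L) {
  stopifnot(inherits(probe, "fous_probe"))
  n <- probe$n_scanlines
  events <- vector("list", n)
  if (probe$kind == "phased_sector") {
    half <- probe$fov_angle / 2
    angles <- if (n == 1) 0 else seq(-half, half, length.out = n)
    for (j in seq_len(n)) {
      a <- angles[j] * pi / 180
      dirv <- c(sin(a), cos(a))
      fp <- probe$focus_depth * dirv
      events[[j]] <- list(
        line_index = j - 1L,
        origin = c(0, 0),
        direction = dirv,
        angle = angles[j],
        element_positions = cbind(probe$element_x, 0),
        element_delays = .focus_delays(probe$element_x, fp, speed_of_sound))
    }
  } else {
    ap <- range(probe$element_x)
    origins <- if (n == 1) mean(ap) else seq(ap[1], ap[2], length.out = n)
    k <- min(as.integer(subaperture), probe$n_elements)
    for (j in seq_len(n)) {
      ord <- order(abs(probe$element_x - origins[j]), probe$element_x)
      sel <- sort(ord[seq_len(k)])
      ex <- probe$element_x[sel]
      fp <- c(origins[j], probe$focus_depth)
      events[[j]] <- list(
        line_index = j - 1L,
        origin = c(origins[j], 0),
        direction = c(0, 1),
        angle = 0,
        element_positions = cbind(ex, 0),
        element_delays = .focus_delays(ex, fp, speed_of_sound))
    }
  }
  events
}

#' Beam angles (sector) or lateral origins (linear) of a probe's scanlines
#'
#' @param probe A `fous_probe`.
#' @return Numeric vector of length `n_scanlines`: beam angles in degrees
#'   for a sector probe, beam origin x-coordinates in metres for a linear
#'   probe.
#' @export
beam_table <- function(probe) {
  stopifnot(inherits(probe, "fous_probe"))
  n <- probe$n_scanlines
  if (probe$kind == "phased_sector") {
    half <- probe$fov_angle / 2
    if (n == 1) 0 else seq(-half, half, length.out = n)
  } else {
    ap <- range(probe$element_x)
    if (n == 1) mean(ap) else seq(ap[1], ap[2], length.out = n)
  }
}

#' One-way arrival times from a transmit event at a point sensor
#'
#' For each firing element, the arrival time is its transmit delay plus the
#' element-to-sensor path over the speed of sound. The sensor is a receiver,
#' not a reflector, so times are one-way. The minimum over elements is the
#' first arrival.
#'
#' @param event One element of [enumerate_events()].
#' @param sensor A `fous_pose`.
#' @param medium A `fous_medium`.
#' @return Numeric vector of per-element arrival times in seconds.
#' @export
arrival_times <- function(event, sensor, medium) {
  if (medium$speed_of_sound <= 0) stop("speed of sound must be > 0")
  if (sensor$position["z"] < 0) stop("sensor must have z >= 0")
  ep <- event$element_positions
  d <- sqrt((ep[, 1] - sensor$position["x"])^2 +
            (ep[, 2] - sensor$position["z"])^2)
  unname(event$element_delays + d / medium$speed_of_sound)
}

#' Map a one-way time of flight to distance, and back
#'
#' Receive-only convention: the sensor does not echo, so the mapping is
#' `d = c * t` with no factor of one half.
#'
#' @param t Time(s) of flight in seconds (>= 0).
#' @param medium A `fous_medium`.
#' @return Distance(s) in metres.
#' @export
tof_to_depth <- function(t, medium) {
  if (any(t < 0)) stop("time of flight must be >= 0")
  medium$speed_of_sound * t
}

#' @rdname tof_to_depth
#' @param d Distance(s) in metres (>= 0).
#' @export
depth_to_tof <- function(d, medium) {
  if (any(d < 0)) stop("depth must be >= 0")
  d / medium$speed_of_sound
}

#' Specify a cartesian display grid
#'
#' @param x_range,z_range Extents in metres (`z` is depth).
#' @param pixel_size Pixel edge in metres.
#' @return A `fous_grid` object with precomputed pixel-centre axes.
#' @export
grid_spec <- function(x_range, z_range, pixel_size) {
  if (pixel_size <= 0) stop("'pixel_size' must be > 0")
  structure(list(
    x = seq(x_range[1], x_range[2], by = pixel_size),
    z = seq(z_range[1], z_range[2], by = pixel_size),
    pixel_size = pixel_size), class = "fous_grid")
}

#' Scan-convert a sector (polar) image to cartesian coordinates
#'
#' The polar image is indexed (range sample, beam index); beams are at the
#' angles of [beam_table()]. Every output pixel takes the interpolated polar
#' value at `r = sqrt(x^2 + z^2)`, `theta = atan2(x, z)`; pixels outside the
#' sector or beyond the sampled range are zero.
#'
#' @param polar_image Matrix, rows = range samples, cols = beams.
#' @param probe A sector `fous_probe` (needs `fov_angle`).
#' @param grid A `fous_grid` from [grid_spec()].
#' @param range_spacing Radial sample spacing in metres (`c / fs` for a
#'   tracking image).
#' @param range_origin Range of the first row, metres (default 0).
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return Matrix with `length(grid$z)` rows and `length(grid$x)` columns;
#'   attributes `x` and `z` hold the pixel-centre axes.
#' @export
scan_convert_sector <- function(polar_image, probe, grid, range_spacing,
                                range_origin = 0,
                                method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is.matrix(polar_image), inherits(grid, "fous_grid"))
  if (is.null(probe$fov_angle))
    stop("scan conversion requires a sector probe with 'fov_angle'")
  if (ncol(polar_image) != probe$n_scanlines)
    stop("polar image must have one column per scanline")
  angles <- beam_table(probe)
  rr <- range_origin + (seq_len(nrow(polar_image)) - 1) * range_spacing

  px <- rep(grid$x, each = length(grid$z))
  pz <- rep(grid$z, times = length(grid$x))
  r <- sqrt(px^2 + pz^2)
  th <- atan2(px, pz) * 180 / pi

  inside <- th >= angles[1] & th <= angles[length(angles)] &
            r >= rr[1] & r <= rr[length(rr)]
  vals <- numeric(length(r))
  if (any(inside)) {
    # interp2 treats x as columns, y as rows
    vals[inside] <- pracma::interp2(x = angles, y = rr, Z = polar_image,
                                    xp = th[inside], yp = r[inside],
                                    method = if (method == "bilinear")
                                               "linear" else "nearest")
  }
  vals[is.na(vals)] <- 0
  out <- matrix(vals, nrow = length(grid$z), ncol = length(grid$x))
  attr(out, "x") <- grid$x
  attr(out, "z") <- grid$z
  out
}
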