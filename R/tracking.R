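#' Envelope detection via the analytic signal
#'
#' Magnitude of the FFT-based analytic signal (Hilbert envelope): the
#' negative-frequency half of the spectrum is zeroed, positive frequencies
#' doubled, and the modulus of the inverse transform returned. The result
#' is non-negative and bounds `|x|` at every sample.
#'
#' @param x Finite numeric vector (one RF A-line).
#' @return Non-negative numeric vector of the same length.
#' @export
envelope <- function(x) {
  if (!all(is.finite(x))) stop("input must be finite")
  n <- length(x)
  if (n == 0) return(numeric(0))
  if (n == 1) return(abs(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Tracker configuration
#'
#' @param roi_size Region-of-interest size in pixels, `c(rows, cols)`;
#'   100 x 100 by default.
#' @param threshold_fraction Pixels below this fraction of the ROI maximum
#'   are zeroed before the centre-of-mass; in (0, 1), default 0.70.
#' @param background_method `"median"` (subtract the per-image median) or
#'   `"reference"` (subtract a recorded signal-free frame).
#' @param envelope_method Only `"hilbert"` is implemented.
#' @return An object of class `fous_tracker_config`.
#' @export
tracker_config <- function(roi_size = c(100L, 100L),
                           threshold_fraction = 0.70,
                           background_method = c("median", "reference"),
                           envelope_method = "hilbert") {
  if (length(roi_size) == 1) roi_size <- rep(roi_size, 2)
  if (any(roi_size < 1)) stop("'roi_size' must be >= 1 in both dimensions")
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("'threshold_fraction' must lie in (0, 1)")
  structure(list(roi_size = as.integer(roi_size),
                 threshold_fraction = threshold_fraction,
                 background_method = match.arg(background_method),
                 envelope_method = envelope_method),
            class = "fous_tracker_config")
}

#' Form the 2D tracking image of one frame
#'
#' Concatenates the envelope-detected sensor time series of every scanline
#' into a 2D image: column j is scanline j, row r maps to one-way depth
#' `(r - 1) * c / fs`.
#'
#' @param record A `fous_record`.
#' @param frame_index Which frame (1-based).
#' @param medium A `fous_medium`; defaults to the one in the record
#'   metadata.
#' @return A matrix of class `fous_tracking_image` with attributes
#'   `axial_spacing` (m/pixel), `fs`, `probe` and `frame_index`.
#' @export
build_tracking_image <- function(record, frame_index = 1,
                                 medium = record$metadata$medium) {
  stopifnot(inherits(record, "fous_record"))
  fr <- record$frames[[frame_index]]
  lines <- fr$lines
  if (is.list(lines)) {
    len <- lengths(lines)
    if (length(unique(len)) > 1)
      stop("ragged scanline lengths: all series in a frame must match")
    lines <- do.call(cbind, lines)
  }
  img <- apply(lines, 2, envelope)
  structure(img,
            axial_spacing = medium$speed_of_sound / fr$fs,
            fs = fr$fs,
            probe = record$metadata$probe,
            frame_index = frame_index,
            class = c("fous_tracking_image", "matrix", "array"))
}

#' Background subtraction
#'
#' Default: subtract the per-image median and clamp at zero (offset
#' invariant). Alternatively subtract a recorded signal-free reference
#' frame of identical shape.
#'
#' @param image Tracking image (matrix).
#' @param config A `fous_tracker_config`.
#' @param reference Reference image, required when
#'   `background_method = "reference"`.
#' @return Matrix of the same shape, attributes preserved.
#' @export
background_subtract <- function(image, config = tracker_config(),
                                reference = NULL) {
  if (config$background_method == "reference" || !is.null(reference)) {
    if (is.null(reference)) stop("reference frame required")
    if (!all(dim(reference) == dim(image)))
      stop("reference frame shape mismatch")
    out <- pmax(image - reference, 0)
  } else {
    out <- pmax(image - stats::median(image), 0)
  }
  attributes(out) <- attributes(image)
  out
}

#' Localize the sensor tip by thresholded centre of mass
#'
#' Finds the global maximum pixel, extracts a `roi_size` window centred on
#' it (clipped at the image borders), zeroes pixels below
#' `threshold_fraction` times the ROI maximum, and returns the
#' intensity-weighted mean pixel coordinate of the survivors. Ties among
#' equal maxima break to the smallest row, then smallest column.
#'
#' @param image Tracking image (matrix, non-negative); must have a
#'   strictly positive maximum.
#' @param config A `fous_tracker_config`.
#' @return A list of class `fous_tip`: fractional `row` and `col` (1-based
#'   pixel coordinates), `roi_bounds` (`rmin, rmax, cmin, cmax`), plus
#'   physical coordinates via [map_to_display()] when probe geometry is
#'   attached.
#' @export
localize_tip <- function(image, config = tracker_config()) {
  m <- max(image)
  if (!is.finite(m) || m <= 0)
    stop("no signal: image has no strictly positive maximum")
  # row-major first occurrence: smallest row, then smallest column
  hits <- which(image == m, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  pr <- hits[1, 1]; pc <- hits[1, 2]

  hr <- config$roi_size[1] %/% 2
  hc <- config$roi_size[2] %/% 2
  rmin <- max(1L, pr - hr); rmax <- min(nrow(image), pr - hr + config$roi_size[1] - 1L)
  cmin <- max(1L, pc - hc); cmax <- min(ncol(image), pc - hc + config$roi_size[2] - 1L)
  roi <- image[rmin:rmax, cmin:cmax, drop = FALSE]

  thr <- config$threshold_fraction * max(roi)
  roi[roi < thr] <- 0
  w <- sum(roi)
  rows <- rmin:rmax
  cols <- cmin:cmax
  com_r <- sum(rowSums(roi) * rows) / w
  com_c <- sum(colSums(roi) * cols) / w

  structure(list(row = com_r, col = com_c,
                 peak = c(row = pr, col = pc),
                 roi_bounds = c(rmin = rmin, rmax = rmax,
                                cmin = cmin, cmax = cmax),
                 axial_spacing = attr(image, "axial_spacing"),
                 probe = attr(image, "probe"),
                 frame_index = attr(image, "frame_index")),
            class = "fous_tip")
}

#' Map a tip estimate to cartesian display coordinates
#'
#' Linear probe: `x` is the beam lateral origin at the (fractional) column,
#' `z` the depth of the (fractional) row. Sector probe: the column maps to
#' a beam angle theta and `(x, z) = (r sin theta, r cos theta)` with `r`
#' the one-way range of the row.
#'
#' @param tip A `fous_tip`.
#' @param probe A `fous_probe`; defaults to the one attached to the tip.
#' @return Named numeric `c(x, z)` in metres.
#' @export
map_to_display <- function(tip, probe = tip$probe) {
  if (is.null(probe)) stop("no probe geometry available")
  if (is.null(tip$axial_spacing)) stop("tip estimate lacks axial spacing")
  beams <- beam_table(probe)
  if (tip$col < 1 || tip$col > length(beams))
    stop("column outside the beam table")
  # linear interpolation for fractional columns
  bv <- if (length(beams) == 1) beams
        else stats::approx(seq_along(beams), beams, xout = tip$col)$y
  r <- (tip$row - 1) * tip$axial_spacing
  if (probe$kind == "phased_sector") {
    a <- bv * pi / 180
    c(x = r * sin(a), z = r * cos(a))
  } else {
    c(x = bv, z = r)
  }
}

#' Track the sensor tip across a recorded sequence
#'
#' Applies background subtraction and centre-of-mass localization to every
#' frame. Frames where localization fails (e.g. an all-zero image) are
#' flagged, not dropped.
#'
#' @param record A `fous_record` with >= 1 frame.
#' @param config A `fous_tracker_config`.
#' @param medium Medium used for the depth axis; defaults to the record's.
#' @return Data frame with one row per frame: `frame`, `row`, `col`,
#'   `x_m`, `z_m`, `flag` (TRUE when localization failed).
#' @export
track_sequence <- function(record, config = tracker_config(),
                           medium = record$metadata$medium) {
  stopifnot(inherits(record, "fous_record"))
  if (length(record$frames) == 0) stop("record has no frames")
  out <- lapply(seq_along(record$frames), function(k) {
    img <- build_tracking_image(record, k, medium)
    img <- background_subtract(img, config)
    tip <- tryCatch(localize_tip(img, config), error = function(e) NULL)
    if (is.null(tip))
      return(data.frame(frame = k, row = NA_real_, col = NA_real_,
                        x_m = NA_real_, z_m = NA_real_, flag = TRUE))
    xz <- map_to_display(tip)
    data.frame(frame = k, row = tip$row, col = tip$col,
               x_m = unname(xz["x"]), z_m = unname(xz["z"]), flag = FALSE)
  })
  do.call(rbind, out)
}
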