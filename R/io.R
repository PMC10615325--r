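#' Read a simulation configuration from YAML
#'
#' The schema mirrors the constructors. Top-level keys:
#' \describe{
#'   \item{probe}{`kind`, `n_elements`, `pitch_m`, `f0_hz`, `bw`
#'     (fractional bandwidth), `fov_deg` (sector only), `focus_m`,
#'     `n_lines` (optional).}
#'   \item{sensor}{`x_m`, `z_m`, `orientation_deg`.}
#'   \item{medium}{`c_m_s`, `att_db_cm_mhz`.}
#'   \item{pulse}{`f0_hz`, `bw`, `amplitude`.}
#'   \item{fiber}{`type` and `bends`: list of `{radius_mm, turns}`
#'     entries. Omit for a straight fiber.}
#'   \item{noise_std, n_frames, seed, fs_hz}{Scalars.}
#' }
#' Lengths are metres except where the key says otherwise (radii in mm at
#' this boundary, matching how bench protocols are written down).
#'
#' @param path YAML file path.
#' @return A list of constructed model objects plus scalar settings.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$probe)) stop("config missing 'probe' section")
  # tolerate numbers YAML leaves as strings ("6.0e6")
  num <- function(v, default = NULL) {
    if (is.null(v)) default else as.numeric(v)
  }
  p <- cfg$probe
  probe <- make_probe(kind = p$kind,
                      n_elements = num(p$n_elements),
                      pitch = num(p$pitch_m),
                      center_frequency = num(p$f0_hz),
                      fractional_bandwidth = num(p$bw, 0.6),
                      fov_angle = num(p$fov_deg),
                      focus_depth = num(p$focus_m, 0.055),
                      n_scanlines = num(p$n_lines))
  s <- cfg$sensor
  sensor <- if (is.null(s)) sensor_pose()
            else sensor_pose(x = num(s$x_m, 0), z = num(s$z_m, 0.055),
                             orientation = num(s$orientation_deg, 0))
  m <- cfg$medium
  medium <- if (is.null(m)) make_medium()
            else make_medium(speed_of_sound = num(m$c_m_s, 1500),
                             attenuation_coeff = num(m$att_db_cm_mhz, 0))
  pu <- cfg$pulse
  pulse <- if (is.null(pu)) pulse_spec(probe$center_frequency)
           else pulse_spec(center_frequency = num(pu$f0_hz,
                                                  probe$center_frequency),
                           fractional_bandwidth = num(pu$bw, 0.6),
                           amplitude = num(pu$amplitude, 1))
  fiber <- NULL
  if (!is.null(cfg$fiber)) {
    bends <- cfg$fiber$bends
    bp <- if (is.null(bends)) NULL
          else bend_profile(radius = vapply(bends, function(b)
                              as.numeric(b$radius_mm), 0) * 1e-3,
                            turns = vapply(bends, function(b)
                              as.numeric(b$turns), 0))
    fiber <- fiber_spec(cfg$fiber$type, bp)
  }
  list(probe = probe, sensor = sensor, medium = medium, pulse = pulse,
       fiber = fiber,
       noise_std = num(cfg$noise_std, 0),
       n_frames = if (is.null(cfg$n_frames)) 1L else as.integer(num(cfg$n_frames)),
       seed = if (is.null(cfg$seed)) 1L else as.integer(num(cfg$seed)),
       fs = num(cfg$fs_hz, 40e6))
}

#' Save / load a FOUS record
#'
#' The record is a plain R list (frames of scanline series plus trigger
#' and configuration metadata) and is persisted with R's native
#' serialization.
#'
#' @param record A `fous_record`.
#' @param path File path.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "fous_record"))
  saveRDS(record, path)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  rec <- readRDS(path)
  if (!inherits(rec, "fous_record")) stop("not a FOUS record file")
  rec
}

#' Write / read ITF scan curves as CSV
#'
#' Columns: `radius_mm`, `wavelength_nm`, `phase_rad`,
#' `reflected_power_norm`, `transmission`.
#'
#' @param scan Data frame from [generate_itf_scan()].
#' @param path CSV path.
#' @export
write_itf_csv <- function(scan, path) {
  utils::write.csv(scan, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_itf_csv
#' @export
read_itf_csv <- function(path) {
  utils::read.csv(path)
}

#' Write a per-frame tip table as CSV
#'
#' @param tips Data frame from [track_sequence()].
#' @param path CSV path.
#' @export
write_tip_csv <- function(tips, path) {
  utils::write.csv(tips, path, row.names = FALSE)
  invisible(path)
}

#' Write an image as PNG with a JSON geometry sidecar
#'
#' The image is max-normalized to [0, 1] (flipped so depth runs down the
#' PNG) and a `<path>.json` sidecar records the pixel size and origin so
#' the PNG remains quantitatively interpretable.
#'
#' @param image Matrix (tracking image or scan-converted image).
#' @param path PNG path.
#' @param pixel_size Pixel size in metres; `c(axial, lateral)` or scalar.
#' @param origin Physical position of pixel (1, 1), metres.
#' @export
write_image_png <- function(image, path, pixel_size = NULL,
                            origin = c(0, 0)) {
  img <- unclass(image)
  m <- max(img)
  if (m > 0) img <- img / m
  png::writePNG(img, path)
  side <- list(pixel_size_m = pixel_size, origin_m = origin,
               rows = nrow(img), cols = ncol(img), max_value = m)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# Polynomial rolling hash of a config object's JSON form; run logging only.
.config_digest <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
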