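#' Fabry-Perot interference transfer function model
#'
#' The sensor is a Fabry-Perot (F-P) cavity on a fiber tip: incident
#' acoustic pressure modulates the cavity's optical thickness, which shifts
#' the round-trip phase and hence the reflected optical power. The ITF is
#' the reflected power as a function of that phase; its slope at the bias
#' point sets the acoustic sensitivity.
#'
#' @param mirror_reflectivity_1,mirror_reflectivity_2 Intensity
#'   reflectivities of the two cavity mirrors, each in (0, 1).
#' @param cavity_optical_thickness Optical thickness of the cavity in
#'   metres (refractive index times physical thickness); used only when
#'   converting a wavelength axis to phase.
#' @param input_power Interrogation laser power, arbitrary optical units.
#' @param bias_wavelength Nominal interrogation wavelength in metres.
#' @return An object of class `fous_itf`.
#' @export
itf_model <- function(mirror_reflectivity_1 = 0.8,
                      mirror_reflectivity_2 = 0.8,
                      cavity_optical_thickness = 15e-6,
                      input_power = 1,
                      bias_wavelength = 1550e-9) {
  for (r in c(mirror_reflectivity_1, mirror_reflectivity_2))
    if (!is.numeric(r) || r <= 0 || r >= 1)
      stop("mirror reflectivities must lie in (0, 1)")
  if (cavity_optical_thickness <= 0)
    stop("'cavity_optical_thickness' must be > 0")
  if (input_power < 0) stop("'input_power' must be >= 0")
  structure(list(r1 = mirror_reflectivity_1,
                 r2 = mirror_reflectivity_2,
                 cavity_optical_thickness = cavity_optical_thickness,
                 input_power = input_power,
                 bias_wavelength = bias_wavelength),
            class = "fous_itf")
}

#' Normalized F-P reflectance versus round-trip phase
#'
#' Airy reflectance of a lossless two-mirror cavity,
#' \deqn{R(\phi) = \frac{(\sqrt{R_1}-\sqrt{R_2})^2 + 4\sqrt{R_1 R_2}\sin^2(\phi/2)}
#'                     {(1-\sqrt{R_1 R_2})^2 + 4\sqrt{R_1 R_2}\sin^2(\phi/2)},}
#' smooth, 2-pi-periodic, valued in [0, 1], with a null at resonance
#' (`phase = 0` mod 2 pi) for matched mirrors.
#'
#' @param itf A `fous_itf`.
#' @param phase Round-trip phase(s) in radians.
#' @return Normalized reflected power in [0, 1], same length as `phase`.
#' @export
itf_reflectance <- function(itf, phase) {
  stopifnot(inherits(itf, "fous_itf"))
  a1 <- sqrt(itf$r1); a2 <- sqrt(itf$r2)
  s2 <- sin(phase / 2)^2
  ((a1 - a2)^2 + 4 * a1 * a2 * s2) / ((1 - a1 * a2)^2 + 4 * a1 * a2 * s2)
}

# Maximum |dR/dphi| of the ITF, by dense-grid numerical differentiation.
# One free-spectral range suffices by periodicity.
.itf_max_slope <- function(itf, n = 20001L) {
  phi <- seq(0, 2 * pi, length.out = n)
  R <- itf_reflectance(itf, phi)
  max(abs(diff(R) / diff(phi)))
}

#' Specify a fiber and its bend profile
#'
#' @param fiber_type `"standard_smf"` or `"bend_insensitive"`.
#' @param bend_profile Data frame with columns `radius` (metres, > 0) and
#'   `turns` (fraction of a full turn, >= 0; 0.5 is a 180 degree bend).
#'   A zero-row profile is a straight fiber.
#' @param outer_diameter Coating outer diameter in metres (bookkeeping
#'   only; 250 um for the standard fiber, 155 um for the bend-insensitive
#'   one).
#' @return An object of class `fous_fiber`.
#' @examples
#' straight <- fiber_spec("bend_insensitive")
#' bent <- fiber_spec("standard_smf", bend_profile(radius = 5e-3, turns = 0.5))
#' @export
fiber_spec <- function(fiber_type = c("standard_smf", "bend_insensitive"),
                       bend_profile = NULL,
                       outer_diameter = NULL) {
  fiber_type <- match.arg(fiber_type)
  if (is.null(bend_profile))
    bend_profile <- data.frame(radius = numeric(0), turns = numeric(0))
  stopifnot(is.data.frame(bend_profile),
            all(c("radius", "turns") %in% names(bend_profile)))
  if (nrow(bend_profile) > 0) {
    if (any(bend_profile$radius <= 0)) stop("bend radius must be > 0")
    if (any(bend_profile$turns < 0)) stop("bend turns must be >= 0")
  }
  if (is.null(outer_diameter))
    outer_diameter <- if (fiber_type == "standard_smf") 250e-6 else 155e-6
  structure(list(fiber_type = fiber_type, bend_profile = bend_profile,
                 outer_diameter = outer_diameter),
            class = "fous_fiber")
}

#' @rdname fiber_spec
#' @param radius,turns Vectors describing one bend segment per entry.
#' @export
bend_profile <- function(radius, turns) {
  data.frame(radius = radius, turns = turns)
}

#' Macrobend loss model calibrated to printed reflectivity anchors
#'
#' Macrobend loss in single-mode fiber follows the standard exponential
#' phenomenology `loss_per_turn(r) = a * exp(-b * r)` dB per full turn.
#' Two anchors per fiber type fix `(a, b)`:
#' \itemize{
#'   \item standard SMF: round-trip reflectivity (180 degree bend) of 50%
#'     at r = 10 mm and 2% at r = 5 mm;
#'   \item bend-insensitive (ITU-T G.657.B3 class): one-way loss 0.2
#'     dB/turn at r = 5 mm, and round-trip reflectivity 95% for a 180
#'     degree bend at r = 2.5 mm.
#' }
#' Round-trip reflectivity anchors convert to one-way dB/turn as
#' `-10*log10(T_rt) / (2 * turns)` since interrogation light crosses each
#' bend twice.
#'
#' @param anchors Optional replacement anchor table (same shape as the
#'   default; see the source).
#' @return An object of class `fous_bend_model`: per fiber type, `a`
#'   (dB/turn) and `b` (1/m).
#' @export
bend_loss_model <- function(anchors = NULL) {
  if (is.null(anchors)) {
    anchors <- list(
      standard_smf = data.frame(
        radius = c(10e-3, 5e-3),
        loss_db_per_turn = c(-10 * log10(0.50), -10 * log10(0.02)) / (2 * 0.5)),
      bend_insensitive = data.frame(
        radius = c(5e-3, 2.5e-3),
        loss_db_per_turn = c(0.2, -10 * log10(0.95) / (2 * 0.5))))
  }
  coef <- lapply(anchors, function(an) {
    stopifnot(nrow(an) == 2, all(an$loss_db_per_turn > 0))
    b <- log(an$loss_db_per_turn[2] / an$loss_db_per_turn[1]) /
         (an$radius[1] - an$radius[2])
    a <- an$loss_db_per_turn[1] * exp(b * an$radius[1])
    c(a = a, b = b)
  })
  structure(coef, class = "fous_bend_model")
}

#' One-way macrobend loss of a bend profile, in dB
#'
#' Sums `turns * a * exp(-b * radius)` over the segments of the fiber's
#' bend profile; partial turns scale linearly in dB. A straight fiber
#' (empty profile) has zero loss.
#'
#' @param model A `fous_bend_model` (default: the calibrated one).
#' @param fiber A `fous_fiber`.
#' @return One-way loss in dB (>= 0).
#' @export
bend_loss_db <- function(fiber, model = bend_loss_model()) {
  stopifnot(inherits(fiber, "fous_fiber"), inherits(model, "fous_bend_model"))
  bp <- fiber$bend_profile
  if (nrow(bp) == 0) return(0)
  if (any(bp$radius <= 0)) stop("bend radius must be > 0")
  cf <- model[[fiber$fiber_type]]
  sum(bp$turns * cf["a"] * exp(-cf["b"] * bp$radius))
}

#' Round-trip optical transmission through the bends
#'
#' Interrogation light traverses each bend on the way to the cavity and
#' again on the way back, so the received-power fraction relative to a
#' straight fiber is `10^(-2 * loss_one_way_dB / 10)`.
#'
#' @inheritParams bend_loss_db
#' @return Fraction in [0, 1].
#' @export
roundtrip_transmission <- function(fiber, model = bend_loss_model()) {
  10^(-2 * bend_loss_db(fiber, model) / 10)
}

#' Relative acoustic sensitivity after bend loss
#'
#' Sensitivity of the F-P sensor scales linearly with the optical power
#' reaching the detector: it is the maximum ITF slope at the bias point
#' times input power times round-trip transmission, normalized so that a
#' straight fiber has relative sensitivity 1. With `normalize = FALSE` the
#' un-normalized product is returned (doubling `input_power` doubles it).
#'
#' @param itf A `fous_itf`.
#' @param transmission Round-trip power transmission in [0, 1].
#' @param normalize Normalize to the straight-fiber value (default TRUE).
#' @return Dimensionless sensitivity.
#' @export
sensor_sensitivity <- function(itf, transmission, normalize = TRUE) {
  if (any(transmission < 0 | transmission > 1))
    stop("'transmission' must lie in [0, 1]")
  s <- .itf_max_slope(itf) * itf$input_power * transmission
  if (normalize) {
    s0 <- .itf_max_slope(itf) * itf$input_power
    s / s0
  } else s
}

#' Angular directivity of the sensor
#'
#' The tip sensor is close to omnidirectional: the default model is flat
#' (gain 1) for incidence angles within +/-165 degrees of the fiber axis
#' and rolls off smoothly (raised cosine) to 0 at +/-180 degrees, where the
#' sensor is shadowed by its own fiber.
#'
#' @param edge_deg Angle (degrees) at which roll-off begins.
#' @param floor Minimum gain guaranteed inside `edge_deg` (the default
#'   model is flat at 1, which trivially satisfies any floor <= 1).
#' @return An object of class `fous_directivity`.
#' @export
directivity_model <- function(edge_deg = 165, floor = 0.5) {
  stopifnot(edge_deg > 0, edge_deg < 180, floor >= 0, floor <= 1)
  structure(list(edge_deg = edge_deg, floor = floor),
            class = "fous_directivity")
}

#' @rdname directivity_model
#' @param model A `fous_directivity`.
#' @param angle Incidence angle(s) in degrees, in [-180, 180].
#' @return Gain(s) in [0, 1]; symmetric about 0 with g(0) = 1.
#' @export
directivity_gain <- function(model, angle) {
  if (any(abs(angle) > 180)) stop("angle must lie in [-180, 180] degrees")
  a <- abs(angle)
  g <- rep(1, length(a))
  ro <- a > model$edge_deg
  g[ro] <- 0.5 * (1 + cos(pi * (a[ro] - model$edge_deg) /
                          (180 - model$edge_deg)))
  g
}
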