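# Shared fixtures: the two study probes, water medium, default pulse.

tee_probe <- function(...) {
  make_probe("phased_sector", n_elements = 16, pitch = 0.3e-3,
             center_frequency = 6e6, fov_angle = 90, focus_depth = 0.055, ...)
}

lap_probe <- function(...) {
  make_probe("linear", n_elements = 128, pitch = 0.3e-3,
             center_frequency = 6e6, focus_depth = 0.055, ...)
}

water <- function() make_medium(1500, 0)

# Brute-force centre-of-mass oracle: global max, clipped ROI, threshold,
# weighted mean over every surviving pixel by explicit double loop.
com_oracle <- function(img, roi = c(100L, 100L), thr_frac = 0.7) {
  pk <- which(img == max(img), arr.ind = TRUE)
  pk <- pk[order(pk[, 1], pk[, 2]), , drop = FALSE]
  pr <- pk[1, 1]; pc <- pk[1, 2]
  rmin <- max(1L, pr - roi[1] %/% 2)
  rmax <- min(nrow(img), pr - roi[1] %/% 2 + roi[1] - 1L)
  cmin <- max(1L, pc - roi[2] %/% 2)
  cmax <- min(ncol(img), pc - roi[2] %/% 2 + roi[2] - 1L)
  sub <- img[rmin:rmax, cmin:cmax, drop = FALSE]
  thr <- thr_frac * max(sub)
  sw <- 0; sr <- 0; sc <- 0
  for (i in seq_len(nrow(sub))) for (j in seq_len(ncol(sub))) {
    v <- sub[i, j]
    if (v >= thr) {
      sw <- sw + v
      sr <- sr + v * (rmin + i - 1)
      sc <- sc + v * (cmin + j - 1)
    }
  }
  c(row = sr / sw, col = sc / sw)
}
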