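test_that("envelope has the analytic-signal properties", {
  t <- (0:2047) / 40e6
  x <- 3 * sin(2 * pi * 5e6 * t)
  env <- envelope(x)
  mid <- 200:1848
  expect_true(all(abs(env[mid] - 3) < 0.01))            # constant-amplitude tone
  expect_true(all(env >= abs(x) - 1e-9))                # bounds the signal
  expect_equal(envelope(numeric(128)), numeric(128))
  expect_error(envelope(c(1, NA, 2)), "finite")
})

test_that("envelope of a windowed tone matches the quadrature oracle", {
  fs <- 40e6; f0 <- 5e6; sigma <- 0.3e-6; t0 <- 10e-6
  t <- (0:1599) / fs
  x <- exp(-(t - t0)^2 / (2 * sigma^2)) * cos(2 * pi * f0 * t)
  env <- envelope(x)
  expect_lt(abs(which.max(env) - (t0 * fs + 1)), 1.5)   # peak at window centre
  # closed-form envelope away from the edges
  mid <- which(t > 8e-6 & t < 12e-6)
  expect_equal(env[mid], exp(-(t[mid] - t0)^2 / (2 * sigma^2)),
               tolerance = 0.02)
})

test_that("tracking images concatenate envelope-detected scanlines", {
  probe <- tee_probe()
  rec <- generate_frame(probe, sensor_pose(z = 0.055), water(),
                        pulse_spec(6e6), noise_std = 0, seed = 1)
  img <- build_tracking_image(rec)
  expect_equal(ncol(img), probe$n_scanlines)
  expect_true(all(img >= 0))
  expect_equal(attr(img, "axial_spacing"), 1500 / 40e6)
  w <- which(img == max(img), arr.ind = TRUE)
  expect_equal(unname(w[1, 2]), 46)                        # boresight column
  expect_equal(unname(w[1, 1]), 0.055 * 40e6 / 1500, tolerance = 0.005)

  # single-scanline frame gives a single-column image
  rec1 <- generate_frame(tee_probe(n_scanlines = 1), sensor_pose(z = 0.03),
                         water(), pulse_spec(6e6), seed = 1)
  expect_equal(ncol(build_tracking_image(rec1)), 1)

  # ragged scanlines are rejected
  bad <- rec
  bad$frames[[1]]$lines <- list(rnorm(10), rnorm(11))
  expect_error(build_tracking_image(bad), "ragged")
})

test_that("background subtraction removes offsets and keeps spikes", {
  cfg <- tracker_config()
  img <- matrix(2, 10, 10); img[4, 7] <- 10
  out <- background_subtract(img, cfg)
  expect_equal(out[4, 7], 8)                               # spike minus median
  expect_equal(sum(out > 0), 1)
  expect_true(all(background_subtract(matrix(5, 6, 6), cfg) == 0))
  expect_equal(background_subtract(img + 3, cfg), out, ignore_attr = TRUE)

  ref <- matrix(2, 10, 10)
  out2 <- background_subtract(img, tracker_config(background_method = "reference"),
                              reference = ref)
  expect_equal(out2, pmax(img - ref, 0), ignore_attr = TRUE)
  expect_error(background_subtract(img, cfg, reference = matrix(0, 3, 3)),
               "shape")
})

test_that("centre-of-mass localization matches hand-computed cases", {
  cfg <- tracker_config()
  img <- matrix(0, 9, 9); img[5, 6] <- 2
  tip <- localize_tip(img, cfg)
  expect_equal(c(tip$row, tip$col), c(5, 6))               # single pixel exact

  img2 <- matrix(0, 11, 11); img2[5:7, 4:6] <- 1
  tip2 <- localize_tip(img2, cfg)
  expect_equal(c(tip2$row, tip2$col), c(6, 5))             # plateau centre

  # 5x5 toy: 10 at [3,3], 8 at [3,4], 6 at [2,3], rest 1; threshold 0.7
  # keeps only the 10 and the 8 -> CoM (3, 3 + 8/18)
  img3 <- matrix(1, 5, 5)
  img3[3, 3] <- 10; img3[3, 4] <- 8; img3[2, 3] <- 6
  tip3 <- localize_tip(img3, cfg)
  expect_equal(tip3$row, 3)
  expect_equal(tip3$col, (10 * 3 + 8 * 4) / 18)

  expect_error(localize_tip(matrix(0, 5, 5), cfg), "no signal")
})

test_that("localization equals the brute-force weighted-mean oracle", {
  set.seed(7)
  cfg <- tracker_config(roi_size = c(7L, 7L))
  for (i in 1:200) {
    img <- matrix(stats::runif(400), 20, 20)
    tip <- localize_tip(img, cfg)
    oracle <- com_oracle(img, roi = c(7L, 7L))
    expect_identical(c(row = tip$row, col = tip$col), oracle)
  }
})

test_that("thresholding is monotone and the CoM is scale invariant", {
  set.seed(11)
  img <- matrix(stats::runif(400), 20, 20)
  survivors <- function(tf) {
    cfg <- tracker_config(roi_size = c(9L, 9L), threshold_fraction = tf)
    tip <- localize_tip(img, cfg)
    b <- tip$roi_bounds
    roi <- img[b["rmin"]:b["rmax"], b["cmin"]:b["cmax"]]
    sum(roi >= tf * max(roi))
  }
  ns <- vapply(seq(0.1, 0.9, by = 0.1), survivors, numeric(1))
  expect_true(all(diff(ns) <= 0))

  cfg <- tracker_config()
  t1 <- localize_tip(img, cfg)
  t2 <- localize_tip(img * 17.3, cfg)
  expect_equal(c(t1$row, t1$col), c(t2$row, t2$col))
})

test_that("display mapping converts beam/range to cartesian coordinates", {
  probe <- tee_probe()
  tip <- structure(list(row = 1 + 0.05 / (1500 / 40e6), col = 46,
                        axial_spacing = 1500 / 40e6, probe = probe),
                   class = "fous_tip")
  expect_equal(map_to_display(tip), c(x = 0, z = 0.05))    # boresight

  tip45 <- tip; tip45$col <- 91                            # +45 degree beam
  xz <- map_to_display(tip45)
  expect_equal(unname(xz), rep(0.05 / sqrt(2), 2), tolerance = 1e-12)

  tip_bad <- tip; tip_bad$col <- 200
  expect_error(map_to_display(tip_bad), "beam table")

  lin <- lap_probe()
  tipl <- structure(list(row = 1 + 0.03 / (1500 / 40e6), col = 1,
                         axial_spacing = 1500 / 40e6, probe = lin),
                    class = "fous_tip")
  expect_equal(map_to_display(tipl),
               c(x = min(lin$element_x), z = 0.03))
})

test_that("a simulation posed at the reported straight-catheter point closes", {
  # feed the display coordinates [3.26, 5.44] cm back through the full
  # pipeline as the true pose and recover them
  probe <- tee_probe()
  pose <- sensor_pose(x = 0.0326, z = 0.0544)
  rec <- generate_frame(probe, pose, water(), pulse_spec(6e6),
                        noise_std = 0, seed = 2)
  tips <- track_sequence(rec)
  expect_false(tips$flag[1])
  expect_equal(c(tips$x_m[1], tips$z_m[1]), c(0.0326, 0.0544),
               tolerance = 0.02)
})

test_that("sequence tracking flags unlocalizable frames instead of dropping them", {
  probe <- tee_probe(n_scanlines = 5)
  rec <- generate_sequence(3, probe, sensor_pose(z = 0.04), water(),
                           pulse_spec(6e6), noise_std = 0, seed = 1)
  tips <- track_sequence(rec)
  expect_equal(nrow(tips), 3)
  expect_false(any(tips$flag))
  # identical noiseless frames localize identically
  expect_equal(tips$row[1], tips$row[3])

  # all-zero frames (no pulse) are flagged, not dropped
  rec0 <- generate_sequence(2, probe, sensor_pose(z = 0.04), water(),
                            pulse_spec(6e6, amplitude = 0), noise_std = 0,
                            seed = 1)
  tips0 <- track_sequence(rec0)
  expect_equal(nrow(tips0), 2)
  expect_true(all(tips0$flag))
  expect_true(all(is.na(tips0$x_m)))
})
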