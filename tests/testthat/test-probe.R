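test_that("probe construction validates and lays out the aperture", {
  p <- tee_probe()
  expect_length(p$element_x, 16)
  expect_equal(sum(p$element_x), 0)                      # symmetric about x = 0
  expect_equal(p$n_scanlines, 91L)                       # 1 line per degree

  lap <- lap_probe()
  expect_equal(diff(range(lap$element_x)), 127 * 0.3e-3) # 38.1 mm aperture
  expect_equal(lap$n_scanlines, 128L)

  single <- make_probe("linear", 1, 1e-3, 5e6)
  expect_equal(single$element_x, 0)

  expect_error(make_probe("linear", 8, -1e-3, 5e6), "pitch")
  expect_error(make_probe("linear", 8, 1e-3, 0), "center_frequency")
  expect_error(make_probe("phased_sector", 8, 1e-3, 5e6), "fov_angle")
  expect_error(make_probe("phased_sector", 8, 1e-3, 5e6, fov_angle = 200),
               "fov_angle")
})

test_that("sector events fan evenly over the field of view", {
  ev <- enumerate_events(tee_probe())
  angles <- vapply(ev, `[[`, 0, "angle")
  expect_equal(angles, seq(-45, 45, by = 1))
  expect_equal(vapply(ev, `[[`, 0L, "line_index"), 0:90)
  for (e in ev[c(1, 46, 91)]) {
    expect_equal(sqrt(sum(e$direction^2)), 1)
    expect_true(all(e$element_delays >= 0))
    expect_equal(min(e$element_delays), 0)
  }
  ev1 <- enumerate_events(tee_probe(n_scanlines = 1))
  expect_equal(ev1[[1]]$angle, 0)
})

test_that("focusing delays match a geometric three-point oracle", {
  p <- make_probe("linear", 3, 1e-3, 5e6, focus_depth = 0.05, n_scanlines = 3)
  ev <- enumerate_events(p, speed_of_sound = 1500)[[2]]  # centre line, on-axis
  ex <- ev$element_positions[, 1]
  d <- sqrt((ex - 0)^2 + 0.05^2)
  expect_equal(ev$element_delays, (max(d) - d) / 1500)
  # outer-element delay relative to centre: (d_outer - d_center)/c
  expect_equal(ev$element_delays[2] - ev$element_delays[1],
               (sqrt(0.001^2 + 0.05^2) - 0.05) / 1500)
})

test_that("arrival times agree with brute-force distances for random poses", {
  set.seed(42)
  med <- water()
  for (probe in list(tee_probe(), lap_probe())) {
    ev <- enumerate_events(probe, med$speed_of_sound)
    for (i in 1:50) {
      pose <- sensor_pose(x = runif(1, -0.03, 0.03), z = runif(1, 0.001, 0.08))
      e <- ev[[sample(length(ev), 1)]]
      tt <- arrival_times(e, pose, med)
      brute <- e$element_delays + apply(e$element_positions, 1, function(ep)
        sqrt(sum((ep - pose$position)^2))) / med$speed_of_sound
      expect_equal(tt, unname(brute))
    }
  }
})

test_that("a sensor at the focus receives all elements coherently", {
  med <- water()
  ev <- enumerate_events(tee_probe(), med$speed_of_sound)
  for (j in c(1, 46, 91)) {
    e <- ev[[j]]
    fp <- 0.055 * e$direction
    tt <- arrival_times(e, sensor_pose(x = fp[1], z = fp[2]), med)
    expect_lt(diff(range(tt)), 1e-15)
  }
})

test_that("time of flight maps one-way (no pulse-echo halving) and inverts", {
  med <- water()
  expect_equal(tof_to_depth(0, med), 0)
  expect_equal(tof_to_depth(0.055 / 1500, med), 0.055)   # 36.67 us -> 5.5 cm
  expect_equal(tof_to_depth(10e-6, med), 0.015)          # 10 us -> 1.5 cm
  t <- runif(20, 0, 1e-4)
  expect_equal(depth_to_tof(tof_to_depth(t, med), med), t)
  expect_error(tof_to_depth(-1e-6, med))
  expect_error(arrival_times(enumerate_events(tee_probe())[[1]],
                             sensor_pose(z = 0.05), make_medium(1500)),
               NA)
})

test_that("sector scan conversion maps beams and ranges correctly", {
  probe <- tee_probe()
  dr <- 1500 / 40e6
  nr <- 1600L
  g <- grid_spec(c(-0.045, 0.045), c(0, 0.062), 0.2e-3)

  # all-zero polar -> all-zero cartesian
  z0 <- scan_convert_sector(matrix(0, nr, 91), probe, g, dr)
  expect_true(all(z0 == 0))

  # boresight beam maps to the x = 0 line
  pol <- matrix(0, nr, 91); pol[, 46] <- 1
  cart <- scan_convert_sector(pol, probe, g, dr, method = "nearest")
  lit_cols <- which(colSums(cart) > 0)
  # nearest-beam assignment spreads the boresight line over half a beam
  # spacing (0.5 deg) at most
  expect_true(all(abs(attr(cart, "x")[lit_cols]) <=
                  0.062 * tan(0.5 * pi / 180) + g$pixel_size))

  # a point at range r on the +45 degree beam lands at (r/sqrt2, r/sqrt2)
  pol2 <- matrix(0, nr, 91); pol2[1000, 91] <- 1
  cart2 <- scan_convert_sector(pol2, probe, g, dr, method = "nearest")
  w <- which(cart2 == max(cart2), arr.ind = TRUE)
  r <- 999 * dr
  expect_equal(attr(cart2, "x")[w[1, 2]], r / sqrt(2), tolerance = 2 * g$pixel_size / (r / sqrt(2)))
  expect_equal(attr(cart2, "z")[w[1, 1]], r / sqrt(2), tolerance = 2 * g$pixel_size / (r / sqrt(2)))

  expect_error(scan_convert_sector(pol, lap_probe(), g, dr), "sector")
})

test_that("scan conversion round-trips a smooth image within 2% L2", {
  probe <- tee_probe()
  angles <- beam_table(probe)
  dr <- 1500 / 40e6
  rr <- (seq_len(1600L) - 1) * dr
  pol <- outer(rr, angles, function(r, a)
    exp(-((r - 0.04)^2 / (2 * 0.002^2) + (a - 10)^2 / (2 * 5^2))))
  g <- grid_spec(c(-0.045, 0.045), c(0, 0.062), 0.2e-3)
  cart <- scan_convert_sector(pol, probe, g, dr)
  px <- outer(rr, angles, function(r, a) r * sin(a * pi / 180))
  pz <- outer(rr, angles, function(r, a) r * cos(a * pi / 180))
  back <- matrix(pracma::interp2(x = attr(cart, "x"), y = attr(cart, "z"),
                                 Z = cart, xp = as.vector(px),
                                 yp = as.vector(pz)), nrow(pol))
  back[is.na(back)] <- 0
  expect_lt(sqrt(sum((back - pol)^2) / sum(pol^2)), 0.02)
})
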