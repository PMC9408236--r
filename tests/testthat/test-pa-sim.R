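# Photoacoustic signal synthesis: sensor impulse response and A-lines.

test_that("sensor model validates its spectral parameters", {
  expect_s3_class(sensor_model(), "sensor_model")
  expect_error(sensor_model(8, 17), "bandwidth")
  expect_error(sensor_model(8, 6.5, 30), "sample_rate")
  expect_error(sensor_impulse_response(sensor_model(), duration = 100),
               "6 envelope")
})

test_that("the impulse response is a zero-mean band-limited burst", {
  h <- sensor_impulse_response(sensor_model())
  expect_equal(h$t0, -max(abs(h$t0)))
  dc <- abs(sum(h$samples)) / sum(abs(h$samples))
  expect_lt(dc, 0.05)
  # amplitude spectrum peaks at the carrier
  n <- 2^14
  sp <- abs(fft(c(h$samples, rep(0, n - length(h$samples)))))
  fr <- (0:(n - 1)) / (n * h$dt * 1e-3)
  lo <- fr < 30
  expect_lt(abs(fr[lo][which.max(sp[lo])] - 8), 0.2)
})

test_that("point absorbers arrive at z / c and scale linearly", {
  ph <- make_point_phantom(data.frame(x = 0, y = 0, z = 100),
                           extent = c(11, 11), pitch = 1)
  f <- excitation_focus(0, 0, plane_z = 100)
  s <- sensor_model()
  tr <- simulate_a_line(ph, f, s, duration = 600)
  env <- pamendo:::analytic_envelope(tr$samples)
  t_pk <- (which.max(env) - 1) * tr$dt
  expect_lt(abs(t_pk - 1e3 * 100 / 1485), tr$dt + 1e-9)   # ~ 67.3 ns
  # linear in pulse energy
  f2 <- f; f2$pulse_energy <- 2 * f$pulse_energy
  tr2 <- simulate_a_line(ph, f2, s, duration = 600)
  expect_equal(tr2$samples, 2 * tr$samples, tolerance = 1e-12)
  # linear in absorption
  ph2 <- ph; ph2$absorption <- 2 * ph$absorption
  tr3 <- simulate_a_line(ph2, f, s, duration = 600)
  expect_equal(tr3$samples, 2 * tr$samples, tolerance = 1e-12)
  # empty phantom is silent
  ph0 <- ph; ph0$absorption[] <- 0
  expect_true(all(simulate_a_line(ph0, f, s)$samples == 0))
})

test_that("two absorbers 200 um apart give two peaks ~134.7 ns apart", {
  solo_peak <- function(z) {
    ph <- make_point_phantom(data.frame(x = 0, y = 0, z = z),
                             extent = c(11, 11), pitch = 1, z_max = 500)
    f <- excitation_focus(0, 0, plane_z = 200, axial_fwhm = 600)
    tr <- simulate_a_line(ph, f, sensor_model(), duration = 600)
    (which.max(pamendo:::analytic_envelope(tr$samples)) - 1) * tr$dt
  }
  expect_lt(abs(solo_peak(150) - 1e3 * 150 / 1485), 4 + 1e-9)
  expect_lt(abs(solo_peak(350) - 1e3 * 350 / 1485), 4 + 1e-9)
  ph <- make_point_phantom(data.frame(x = c(0, 0), y = c(0, 0),
                                      z = c(150, 350)),
                           extent = c(11, 11), pitch = 1, z_max = 500)
  f <- excitation_focus(0, 0, plane_z = 250, axial_fwhm = 600)
  tr <- simulate_a_line(ph, f, sensor_model(), duration = 600)
  env <- pamendo:::analytic_envelope(tr$samples)
  t_axis <- (seq_along(env) - 1) * tr$dt
  mid <- 1e3 * 250 / 1485
  p1 <- t_axis[which.max(env[t_axis < mid])]
  p2 <- t_axis[t_axis >= mid][which.max(env[t_axis >= mid])]
  # the overlapping envelope tails pull the two maxima together by up to
  # ~20 ns at this bandwidth; the separation still tracks delta-z / c
  expect_lt(abs((p2 - p1) - 1e3 * 200 / 1485), 25)
})

test_that("arrival times are invariant to sensor bandwidth", {
  ph <- make_point_phantom(data.frame(x = 0, y = 0, z = 400),
                           extent = c(11, 11), pitch = 1, z_max = 500)
  f <- excitation_focus(0, 0, plane_z = 400)
  pk <- function(bw) {
    tr <- simulate_a_line(ph, f, sensor_model(8, bw), duration = 1000)
    which.max(pamendo:::analytic_envelope(tr$samples))
  }
  expect_lte(abs(pk(6.5) - pk(3.25)), 1)
})

test_that("frames cover the grid in raster order and respect translation", {
  g <- make_scan_grid(4, 1)
  ph <- make_point_phantom(data.frame(x = 1, y = 0, z = 60),
                           extent = c(11, 11), pitch = 1)
  f <- excitation_focus(plane_z = 60)
  s <- sensor_model()
  fr <- simulate_frame(ph, g, f, s, duration = 300)
  expect_equal(nrow(fr$traces), nrow(g$positions))
  peaks <- apply(fr$traces, 1, function(x) max(abs(x)))
  expect_equal(g$positions[which.max(peaks), c("x", "y")],
               data.frame(x = 1, y = 0), ignore_attr = TRUE)
  # shift equivariance: move phantom and grid together by +1 um in x
  ph_shift <- make_point_phantom(data.frame(x = 2, y = 0, z = 60),
                                 extent = c(11, 11), pitch = 1)
  g_shift <- make_scan_grid(4, 1, center = c(1, 0))
  fr_shift <- simulate_frame(ph_shift, g_shift, f, s, duration = 300)
  expect_equal(fr_shift$traces, fr$traces, tolerance = 1e-12)
  # empty phantom gives an all-zero frame
  ph0 <- ph; ph0$absorption[] <- 0
  expect_true(all(simulate_frame(ph0, g, f, s, duration = 300)$traces == 0))
  expect_error(simulate_frame(ph, make_scan_grid(40, 1), f, s),
               "outside the phantom")
})
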