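# Filtering, image/volume assembly and the quality metrics.

make_trace <- function(samples, dt = 4) pamendo:::new_pa_trace(samples, dt, 0)

test_that("the low-pass filter is flat at DC, steep above cutoff, zero-phase", {
  n <- 512; dt <- 4                      # 250 MHz sampling
  dc <- make_trace(rep(2.5, n), dt)
  expect_equal(lowpass(dc)$samples, dc$samples, tolerance = 1e-6)
  t_ns <- (0:(n - 1)) * dt
  tone40 <- make_trace(sin(2 * pi * 40e-3 * t_ns), dt)
  att <- max(abs(lowpass(tone40)$samples[100:400]))     # avoid edge transients
  expect_lt(att, 10^(-12 / 20))                          # >= 12 dB down
  # zero phase: a band-limited pulse's envelope peak does not move
  h <- sensor_impulse_response(sensor_model(), duration = 600)
  pulse <- make_trace(c(rep(0, 100), h$samples, rep(0, 100)), h$dt)
  p0 <- which.max(pamendo:::analytic_envelope(pulse$samples))
  p1 <- which.max(pamendo:::analytic_envelope(lowpass(pulse)$samples))
  expect_lte(abs(p1 - p0), 1)
  expect_error(lowpass(dc, cutoff = 200), "Nyquist")
})

test_that("time maps to depth one-way and linearly", {
  expect_equal(time_to_depth(0), 0)
  expect_equal(time_to_depth(1000), 1485)
  expect_equal(time_to_depth(2 * 321.7), 2 * time_to_depth(321.7))
  expect_error(time_to_depth(1, c_sound = 0), "positive")
})

test_that("MIP projects envelopes onto the scan lattice", {
  g <- make_scan_grid(4, 1)
  np <- nrow(g$positions)
  traces <- matrix(0, np, 64)
  fr <- structure(list(traces = traces, dt = 4, t0 = 0, grid = g,
                       plane_z = 0, filtered = TRUE), class = "pa_frames")
  expect_true(all(mip(fr)$pixels == 0))
  fr$traces[3, 20] <- 1                    # single impulse in one trace
  img <- mip(fr)
  expect_equal(sum(img$pixels > 1e-6), 1)
  expect_equal(img$pixels[g$positions$iy[3], g$positions$ix[3]],
               max(pamendo:::analytic_envelope(fr$traces[3, ])))
  expect_error(mip(structure(list(traces = matrix(0, 0, 4), grid = g),
                             class = "pa_frames")), "empty")
})

test_that("acoustic volumes localise depth and agree with the 2D MIP", {
  g <- make_scan_grid(4, 1)
  ph <- make_point_phantom(data.frame(x = 0, y = 0, z = 150),
                           extent = c(11, 11), pitch = 1)
  fr <- lowpass(simulate_frame(ph, g, excitation_focus(plane_z = 150),
                               sensor_model(), duration = 400))
  vol <- assemble_volume_acoustic(fr)
  idx <- which(vol$values == max(vol$values), arr.ind = TRUE)[1, ]
  dz <- vol$zs[2] - vol$zs[1]
  expect_lt(abs(vol$zs[idx[3]] - 150), dz + 1e-9)
  expect_equal(volume_mip(vol), mip(fr)$pixels, tolerance = 1e-12)
  # empty frames give an all-zero volume
  fr0 <- fr; fr0$traces[] <- 0
  expect_true(all(assemble_volume_acoustic(fr0)$values == 0))
})

test_that("optical stacks span the plane range and reject mixed grids", {
  g <- make_scan_grid(4, 1)
  blank <- function(z) pamendo:::new_pa_image(matrix(0, g$ny, g$nx), g, z)
  v5 <- assemble_volume_optical(lapply(seq(0, 20, 5), blank))
  expect_equal(depth_span(v5), 20)
  v21 <- assemble_volume_optical(lapply(seq(0, 100, 5), blank))
  expect_equal(depth_span(v21), 100)
  v1 <- assemble_volume_optical(list(blank(0)))
  expect_equal(dim(v1$values)[3], 1)
  g2 <- make_scan_grid(6, 1)
  im2 <- pamendo:::new_pa_image(matrix(0, g2$ny, g2$nx), g2, 5)
  expect_error(assemble_volume_optical(list(blank(0), im2)), "share")
  expect_error(assemble_volume_optical(list(blank(5), blank(0))), "increasing")
})

test_that("enhancement factor and power ratio behave on crafted images", {
  flat <- flat_speckle(1, c(41, 41))
  expect_equal(enhancement_factor(flat, c(21, 21), fwhm = 2), 1)
  peaked <- flat
  peaked$intensity[21, 21] <- 769
  expect_equal(enhancement_factor(peaked, c(21, 21), fwhm = 2), 769)
  # excluding the focal region from the background raises EF above the
  # naive global-mean version
  naive <- max(peaked$intensity) / mean(peaked$intensity[peaked$core_mask])
  expect_gt(enhancement_factor(peaked, c(21, 21), fwhm = 2), naive)
  # power ratio: single hot pixel holds almost all energy
  hot <- flat; hot$intensity[] <- 0; hot$intensity[21, 21] <- 5
  expect_equal(power_ratio(hot, c(21, 21), fwhm = 2), 1)
  pr_flat <- power_ratio(flat, c(21, 21), fwhm = 10)
  disc <- sum(pamendo:::disc_distance(c(41, 41), 1, c(21, 21)) <= 5 &
                flat$core_mask)
  expect_equal(pr_flat, disc / sum(flat$core_mask))
  expect_lte(pr_flat, 1)
})

test_that("profile FWHM is exact for Gaussians and invariant to amplitude", {
  x <- seq(-10, 10, 0.1)
  prof <- exp(-x^2 / (2 * (0.2)^2))        # sigma = 2 px at 0.1 um pitch
  expect_lt(abs(profile_fwhm(prof, pitch = 0.1) - 2 * sqrt(2 * log(2)) * 0.2) /
              (2 * sqrt(2 * log(2)) * 0.2), 0.02)
  expect_equal(profile_fwhm(3.7 * prof, pitch = 0.1),
               profile_fwhm(prof, pitch = 0.1))
  impulse <- c(0, 0, 1, 0, 0)
  expect_lte(profile_fwhm(impulse, pitch = 1), 1)
  expect_error(profile_fwhm(c(1, 2, 3), pitch = 1), "peak")
})

test_that("ESF/LSF resolution recovers the blur width and its ordering", {
  step_image <- function(sigma, pitch = 0.25, n = 201) {
    xs <- (seq_len(n) - (n + 1) / 2) * pitch
    esf <- stats::pnorm(xs / sigma)
    as_pa_image(matrix(rep(esf, each = 20), nrow = 20), pitch = pitch)
  }
  res <- sapply(c(0.5, 1, 2), function(s)
    as.numeric(lateral_resolution_esf(step_image(s), n_adjacent = 10)))
  expect_lt(abs(res[2] - 2.355) / 2.355, 0.05)
  expect_true(all(diff(res) > 0))
  scaled <- step_image(1)
  scaled$pixels <- 5 * scaled$pixels
  expect_equal(as.numeric(lateral_resolution_esf(scaled)),
               as.numeric(lateral_resolution_esf(step_image(1))),
               tolerance = 1e-6)
})

test_that("axial resolution rejects multi-lobed profiles", {
  v <- array(0, dim = c(3, 3, 60))
  zs <- seq(0, 295, 5)
  v[2, 2, ] <- exp(-(zs - 80)^2 / 200) + exp(-(zs - 220)^2 / 200)
  vol <- structure(list(values = v, pitch = 1, zs = zs, mode = "acoustic",
                        signal = "envelope"), class = "pa_volume")
  expect_error(axial_resolution(vol, at = c(2, 2)), "lobes")
  v1 <- v; v1[2, 2, ] <- exp(-(zs - 150)^2 / (2 * 20^2))
  vol1 <- structure(list(values = v1, pitch = 1, zs = zs, mode = "acoustic",
                         signal = "envelope"), class = "pa_volume")
  expect_lt(abs(as.numeric(axial_resolution(vol1, at = c(2, 2))) -
                  2 * sqrt(2 * log(2)) * 20), 1)
})

test_that("fluence follows the focal-disc geometry", {
  expect_equal(fluence(20, 1.2), 20e-9 / (pi * (0.6e-4)^2))
  expect_equal(fluence(0, 1.2), 0)
  expect_equal(fluence(20, 2.4), fluence(20, 1.2) / 4)
  expect_error(fluence(20, 0), "positive")
})

test_that("a simulated bar-target image reproduces the target geometry", {
  g <- make_scan_grid(20, 1)
  ph <- make_bar_target(bar_width = 8, n_bars = 1, extent = 30, pitch = 0.5,
                        z = 30)
  img <- mip(lowpass(simulate_frame(ph, g, excitation_focus(plane_z = 30),
                                    sensor_model(), duration = 300)))
  seg <- img$pixels >= max(img$pixels) / 2
  truth <- outer(abs(img$ys) <= 4, rep(TRUE, length(img$xs))) & img$mask
  dice <- 2 * sum(seg & truth) / (sum(seg) + sum(truth))
  expect_gte(dice, 0.9)
})
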