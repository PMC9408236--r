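# Hadamard pattern construction and the RVITM estimator.

test_that("Sylvester Hadamard pattern sets satisfy the defining identities", {
  p2 <- build_hadamard_pattern_set(2)
  expect_equal(p2$H, matrix(c(1, 1, 1, -1), 2, byrow = TRUE))
  expect_equal(p2$H1, matrix(c(1, 1, 1, 0), 2, byrow = TRUE))
  expect_equal(p2$H2, matrix(c(0, 0, 0, 1), 2, byrow = TRUE))
  for (N in c(4, 16, 64)) {
    p <- build_hadamard_pattern_set(N)
    expect_true(all(p$H1 + p$H2 == 1))
    expect_equal(p$H1 - p$H2, p$H)
    expect_equal(t(p$H) %*% p$H, N * diag(N))
    hh <- cbind(p$H, -p$H)
    expect_equal(hh %*% t(hh), 2 * N * diag(N))
    expect_equal(p$display[, 1], rep(1, N))          # first H1 pattern all-ON
    expect_equal(p$display[, N + 1], rep(0, N))      # first H2 pattern all-OFF
  }
  expect_error(build_hadamard_pattern_set(12), "power of two")
})

test_that("calibration columns match hand-computed field arithmetic", {
  t_row <- c(1, 1i, 1, 1)
  tm <- make_toy_tm(t_row)
  p <- build_hadamard_pattern_set(4)
  meas <- acquire_calibration(tm, p)
  expect_equal(ncol(meas$I), 8)
  # independent oracle: plain complex arithmetic per displayed pattern
  expected <- apply(p$display, 2, function(m) Mod(sum(m * t_row))^2)
  expect_equal(meas$I[1, ], expected, tolerance = 1e-12)
  expect_equal(meas$I[1, 5], 0)                         # all-OFF column
  expect_equal(meas$I[1, 1], Mod(sum(t_row))^2)         # all-ON column
  expect_error(acquire_calibration(tm, build_hadamard_pattern_set(8)),
               "does not match")
})

test_that("the estimator reproduces the worked single-pixel example", {
  tm <- make_toy_tm(c(1, 1i, 1, 1))
  p <- build_hadamard_pattern_set(4)
  fit <- rvitm(acquire_calibration(tm, p), p)
  expect_equal(as.numeric(coef(fit)[1, ]), c(24, 8, 24, 24), tolerance = 1e-12)
  expect_equal(as.numeric(coef(analytic_rvitm_oracle(tm))[1, ]),
               c(24, 8, 24, 24), tolerance = 1e-12)
})

test_that("noiseless estimation equals the analytic oracle", {
  tm <- generate_tm(16, c(8, 8), seed = 5)
  p <- build_hadamard_pattern_set(16)
  est <- coef(rvitm(acquire_calibration(tm, p), p))
  ora <- coef(analytic_rvitm_oracle(tm))
  expect_lt(norm(est - ora, "F") / norm(ora, "F"), 1e-9)
})

test_that("zero measurements give a zero fit and the all-ON offset cancels", {
  p <- build_hadamard_pattern_set(4)
  tm <- make_toy_tm(c(1, 1i, 1, 1))
  meas <- acquire_calibration(tm, p)
  zero <- meas; zero$I[] <- 0
  expect_true(all(coef(rvitm(zero, p)) == 0))
  # the subtracted offset enters the two Hadamard blocks with opposite sign
  # and cancels: a constant added to every measurement changes nothing
  fit0 <- rvitm(meas, p)
  meas2 <- meas; meas2$I[] <- meas$I + 3.3
  fit2 <- rvitm(meas2, p)
  expect_equal(coef(fit2), coef(fit0), tolerance = 1e-9)
  expect_error(rvitm(structure(list(I = meas$I[, 1:6, drop = FALSE],
                                    n_inputs = 4, plane_z = 0,
                                    output_shape = c(1, 1), pixel_pitch = 1,
                                    core_mask = tm$core_mask),
                               class = "speckle_measurements"), p),
               "columns")
})

test_that("top-fraction focus patterns follow rank and tie-break rules", {
  tm <- make_toy_tm(c(1, 1i, 1, 1))
  p <- build_hadamard_pattern_set(4)
  fit <- rvitm(acquire_calibration(tm, p), p)
  # estimated values carry ~1e-15 arithmetic fuzz; exact ties need exact rows
  exact <- fit; exact$values[1, ] <- c(24, 8, 24, 24)
  fp <- select_focus_pattern(exact, 1, 0.3)    # ceil(1.2) = 2 mirrors
  expect_equal(fp$n_on, 2)
  expect_equal(which(fp$mask == 1), c(1, 3))   # ties among the 24s by index
  fp_est <- select_focus_pattern(fit, 1, 0.3)
  expect_true(all(which(fp_est$mask == 1) %in% c(1, 3, 4)))
  expect_equal(sum(select_focus_pattern(fit, 1, 1)$mask), 4)
  flat <- fit; flat$values[1, ] <- 5
  expect_equal(which(select_focus_pattern(flat, 1, 0.3)$mask == 1), c(1, 2))
  expect_error(select_focus_pattern(fit, 1, 0), "on_fraction")
  expect_error(select_focus_pattern(fit, 1, 1.2), "on_fraction")
})

test_that("pattern selection is invariant to intensity rescaling", {
  tm <- generate_tm(64, c(12, 12), seed = 9)
  p <- build_hadamard_pattern_set(64)
  meas <- acquire_calibration(tm, p)
  scaled <- meas; scaled$I <- meas$I * 37.5
  px <- c(6, 6)
  expect_equal(select_focus_pattern(rvitm(scaled, p), px)$mask,
               select_focus_pattern(rvitm(meas, p), px)$mask)
})

test_that("selected positive-value mirrors interfere constructively", {
  tm <- generate_tm(64, c(12, 12), seed = 4)
  p <- build_hadamard_pattern_set(64)
  fit <- rvitm(acquire_calibration(tm, p), p)
  px <- pamendo:::resolve_pixel(c(6, 6), c(12, 12))
  fp <- select_focus_pattern(fit, c(6, 6))
  row <- tm$entries[px$index, ]
  er <- sum(row)
  sel_pos <- which(fp$mask == 1 & fit$values[px$index, ] > 0)
  expect_gt(length(sel_pos), 0)
  expect_true(all(cos(Arg(row[sel_pos]) - Arg(er)) > 0))
})

test_that("multi-plane characterisation matches per-plane oracles in order", {
  st <- generate_tm_stack(c(0, 5), 16, c(8, 8), seed = 2)
  p <- build_hadamard_pattern_set(16)
  fits <- characterise_all_planes(st, p)
  expect_length(fits, 2)
  for (i in 1:2) {
    expect_equal(fits[[i]]$plane_z, st[[i]]$plane_z)
    ora <- coef(analytic_rvitm_oracle(st[[i]]))
    expect_lt(norm(coef(fits[[i]]) - ora, "F") / norm(ora, "F"), 1e-9)
  }
  one <- characterise_all_planes(st[[1]], p)
  expect_equal(coef(one[[1]]), coef(fits[[1]]))
})

test_that("fit methods expose coherent summaries, predictions and residuals", {
  tm <- generate_tm(16, c(8, 8), seed = 6)
  p <- build_hadamard_pattern_set(16)
  meas <- acquire_calibration(tm, p)
  fit <- rvitm(meas, p, keep_data = TRUE)
  s <- summary(fit)
  expect_equal(s$n_inputs, 16)
  expect_gt(s$frac_positive, 0.3); expect_lt(s$frac_positive, 0.7)
  pr <- predict(fit, p)
  expect_equal(dim(pr), dim(meas$I))
  r <- residuals(fit)
  expect_equal(dim(r), dim(meas$I))
  expect_true(all(is.finite(r)))
  # model captures the interference term: predictions correlate with data
  expect_gt(cor(as.vector(pr), as.vector(meas$I)), 0.5)
  expect_error(residuals(rvitm(meas, p)), "keep_data")
  expect_output(print(fit), "RVITM")
  expect_output(print(s), "mirrors")
})
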