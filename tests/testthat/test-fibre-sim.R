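# Ground-truth fibre simulator: statistics, determinism, propagation algebra.

test_that("transmission matrices are reproducible and validated", {
  a <- generate_tm(4, c(4, 4), seed = 7)
  b <- generate_tm(4, c(4, 4), seed = 7)
  expect_identical(a$entries, b$entries)
  expect_false(identical(a$entries, generate_tm(4, c(4, 4), seed = 8)$entries))
  expect_error(generate_tm(3, c(4, 4)), "power of two")
  expect_error(generate_tm(4, c(0, 4)), "positive")
})

test_that("entry variance is 1/N in-core and exactly zero outside", {
  tm <- generate_tm(256, c(64, 64), seed = 1)
  incore <- Mod(tm$entries[as.vector(tm$core_mask), ])^2
  expect_gt(mean(incore), 0.95 / 256)
  expect_lt(mean(incore), 1.05 / 256)
  expect_true(all(tm$entries[!as.vector(tm$core_mask), ] == 0))
})

test_that("plane stacks are independent, ordered and deterministic", {
  zs <- c(0, 5, 10, 15, 20)
  st <- generate_tm_stack(zs, 16, c(8, 8), seed = 3)
  expect_length(st, 5)
  expect_equal(vapply(st, `[[`, 0, "plane_z"), zs)
  for (i in 1:4)
    expect_false(identical(st[[i]]$entries, st[[i + 1]]$entries))
  st2 <- generate_tm_stack(zs, 16, c(8, 8), seed = 3)
  expect_identical(st, st2)
  one <- generate_tm_stack(7, 16, c(8, 8), seed = 3)
  expect_identical(one[[1]]$entries,
                   generate_tm(16, c(8, 8), plane_z = 7,
                               seed = pamendo:::derive_seed(3, 1))$entries)
  expect_error(generate_tm_stack(c(0, 5, 5), 16, c(8, 8)), "increasing")
})

test_that("propagation is the squared coherent sum of ON columns", {
  tm <- make_toy_tm(c(1, 1i, 1, 1))
  expect_equal(propagate(tm, c(0, 0, 0, 0))$intensity[1, 1], 0)
  expect_equal(propagate(tm, c(0, 1, 0, 0))$intensity[1, 1], 1)   # |i|^2
  expect_equal(propagate(tm, c(1, 1, 0, 0))$intensity[1, 1], 2)   # |1+i|^2
  expect_error(propagate(tm, c(1, 0)), "length")
  # fields add, intensities do not: 1 and -1 interfere destructively
  tmd <- make_toy_tm(c(1, -1))
  i_both <- propagate(tmd, c(1, 1))$intensity[1, 1]
  i_sum <- propagate(tmd, c(1, 0))$intensity[1, 1] +
    propagate(tmd, c(0, 1))$intensity[1, 1]
  expect_equal(i_both, 0)
  expect_equal(i_sum, 2)
})

test_that("reference field is the all-ON coherent sum", {
  tm <- make_toy_tm(c(1, 1i, 1, 1))
  rf <- reference_field(tm)
  expect_equal(rf$amplitude[1, 1], sqrt(10))
  expect_equal(rf$phase[1, 1], atan2(1, 3))
  tm0 <- make_toy_tm(c(0, 0, 0, 0))
  expect_true(all(reference_field(tm0)$amplitude == 0))
  tm2 <- generate_tm(16, c(8, 8), seed = 5)
  expect_equal(reference_field(tm2)$amplitude^2,
               propagate(tm2, rep(1, 16))$intensity, tolerance = 1e-12)
})

test_that("camera noise is clamped, seeded and has the configured scale", {
  img <- flat_speckle(100, c(100, 100))
  expect_identical(apply_camera_noise(img, 0, 0), img)
  noisy <- apply_camera_noise(img, read_noise_sd = 3, shot_scale = 0, seed = 2)
  expect_true(all(noisy$intensity >= 0))
  expect_true(noisy$noise_applied)
  sd_emp <- sd(noisy$intensity - img$intensity)
  expect_lt(abs(sd_emp - 3) / 3, 0.05)
  expect_identical(apply_camera_noise(img, 3, 0, seed = 2)$intensity,
                   noisy$intensity)
  expect_error(apply_camera_noise(img, -1, 0), "non-negative")
})

test_that("the all-ON reference intensity stays O(1) as N grows", {
  # entry variance 1/N keeps the mean in-core all-ON intensity near 1
  # for any mirror count (the design normalisation of the simulator)
  means <- sapply(c(64, 256, 1024), function(n) {
    mean(sapply(1:10, function(s) {
      tm <- generate_tm(n, c(16, 16), seed = s)
      mean(propagate(tm, rep(1, n))$intensity[tm$core_mask])
    }))
  })
  expect_true(all(abs(means - 1) < 0.2))
})

test_that("the focusing oracle is optimal for small N and tight for larger N", {
  tm2 <- make_toy_tm(c(1, 1))
  o <- phase_conjugation_oracle(tm2, 1)
  expect_equal(o$intensity, 4)
  expect_equal(o$mask, c(1, 1))
  tmd <- make_toy_tm(c(1, -1))
  od <- phase_conjugation_oracle(tmd, 1)
  expect_equal(od$intensity, 1)
  expect_equal(sum(od$mask), 1)
  # exhaustive (N = 8) beats the constructive-phase rule by < 1.5x
  tm8 <- generate_tm(8, c(4, 4), seed = 3)
  px <- which(tm8$core_mask, arr.ind = TRUE)[1, ]
  ex <- phase_conjugation_oracle(tm8, px)$intensity
  row <- tm8$entries[(px[2] - 1) * 4 + px[1], ]
  rule_mask <- Re(row * Conj(sum(row))) > 0
  rule <- Mod(sum(row[rule_mask]))^2
  expect_gte(ex, rule - 1e-12)
  expect_lt(ex / max(rule, 1e-12), 1.5)
  expect_error(phase_conjugation_oracle(generate_tm(4, c(8, 8), seed = 1),
                                        c(1, 1)), "core")
})

test_that("transmission-matrix stacks round-trip through CSV", {
  st <- generate_tm_stack(c(0, 5), 8, c(6, 6), seed = 11)
  dir <- tempfile("tmio")
  write_tm_stack(st, dir)
  back <- read_tm_stack(dir)
  expect_equal(back[[1]]$entries, st[[1]]$entries, tolerance = 1e-12)
  expect_equal(back[[2]]$plane_z, 5)
  expect_equal(back[[1]]$core_mask, st[[1]]$core_mask)
  unlink(dir, recursive = TRUE)
})
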