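# Fixture builders shared across tests; everything is generated in code.

# Transmission matrix with hand-set complex rows (simulator internals used
# deliberately so tests can craft exact fields).
make_toy_tm <- function(rows, output_shape = c(1, 1), pixel_pitch = 1,
                        core_diameter = NULL, plane_z = 0) {
  rows <- if (is.matrix(rows)) rows else matrix(rows, nrow = 1)
  n <- ncol(rows)
  if (is.null(core_diameter))
    core_diameter <- max(output_shape) * pixel_pitch * 2  # everything in-core
  tm <- generate_tm(n, output_shape, pixel_pitch, core_diameter,
                    plane_z = plane_z, seed = 1)
  tm$entries[] <- 0
  tm$entries[seq_len(nrow(rows)), ] <- rows
  tm
}

# Exact circular translation by integer or fractional pixels via the Fourier
# shift theorem (independent of the registration code under test).
fourier_shift <- function(m, dy, dx) {
  M <- nrow(m); N <- ncol(m)
  fy <- 0:(M - 1); fy[fy > M / 2] <- fy[fy > M / 2] - M
  fx <- 0:(N - 1); fx[fx > N / 2] <- fx[fx > N / 2] - N
  ph <- exp(-2i * pi * (outer(fy, rep(1, N)) * dy / M +
                        outer(rep(1, M), fx) * dx / N))
  Re(stats::fft(stats::fft(m) * ph, inverse = TRUE)) / (M * N)
}

# Smooth random test image (band-limited so subpixel shifts are well posed).
smooth_random_image <- function(n = 96, seed = 2, sigma_k = 12) {
  set.seed(seed)
  a <- matrix(stats::rnorm(n * n), n)
  f <- 0:(n - 1); f[f > n / 2] <- f[f > n / 2] - n
  k2 <- outer(f^2, f^2, `+`)
  a <- Re(stats::fft(stats::fft(a) * exp(-k2 / (2 * sigma_k^2)),
                     inverse = TRUE)) / n^2
  a - min(a)
}

# Absorber map holding isolated point absorbers at (x, y, z) micrometres.
make_point_phantom <- function(points, extent = c(20, 20), pitch = 0.5,
                               z_min = 0, z_max = 300, pitch_z = 1) {
  ny <- round(extent[2] / pitch); nx <- round(extent[1] / pitch)
  nz <- round((z_max - z_min) / pitch_z) + 1
  a <- array(0, dim = c(ny, nx, nz))
  ax_y <- (seq_len(ny) - (ny + 1) / 2) * pitch
  ax_x <- (seq_len(nx) - (nx + 1) / 2) * pitch
  zs <- z_min + (seq_len(nz) - 1) * pitch_z
  for (i in seq_len(nrow(points))) {
    iy <- which.min(abs(ax_y - points$y[i]))
    ix <- which.min(abs(ax_x - points$x[i]))
    iz <- which.min(abs(zs - points$z[i]))
    a[iy, ix, iz] <- if (is.null(points$value)) 1 else points$value[i]
  }
  pamendo:::new_absorber_map(a, pitch, pitch_z, z_min, "custom")
}

# Flat in-core speckle image of a constant value.
flat_speckle <- function(value, shape = c(32, 32), pitch = 1) {
  tm <- generate_tm(2, shape, pitch, core_diameter = max(shape) * pitch * 2,
                    seed = 1)
  structure(list(intensity = matrix(value, shape[1], shape[2]),
                 pixel_pitch = pitch, core_mask = tm$core_mask,
                 plane_z = 0, noise_applied = FALSE), class = "speckle_image")
}
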