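## Photoacoustic A-line synthesis: a focused excitation spot interrogates an
## absorber map; per-depth source strength is weighted by the 3D Gaussian
## focus, delayed by one-way time of flight at the coupling-medium speed of
## sound, and convolved with the band-limited sensor impulse response.

#' Ultrasound sensor model
#'
#' Band-pass sensor characterised by its centre frequency and -6 dB
#' amplitude-spectrum full width, with omnidirectional response (the
#' microresonator sensor it emulates is nearly omnidirectional).
#'
#' @param center_freq centre frequency, MHz (default 8).
#' @param minus6dB_bandwidth -6 dB full width of the amplitude spectrum,
#'   MHz (default 6.5).
#' @param sample_rate acquisition sampling rate, MHz (default 250, i.e.
#'   4 ns samples).
#' @return a `"sensor_model"` list.
#' @export
sensor_model <- function(center_freq = 8, minus6dB_bandwidth = 6.5,
                         sample_rate = 250) {
  if (minus6dB_bandwidth <= 0 || minus6dB_bandwidth >= 2 * center_freq)
    stop("need 0 < bandwidth < 2 * center_freq")
  if (sample_rate <= 4 * center_freq)
    stop("sample_rate must exceed 4 * center_freq")
  structure(list(center_freq = center_freq,
                 minus6dB_bandwidth = minus6dB_bandwidth,
                 sample_rate = sample_rate, directivity = "omnidirectional"),
            class = "sensor_model")
}

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf("Sensor: %.3g MHz centre, %.3g MHz -6 dB width, %.4g MHz sampling\n",
              x$center_freq, x$minus6dB_bandwidth, x$sample_rate))
  invisible(x)
}

## Envelope sigma (ns) giving the requested -6 dB spectral full width.
## A Gaussian-envelope burst has a Gaussian amplitude spectrum with
## sigma_f = 1/(2 pi sigma_t); -6 dB amplitude (factor 10^(-6/20) ~ 1/2)
## full width = 2 sqrt(2 ln 10^(6/20)) sigma_f.
sensor_sigma_t <- function(sensor) {
  sigma_f <- sensor$minus6dB_bandwidth / (2 * sqrt(2 * log(10^(6 / 20))))  # MHz
  1e3 / (2 * pi * sigma_f)   # ns
}

new_pa_trace <- function(samples, dt, t0, position = NULL) {
  structure(list(samples = samples, dt = dt, t0 = t0, position = position),
            class = "pa_trace")
}

#' @export
print.pa_trace <- function(x, ...) {
  cat(sprintf("PA trace: %d samples, dt %.3g ns, t0 %.3g ns\n",
              length(x$samples), x$dt, x$t0))
  invisible(x)
}

#' Sensor impulse response
#'
#' Gaussian-envelope cosine burst at the sensor centre frequency, with the
#' envelope width chosen so the amplitude spectrum's -6 dB full width equals
#' the sensor bandwidth; centred on t = 0 and (near-)zero-mean.
#'
#' @param sensor a [sensor_model()].
#' @param duration burst window, ns; must cover at least 6 envelope standard
#'   deviations (default 1000 ns).
#' @return a `"pa_trace"` with `t0 = -duration/2`.
#' @examples
#' h <- sensor_impulse_response(sensor_model())
#' @export
sensor_impulse_response <- function(sensor, duration = 1000) {
  stopifnot(inherits(sensor, "sensor_model"))
  st <- sensor_sigma_t(sensor)
  if (duration < 6 * st)
    stop("duration must cover >= 6 envelope standard deviations (",
         round(6 * st), " ns)")
  dt <- 1e3 / sensor$sample_rate        # ns
  t <- seq(-duration / 2, duration / 2, by = dt)
  h <- exp(-t^2 / (2 * st^2)) * cos(2 * pi * sensor$center_freq * 1e-3 * t)
  new_pa_trace(h, dt, t[1])
}

## Per-depth source strength s(z) of a phantom under a Gaussian focus:
## separable lateral Gaussian (FWHM focus$lateral_fwhm) times axial Gaussian
## centred on focus$plane_z (FWHM focus$axial_fwhm), times pulse energy.
## Returns list(z = depths um, s = strengths).
focus_source_profile <- function(phantom, focus) {
  ax <- phantom_axes(phantom)
  k_lat <- 4 * log(2) / focus$lateral_fwhm^2
  wy <- exp(-k_lat * (ax$y - focus$y)^2)
  wx <- exp(-k_lat * (ax$x - focus$x)^2)
  ## restrict to the lateral support of the focus for speed
  iy <- which(wy > 1e-8); ix <- which(wx > 1e-8)
  if (!length(iy) || !length(ix))
    return(list(z = ax$z, s = numeric(length(ax$z))))
  k_ax <- 4 * log(2) / focus$axial_fwhm^2
  wz <- exp(-k_ax * (ax$z - focus$plane_z)^2)
  s <- vapply(seq_along(ax$z), function(k) {
    if (wz[k] < 1e-10) return(0)
    slab <- phantom$absorption[iy, ix, k, drop = TRUE]
    wz[k] * as.numeric(wy[iy] %*% matrix(slab, length(iy), length(ix)) %*% wx[ix])
  }, 0)
  list(z = ax$z, s = focus$pulse_energy * s)
}

#' Excitation focus description
#'
#' @param x,y lateral focus position, micrometres.
#' @param plane_z focal-plane depth, micrometres.
#' @param lateral_fwhm lateral focus FWHM, micrometres (default 1.2).
#' @param axial_fwhm axial FWHM (depth of field), micrometres (default 22).
#' @param pulse_energy energy at the focus, nJ (default 20).
#' @return an `"excitation_focus"` list.
#' @export
excitation_focus <- function(x = 0, y = 0, plane_z = 0, lateral_fwhm = 1.2,
                             axial_fwhm = 22, pulse_energy = 20) {
  if (lateral_fwhm <= 0 || axial_fwhm <= 0)
    stop("focus extents must be positive")
  structure(list(x = x, y = y, plane_z = plane_z, lateral_fwhm = lateral_fwhm,
                 axial_fwhm = axial_fwhm, pulse_energy = pulse_energy),
            class = "excitation_focus")
}

#' Simulate a single photoacoustic A-line
#'
#' Source strength per depth is the focus-weighted absorption; each depth
#' contributes the sensor impulse response delayed by the one-way time of
#' flight `z / c` (delay-only acoustics: no attenuation or spreading over
#' the sub-millimetre depth range modelled here). Optional additive Gaussian
#' noise.
#'
#' @param phantom an `"absorber_map"`.
#' @param focus an [excitation_focus()]; must lie inside the lateral grid.
#' @param sensor a [sensor_model()].
#' @param c_sound speed of sound in the coupling medium, m/s (default 1485).
#' @param noise_sd additive noise standard deviation, a.u.
#' @param seed noise seed.
#' @param duration recording window, ns (default 1000).
#' @param t0 window start, ns (default 0).
#' @return a `"pa_trace"`.
#' @export
simulate_a_line <- function(phantom, focus, sensor, c_sound = 1485,
                            noise_sd = 0, seed = 1, duration = 1000, t0 = 0) {
  stopifnot(inherits(phantom, "absorber_map"),
            inherits(focus, "excitation_focus"),
            inherits(sensor, "sensor_model"))
  if (c_sound <= 0) stop("c_sound must be positive")
  ax <- phantom_axes(phantom)
  if (focus$x < min(ax$x) - phantom$pitch || focus$x > max(ax$x) + phantom$pitch ||
      focus$y < min(ax$y) - phantom$pitch || focus$y > max(ax$y) + phantom$pitch)
    stop("focus lies outside the phantom lateral extent")
  prof <- focus_source_profile(phantom, focus)
  dt <- 1e3 / sensor$sample_rate
  n <- floor(duration / dt) + 1L
  h <- sensor_impulse_response(sensor, duration = impulse_window(sensor))
  tr <- source_to_trace(prof, h, dt, n, t0, c_sound)
  if (noise_sd > 0)
    tr <- tr + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  new_pa_trace(tr, dt, t0, position = c(x = focus$x, y = focus$y,
                                        plane_z = focus$plane_z))
}

## Impulse-response window: 8 envelope sigmas, rounded up.
impulse_window <- function(sensor) 2 * ceiling(4 * sensor_sigma_t(sensor))

## Bin the per-depth sources onto the time axis (linear split between the
## two neighbouring samples) and convolve with the impulse response.
source_to_trace <- function(prof, h, dt, n, t0, c_sound) {
  src <- numeric(n)
  nz <- which(prof$s != 0)
  if (length(nz)) {
    t_arr <- 1e3 * prof$z[nz] / c_sound      # ns, one-way
    pos <- (t_arr - t0) / dt + 1
    lo <- floor(pos); fr <- pos - lo
    ok <- lo >= 1 & lo <= n
    for (j in which(ok)) {
      src[lo[j]] <- src[lo[j]] + prof$s[nz][j] * (1 - fr[j])
      if (lo[j] + 1 <= n) src[lo[j] + 1] <- src[lo[j] + 1] + prof$s[nz][j] * fr[j]
    }
  }
  if (!any(src != 0)) return(numeric(n))
  full <- stats::convolve(src, rev(h$samples), type = "open")
  offset <- round(-h$t0 / h$dt)              # h is centred on t = 0
  full[offset + seq_len(n)]
}

#' Simulate a raster-scanned frame
#'
#' One A-line per scan position, in raster order, with the excitation focus
#' translated to each position. Scan positions must lie inside the phantom's
#' lateral extent.
#'
#' @param phantom an `"absorber_map"`.
#' @param grid a [make_scan_grid()] result.
#' @param focus focus template (its x, y are overridden per position).
#' @param sensor a [sensor_model()].
#' @inheritParams simulate_a_line
#' @return a `"pa_frames"` object: list with `traces` (positions x samples
#'   matrix), `dt`, `t0`, `grid`, `plane_z`, `filtered`.
#' @export
simulate_frame <- function(phantom, grid, focus, sensor, c_sound = 1485,
                           noise_sd = 0, seed = 1, duration = 1000, t0 = 0) {
  stopifnot(inherits(grid, "scan_grid"))
  ax <- phantom_axes(phantom)
  pos <- grid$positions
  if (min(pos$x) < min(ax$x) - phantom$pitch ||
      max(pos$x) > max(ax$x) + phantom$pitch ||
      min(pos$y) < min(ax$y) - phantom$pitch ||
      max(pos$y) > max(ax$y) + phantom$pitch)
    stop("scan grid extends outside the phantom lateral extent")
  dt <- 1e3 / sensor$sample_rate
  n <- floor(duration / dt) + 1L
  h <- sensor_impulse_response(sensor, duration = impulse_window(sensor))
  traces <- matrix(0, nrow(pos), n)
  for (i in seq_len(nrow(pos))) {
    f <- focus; f$x <- pos$x[i]; f$y <- pos$y[i]
    prof <- focus_source_profile(phantom, f)
    traces[i, ] <- source_to_trace(prof, h, dt, n, t0, c_sound)
  }
  if (noise_sd > 0)
    traces <- traces + with_seed(seed, matrix(stats::rnorm(length(traces),
                                                           sd = noise_sd),
                                              nrow(traces)))
  structure(list(traces = traces, dt = dt, t0 = t0, grid = grid,
                 plane_z = focus$plane_z, filtered = FALSE),
            class = "pa_frames")
}

#' @export
print.pa_frames <- function(x, ...) {
  cat(sprintf("PA frame set: %d traces x %d samples (dt %.3g ns), plane z = %.3g um%s\n",
              nrow(x$traces), ncol(x$traces), x$dt, x$plane_z,
              if (x$filtered) ", filtered" else ""))
  invisible(x)
}
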