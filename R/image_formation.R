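## Signal conditioning and image/volume assembly, plus the imaging-quality
## metrics: enhancement factor, power ratio, focus FWHM, ESF/LSF lateral
## resolution, axial resolution, fluence.

#' Zero-phase low-pass filtering of PA traces
#'
#' 4th-order Butterworth applied forward-backward (zero phase), so
#' band-limited pulse peaks do not shift. Default cutoff 20 MHz.
#'
#' @param x a `"pa_trace"` or `"pa_frames"`.
#' @param cutoff cutoff frequency, MHz (must be below Nyquist).
#' @param order filter order (default 4).
#' @return the filtered object, same class and length; frames are marked
#'   `filtered`.
#' @export
lowpass <- function(x, cutoff = 20, order = 4) UseMethod("lowpass")

lowpass_check <- function(dt, cutoff) {
  nyq <- 1e3 / dt / 2    # MHz
  if (cutoff <= 0 || cutoff >= nyq)
    stop("cutoff must lie in (0, Nyquist = ", nyq, " MHz)")
  nyq
}

## Zero-phase Butterworth low-pass: the forward-backward cascade has the
## squared magnitude response |H(f)|^2 = 1 / (1 + (f/fc)^(2 * order)) and
## zero phase, applied here exactly in the frequency domain after
## odd-reflection end padding (so edges do not wrap; DC passes unchanged).
butter_zerophase <- function(x, dt, cutoff, order) {
  n <- length(x)
  p <- min(n - 1, 256)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  np <- length(xp)
  f <- (0:(np - 1)) / (np * dt * 1e-3)        # MHz
  f <- pmin(f, (np - seq_len(np) + 1) / (np * dt * 1e-3))
  H2 <- 1 / (1 + (f / cutoff)^(2 * order))
  y <- Re(stats::fft(stats::fft(xp) * H2, inverse = TRUE)) / np
  y[(p + 1):(p + n)]
}

#' @export
lowpass.pa_trace <- function(x, cutoff = 20, order = 4) {
  lowpass_check(x$dt, cutoff)
  x$samples <- butter_zerophase(x$samples, x$dt, cutoff, order)
  x
}

#' @export
lowpass.pa_frames <- function(x, cutoff = 20, order = 4) {
  lowpass_check(x$dt, cutoff)
  x$traces <- t(apply(x$traces, 1, function(tr)
    butter_zerophase(tr, x$dt, cutoff, order)))
  x$filtered <- TRUE
  x
}

#' One-way time-of-flight to depth conversion
#'
#' `z = c * t`: photoacoustic generation propagates one way from absorber to
#' sensor, so no factor of two.
#'
#' @param t_ns time, nanoseconds.
#' @param c_sound speed of sound, m/s (default 1485).
#' @return depth, micrometres.
#' @examples
#' time_to_depth(1000)   # 1485 um
#' @export
time_to_depth <- function(t_ns, c_sound = 1485) {
  if (c_sound <= 0) stop("c_sound must be positive")
  c_sound * t_ns * 1e-3
}

new_pa_image <- function(pixels, grid, plane_z) {
  structure(list(pixels = pixels, pitch = grid$step, mask = grid$mask,
                 xs = grid$xs, ys = grid$ys, plane_z = plane_z, grid = grid),
            class = "pa_image")
}

#' @export
print.pa_image <- function(x, ...) {
  cat(sprintf("PA image: %d x %d pixels (%.3g um pitch), plane z = %.3g um\n",
              nrow(x$pixels), ncol(x$pixels), x$pitch, x$plane_z))
  invisible(x)
}

#' Maximum intensity projection of a frame set
#'
#' Per scan position, the pixel value is the maximum over time of the
#' envelope (analytic-signal magnitude) of the trace, placed on the raster
#' lattice of the scan grid (zero outside the circular FOV).
#'
#' @param frames a `"pa_frames"` (usually after [lowpass()]).
#' @return a `"pa_image"`.
#' @export
mip <- function(frames) {
  stopifnot(inherits(frames, "pa_frames"))
  if (nrow(frames$traces) == 0) stop("empty frame set")
  vals <- apply(frames$traces, 1, function(tr) max(analytic_envelope(tr)))
  g <- frames$grid
  px <- matrix(0, g$ny, g$nx)
  px[cbind(g$positions$iy, g$positions$ix)] <- vals
  new_pa_image(px, g, frames$plane_z)
}

#' Assemble a depth-resolved volume by acoustic sectioning
#'
#' Maps each trace's time axis to depth via [time_to_depth()] (z pitch =
#' `c * dt`). `signal = "envelope"` stores the analytic-signal magnitude
#' (used for display and MIP); `signal = "signed"` stores the filtered
#' bipolar amplitude, the form used for axial-resolution metrology where the
#' positive-peak width is what the time-of-flight mapping resolves.
#'
#' @param frames a `"pa_frames"`.
#' @param c_sound speed of sound, m/s.
#' @param signal `"envelope"` or `"signed"`.
#' @return a `"pa_volume"`: list with `values` (ny x nx x nz), `pitch`
#'   lateral, `zs` depth axis (um), `mode = "acoustic"`, `signal`.
#' @export
assemble_volume_acoustic <- function(frames, c_sound = 1485,
                                     signal = c("envelope", "signed")) {
  stopifnot(inherits(frames, "pa_frames"))
  signal <- match.arg(signal)
  g <- frames$grid
  n_t <- ncol(frames$traces)
  zs <- time_to_depth(frames$t0 + (seq_len(n_t) - 1) * frames$dt, c_sound)
  v <- array(0, dim = c(g$ny, g$nx, n_t))
  for (i in seq_len(nrow(g$positions))) {
    tr <- frames$traces[i, ]
    if (signal == "envelope") tr <- analytic_envelope(tr)
    v[g$positions$iy[i], g$positions$ix[i], ] <- tr
  }
  structure(list(values = v, pitch = g$step, zs = zs, mode = "acoustic",
                 signal = signal, mask = g$mask),
            class = "pa_volume")
}

#' Assemble a volume from per-plane images (optical sectioning)
#'
#' Stacks MIP images acquired at successive focal planes; the z axis is the
#' plane positions (default plane interval 5 um in the imaging protocol this
#' emulates).
#'
#' @param per_plane_images list of `"pa_image"` sharing one scan grid.
#' @param plane_zs plane depths, micrometres; defaults to the images'
#'   `plane_z`; must be strictly increasing.
#' @return a `"pa_volume"` with `mode = "optical"`.
#' @export
assemble_volume_optical <- function(per_plane_images, plane_zs = NULL) {
  stopifnot(length(per_plane_images) >= 1,
            all(vapply(per_plane_images, inherits, TRUE, "pa_image")))
  d1 <- dim(per_plane_images[[1]]$pixels)
  p1 <- per_plane_images[[1]]$pitch
  for (im in per_plane_images)
    if (!identical(dim(im$pixels), d1) || im$pitch != p1)
      stop("per-plane images must share one scan grid")
  if (is.null(plane_zs))
    plane_zs <- vapply(per_plane_images, `[[`, 0, "plane_z")
  if (length(plane_zs) > 1 && any(diff(plane_zs) <= 0))
    stop("plane_zs must be strictly increasing")
  v <- array(0, dim = c(d1, length(per_plane_images)))
  for (k in seq_along(per_plane_images)) v[, , k] <- per_plane_images[[k]]$pixels
  structure(list(values = v, pitch = p1, zs = plane_zs, mode = "optical",
                 signal = "envelope", mask = per_plane_images[[1]]$mask),
            class = "pa_volume")
}

#' @export
print.pa_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("PA volume (%s sectioning, %s): %d x %d x %d, z span %.3g um\n",
              x$mode, x$signal, d[1], d[2], d[3], depth_span(x)))
  invisible(x)
}

#' Depth span of a volume
#'
#' First-to-last distance along the z axis, micrometres.
#' @param volume a `"pa_volume"`.
#' @export
depth_span <- function(volume) {
  stopifnot(inherits(volume, "pa_volume"))
  diff(range(volume$zs))
}

#' Maximum intensity projection of a volume
#'
#' Pixelwise maximum of the envelope values over z; for an acoustic volume
#' this equals the 2D [mip()] of the same frames.
#' @param volume a `"pa_volume"`.
#' @return matrix of MIP values.
#' @export
volume_mip <- function(volume) {
  stopifnot(inherits(volume, "pa_volume"))
  apply(if (volume$signal == "signed") abs(volume$values) else volume$values,
        c(1, 2), max)
}

image_matrix <- function(img) {
  if (inherits(img, "speckle_image")) list(m = img$intensity, pitch = img$pixel_pitch,
                                           mask = img$core_mask)
  else if (inherits(img, "pa_image")) list(m = img$pixels, pitch = img$pitch,
                                           mask = img$mask)
  else list(m = as.matrix(img), pitch = 1, mask = NULL)
}

disc_distance <- function(shape, pitch, center_rc) {
  ax <- grid_axes(shape, pitch)
  cy <- ax$y[center_rc[1]]; cx <- ax$x[center_rc[2]]
  sqrt(outer((ax$y - cy)^2, (ax$x - cx)^2, `+`))
}

#' Enhancement factor of a focus image
#'
#' Ratio between the maximum intensity within the focal disc and the mean
#' background intensity, where the background is the in-core region farther
#' than `3 * fwhm` from the focus.
#'
#' @param img a `"speckle_image"`, `"pa_image"` or matrix.
#' @param center focus centre as (row, col); defaults to the image argmax.
#' @param fwhm focus FWHM, micrometres; defaults to the measured
#'   [profile_fwhm()] through the peak.
#' @return the enhancement factor (`Inf` with a warning if the background
#'   mean is zero).
#' @export
enhancement_factor <- function(img, center = NULL, fwhm = NULL) {
  im <- image_matrix(img)
  if (all(im$m == 0)) stop("image is identically zero")
  if (is.null(center)) {
    w <- which(im$m == max(im$m), arr.ind = TRUE)[1, ]
    center <- c(w[1], w[2])
  }
  if (is.null(fwhm)) fwhm <- profile_fwhm(img, center = center)
  d <- disc_distance(dim(im$m), im$pitch, center)
  inside <- d <= fwhm
  bg <- d > 3 * fwhm
  if (!is.null(im$mask)) bg <- bg & im$mask
  if (!any(bg) || mean(im$m[bg]) == 0) {
    warning("background mean is zero; enhancement factor undefined")
    return(Inf)
  }
  max(im$m[inside]) / mean(im$m[bg])
}

#' Power ratio of a focus image
#'
#' Fraction of the total (in-core) energy that falls within the disc of
#' diameter one FWHM centred on the focus.
#'
#' @inheritParams enhancement_factor
#' @return ratio in \[0, 1\].
#' @export
power_ratio <- function(img, center = NULL, fwhm = NULL) {
  im <- image_matrix(img)
  if (is.null(center)) {
    w <- which(im$m == max(im$m), arr.ind = TRUE)[1, ]
    center <- c(w[1], w[2])
  }
  if (is.null(fwhm)) fwhm <- profile_fwhm(img, center = center)
  d <- disc_distance(dim(im$m), im$pitch, center)
  total_mask <- if (!is.null(im$mask)) im$mask else array(TRUE, dim(im$m))
  total <- sum(im$m[total_mask])
  if (total <= 0) stop("total image energy is zero")
  sum(im$m[d <= fwhm / 2 & total_mask]) / total
}

fwhm_interp <- function(y, x) {
  ipk <- which.max(y)
  if (ipk == 1 || ipk == length(y) || y[ipk] <= y[1] || y[ipk] <= y[length(y)])
    stop("profile peak must lie strictly above the profile ends")
  half <- y[ipk] / 2
  left <- NULL
  for (i in seq(ipk, 2)) if (y[i - 1] < half && y[i] >= half) {
    left <- x[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
    break
  }
  right <- NULL
  for (i in seq(ipk, length(y) - 1)) if (y[i] >= half && y[i + 1] < half) {
    right <- x[i] + (y[i] - half) / (y[i] - y[i + 1]) * (x[i + 1] - x[i])
    break
  }
  if (is.null(left) || is.null(right))
    stop("no half-maximum crossings found on both sides of the peak")
  right - left
}

#' Full width at half maximum of an intensity profile
#'
#' Linear-interpolated width at half of the peak amplitude. Given an image,
#' the profile is taken along a grid line through the peak (or the given
#' centre); given a vector, supply its sample pitch.
#'
#' @param x a numeric profile vector, or a `"speckle_image"`/`"pa_image"`/
#'   matrix.
#' @param pitch sample spacing of a vector profile, micrometres (default 1).
#' @param center (row, col) through which to profile an image; defaults to
#'   the image argmax.
#' @param line `"x"` (along a row) or `"y"` (along a column) for images.
#' @return FWHM in micrometres.
#' @examples
#' profile_fwhm(exp(-(seq(-10, 10, 0.1))^2 / (2 * 2^2)), pitch = 0.1)
#' @export
profile_fwhm <- function(x, pitch = 1, center = NULL, line = c("x", "y")) {
  line <- match.arg(line)
  if (is.numeric(x) && is.null(dim(x))) {
    return(fwhm_interp(x, (seq_along(x) - 1) * pitch))
  }
  im <- image_matrix(x)
  if (is.null(center)) {
    w <- which(im$m == max(im$m), arr.ind = TRUE)[1, ]
    center <- c(w[1], w[2])
  }
  prof <- if (line == "x") im$m[center[1], ] else im$m[, center[2]]
  fwhm_interp(prof, (seq_along(prof) - 1) * im$pitch)
}

#' Lateral resolution from an edge spread function
#'
#' Averages profiles at `n_adjacent` adjacent positions across an edge to
#' form the ESF, differentiates it into the LSF, and reports the FWHM of an
#' unweighted least-squares Gaussian fit to the LSF.
#'
#' @param image a `"pa_image"` or matrix (edge assumed vertical: intensity
#'   varies along x).
#' @param rows indices of the adjacent profiles to average; defaults to
#'   `n_adjacent` rows centred mid-image.
#' @param cols column range containing the edge; defaults to all columns.
#' @param n_adjacent number of adjacent profiles (default 10).
#' @return lateral resolution, micrometres, with attributes `esf`, `lsf`,
#'   `fit`.
#' @export
lateral_resolution_esf <- function(image, rows = NULL, cols = NULL,
                                   n_adjacent = 10) {
  im <- image_matrix(image)
  nr <- nrow(im$m)
  if (is.null(rows)) {
    mid <- round(nr / 2)
    rows <- seq(mid - floor((n_adjacent - 1) / 2), length.out = n_adjacent)
    rows <- rows[rows >= 1 & rows <= nr]
  }
  if (is.null(cols)) cols <- seq_len(ncol(im$m))
  esf <- colMeans(im$m[rows, cols, drop = FALSE])
  dif <- diff(esf)
  if (any(dif > 0) && any(dif < 0) &&
      min(sum(dif[dif > 0]), -sum(dif[dif < 0])) > 0.05 * abs(sum(dif)))
    warning("ESF is not monotone after averaging; fitting best-effort")
  lsf <- abs(dif) / im$pitch
  xs <- (cols[-length(cols)] - 1 + 0.5) * im$pitch
  fit <- fit_gaussian(xs, lsf)
  structure(fit$fwhm, esf = esf, lsf = lsf, fit = fit)
}

#' Axial resolution from a volume z-profile
#'
#' Extracts the z-profile through a structure and reports the FWHM of a
#' Gaussian fit to its dominant lobe. For signed (acoustic, bipolar) values
#' the positive part is used — mirroring the instrument convention of
#' mapping the positive-peak width of the time-resolved signal to distance.
#' The profile must have a single dominant lobe (one connected region above
#' half maximum); multi-lobed profiles raise an error listing the lobes.
#'
#' @param volume a `"pa_volume"`.
#' @param at (row, col) through which to profile; defaults to the location
#'   of the volume maximum.
#' @return axial FWHM, micrometres, with attributes `profile`, `zs`.
#' @export
axial_resolution <- function(volume, at = NULL) {
  stopifnot(inherits(volume, "pa_volume"))
  if (is.null(at)) {
    ref <- if (volume$signal == "signed") volume$values else volume$values
    w <- which(ref == max(ref), arr.ind = TRUE)[1, ]
    at <- c(w[1], w[2])
  }
  prof <- volume$values[at[1], at[2], ]
  if (volume$signal == "signed") prof <- pmax(prof, 0)
  if (max(prof) <= 0) stop("z-profile has no positive mass at this location")
  above <- prof >= max(prof) / 2
  runs <- rle(above)
  n_lobes <- sum(runs$values)
  if (n_lobes > 1) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    lobes <- paste(sprintf("[%.3g, %.3g] um", volume$zs[starts[runs$values]],
                           volume$zs[ends[runs$values]]), collapse = ", ")
    stop("z-profile has ", n_lobes, " lobes above half maximum: ", lobes)
  }
  fit <- fit_gaussian(volume$zs, prof, baseline = FALSE)
  structure(fit$fwhm, profile = prof, zs = volume$zs)
}

#' Optical fluence at the focus
#'
#' Energy divided by the focal-spot area (disc of the given diameter),
#' converted to J/cm^2.
#'
#' @param pulse_energy_nJ pulse energy at the focus, nanojoules.
#' @param focus_diameter_um focal-spot diameter, micrometres.
#' @return fluence, J/cm^2.
#' @examples
#' fluence(20, 1.2)   # ~ 1.77 J/cm^2
#' @export
fluence <- function(pulse_energy_nJ, focus_diameter_um) {
  if (focus_diameter_um <= 0) stop("focus diameter must be positive")
  area_cm2 <- pi * (focus_diameter_um / 2 * 1e-4)^2
  pulse_energy_nJ * 1e-9 / area_cm2
}

#' Write imaging metrics as CSV rows
#'
#' @param metrics named list or vector of metric values.
#' @param units character vector of units (recycled).
#' @param path output CSV path.
#' @param config_hash optional configuration hash recorded per row.
#' @export
write_metrics_csv <- function(metrics, units = "", path, config_hash = "") {
  df <- data.frame(metric = names(metrics),
                   value = as.numeric(unlist(metrics)),
                   units = rep_len(units, length(metrics)),
                   config_hash = config_hash)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
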