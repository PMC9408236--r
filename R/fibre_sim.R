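## Synthetic multimode fibre: ground-truth complex transmission matrices,
## propagation of binary DMD patterns to output-plane speckle intensities,
## and a simple camera-noise model. The simulator is the only component that
## ever sees the complex field; the estimation pipeline works from
## intensities alone, as in the physical instrument.

#' Generate a synthetic fibre transmission matrix
#'
#' Draws a ground-truth complex transmission matrix mapping `n_inputs` DMD
#' micromirrors to the pixels of the distal output plane. Entries are i.i.d.
#' circular complex Gaussian with variance `1/n_inputs` inside the fibre-core
#' disc and exactly zero outside, so the all-ON reference intensity is O(1)
#' per pixel regardless of the mirror count. Micromirror masks are indexed in
#' row-major order over the square DMD sub-region (side `sqrt(n_inputs)`).
#'
#' @param n_inputs number of micromirrors N; must be a power of two >= 2
#'   (Sylvester-Hadamard calibration compatibility).
#' @param output_shape integer (rows, cols) of the output-plane pixel grid.
#' @param pixel_pitch camera pixel pitch at the output plane, micrometres.
#' @param core_diameter fibre core diameter, micrometres; defaults to the
#'   disc inscribed in the pixel grid.
#' @param plane_z focal-plane offset from the fibre tip, micrometres.
#' @param seed integer seed; the same (parameters, seed) reproduce the matrix
#'   bit-identically.
#' @return an object of class `"tmatrix"`: list with `entries` (complex
#'   pixels x N matrix, pixels flattened column-major as in R matrices),
#'   `n_inputs`, `output_shape`, `pixel_pitch`, `core_diameter`, `core_mask`,
#'   `plane_z`, `seed`.
#' @examples
#' tm <- generate_tm(16, c(12, 12), seed = 1)
#' mean(Mod(tm$entries[tm$core_mask, ])^2) * 16  # ~ 1
#' @export
generate_tm <- function(n_inputs, output_shape, pixel_pitch = 1,
                        core_diameter = NULL, plane_z = 0, seed = 1) {
  if (!is_power_of_two(n_inputs) || n_inputs < 2)
    stop("n_inputs must be a power of two >= 2 (got ", n_inputs,
         "); Sylvester-Hadamard calibration requires it")
  output_shape <- as.integer(output_shape)
  if (length(output_shape) != 2L || any(output_shape < 1L))
    stop("output_shape must be two positive integers (rows, cols)")
  if (pixel_pitch <= 0) stop("pixel_pitch must be positive")
  if (is.null(core_diameter)) core_diameter <- min(output_shape) * pixel_pitch
  if (core_diameter <= 0) stop("core_diameter must be positive")
  mask <- core_mask_matrix(output_shape, pixel_pitch, core_diameter)
  if (!any(mask)) stop("no pixels fall inside the core disc")
  m <- prod(output_shape)
  n <- as.integer(n_inputs)
  sd1 <- sqrt(1 / (2 * n))
  entries <- with_seed(seed, {
    e <- matrix(complex(real = stats::rnorm(m * n, sd = sd1),
                        imaginary = stats::rnorm(m * n, sd = sd1)),
                nrow = m, ncol = n)
    e[!as.vector(mask), ] <- 0 + 0i
    e
  })
  structure(list(entries = entries, n_inputs = n, output_shape = output_shape,
                 pixel_pitch = pixel_pitch, core_diameter = core_diameter,
                 core_mask = mask, plane_z = plane_z, seed = seed),
            class = "tmatrix")
}

#' @export
print.tmatrix <- function(x, ...) {
  cat("Synthetic fibre transmission matrix\n")
  cat(sprintf("  %d micromirrors -> %d x %d pixels (%.3g um pitch)\n",
              x$n_inputs, x$output_shape[1], x$output_shape[2], x$pixel_pitch))
  cat(sprintf("  core diameter %.3g um (%d in-core pixels), plane z = %.3g um\n",
              x$core_diameter, sum(x$core_mask), x$plane_z))
  invisible(x)
}

#' Generate transmission matrices for a stack of focal planes
#'
#' One independent transmission matrix per focal plane, with per-plane seeds
#' derived deterministically from the master seed and the plane index.
#'
#' @param plane_zs strictly increasing focal-plane offsets, micrometres.
#' @param seed master seed.
#' @inheritParams generate_tm
#' @return list of `"tmatrix"` objects, one per plane, in plane order.
#' @export
generate_tm_stack <- function(plane_zs, n_inputs, output_shape,
                              pixel_pitch = 1, core_diameter = NULL,
                              seed = 1) {
  if (length(plane_zs) < 1L) stop("plane_zs must be non-empty")
  if (any(diff(plane_zs) <= 0))
    stop("plane_zs must be strictly increasing (duplicates rejected)")
  lapply(seq_along(plane_zs), function(i) {
    generate_tm(n_inputs, output_shape, pixel_pitch, core_diameter,
                plane_z = plane_zs[i], seed = derive_seed(seed, i))
  })
}

pattern_mask <- function(pattern, n_inputs) {
  mask <- if (inherits(pattern, "focus_pattern")) pattern$mask else as.numeric(pattern)
  if (length(mask) != n_inputs)
    stop("pattern length ", length(mask), " does not match n_inputs ", n_inputs)
  if (any(!mask %in% c(0, 1))) stop("pattern must be strictly binary (0/1)")
  mask
}

#' Propagate a binary DMD pattern through the fibre
#'
#' Coherently sums the transmission-matrix columns of the ON mirrors and
#' returns the resulting output-plane intensity (noiseless); intensity at
#' pixel m is `|sum_n mask_n entry_mn|^2`.
#'
#' @param tm a `"tmatrix"`.
#' @param pattern binary vector of length `tm$n_inputs` (row-major mirror
#'   order) or a [select_focus_pattern()] result.
#' @return a `"speckle_image"`: list with `intensity` (rows x cols matrix),
#'   `pixel_pitch`, `core_mask`, `plane_z`, `noise_applied`.
#' @export
propagate <- function(tm, pattern) {
  stopifnot(inherits(tm, "tmatrix"))
  mask <- pattern_mask(pattern, tm$n_inputs)
  field <- as.vector(tm$entries %*% mask)
  structure(list(
    intensity = matrix(Mod(field)^2, tm$output_shape[1], tm$output_shape[2]),
    pixel_pitch = tm$pixel_pitch, core_mask = tm$core_mask,
    plane_z = tm$plane_z, noise_applied = FALSE), class = "speckle_image")
}

#' Reference output field (all micromirrors ON)
#'
#' The coherent sum of all transmission-matrix columns: amplitude `A_R` and
#' phase `phi_R` per output pixel. `A_R^2` equals the all-ON speckle
#' intensity.
#'
#' @param tm a `"tmatrix"`.
#' @return a `"reference_field"`: list with `amplitude` and `phase` matrices
#'   (phase in (-pi, pi]) and `field` (complex matrix).
#' @export
reference_field <- function(tm) {
  stopifnot(inherits(tm, "tmatrix"))
  f <- matrix(rowSums(tm$entries), tm$output_shape[1], tm$output_shape[2])
  structure(list(amplitude = Mod(f), phase = Arg(f), field = f),
            class = "reference_field")
}

#' Add camera noise to a speckle image
#'
#' Additive Gaussian read noise plus a Gaussian shot-noise approximation with
#' standard deviation `shot_scale * sqrt(intensity)`; negative results are
#' clamped to zero.
#'
#' @param img a `"speckle_image"`.
#' @param read_noise_sd read-noise standard deviation, intensity units (a.u.).
#' @param shot_scale shot-noise scale, a.u.
#' @param seed integer seed.
#' @return the noised `"speckle_image"` (`noise_applied = TRUE` when any
#'   noise parameter is positive).
#' @export
apply_camera_noise <- function(img, read_noise_sd = 0, shot_scale = 0, seed = 1) {
  stopifnot(inherits(img, "speckle_image"))
  if (read_noise_sd < 0 || shot_scale < 0)
    stop("noise parameters must be non-negative")
  if (read_noise_sd == 0 && shot_scale == 0) return(img)
  img$intensity <- add_intensity_noise(img$intensity, read_noise_sd, shot_scale, seed)
  img$noise_applied <- TRUE
  img
}

add_intensity_noise <- function(I, read_noise_sd, shot_scale, seed) {
  with_seed(seed, {
    noisy <- I + stats::rnorm(length(I), sd = read_noise_sd) +
      stats::rnorm(length(I), sd = shot_scale * sqrt(as.vector(I)))
    array(pmax(noisy, 0), dim = dim(I))
  })
}

#' Best-focus intensity bound at a target pixel (testing oracle)
#'
#' Upper-bound oracle for binary-amplitude focusing quality, independent of
#' the RVITM pipeline. For `n_inputs <= 16` the best binary pattern is found
#' by exhaustive search over all `2^N` patterns; above that, the
#' constructive-interference rule is used (mirror ON iff
#' `cos(theta_mn - phi_R) > 0`, i.e. its field at the target is within 90
#' degrees of the all-ON reference phase).
#'
#' @param tm a `"tmatrix"`.
#' @param target_pixel linear index or (row, col) of an in-core pixel.
#' @return list with `intensity` (focus intensity at the target) and `mask`
#'   (the binary pattern achieving it).
#' @export
phase_conjugation_oracle <- function(tm, target_pixel) {
  stopifnot(inherits(tm, "tmatrix"))
  px <- resolve_pixel(target_pixel, tm$output_shape)
  if (!tm$core_mask[px$row, px$col]) stop("target pixel lies outside the core disc")
  t_row <- tm$entries[px$index, ]
  n <- tm$n_inputs
  if (n <= 16) {
    n_pat <- 2^n
    bits <- matrix(0, n_pat, n)
    for (j in seq_len(n)) bits[, j] <- bitwAnd(0:(n_pat - 1), bitwShiftL(1L, j - 1L)) > 0
    intens <- Mod(bits %*% t_row)^2
    best <- which.max(intens)
    list(intensity = as.numeric(intens[best]), mask = as.numeric(bits[best, ]))
  } else {
    er <- sum(t_row)
    mask <- as.numeric(Re(t_row * Conj(er)) > 0)
    list(intensity = Mod(sum(t_row[mask == 1]))^2, mask = mask)
  }
}

#' Write a speckle image (or any non-negative image matrix) as 32-bit TIFF
#'
#' @param img a `"speckle_image"`, `"pa_image"`, or numeric matrix.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  m <- if (inherits(img, "speckle_image")) img$intensity
       else if (inherits(img, "pa_image")) img$pixels
       else as.matrix(img)
  tiff::writeTIFF(m / max(max(m), .Machine$double.eps), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' Persist / restore a transmission-matrix stack as plain-text CSV
#'
#' Writes one CSV pair (real and imaginary parts) per plane plus a metadata
#' CSV, so ground-truth matrices can be archived portably.
#'
#' @param stack list of `"tmatrix"` (or a single one).
#' @param dir output directory (created if needed).
#' @return `write_tm_stack`: the directory, invisibly; `read_tm_stack`: the
#'   restored list of `"tmatrix"` objects.
#' @export
write_tm_stack <- function(stack, dir) {
  if (inherits(stack, "tmatrix")) stack <- list(stack)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(
    plane = seq_along(stack),
    plane_z = vapply(stack, `[[`, 0, "plane_z"),
    n_inputs = vapply(stack, `[[`, 0L, "n_inputs"),
    rows = vapply(stack, function(s) s$output_shape[1], 0L),
    cols = vapply(stack, function(s) s$output_shape[2], 0L),
    pixel_pitch = vapply(stack, `[[`, 0, "pixel_pitch"),
    core_diameter = vapply(stack, `[[`, 0, "core_diameter"),
    seed = vapply(stack, function(s) as.double(s$seed), 0))
  utils::write.csv(meta, file.path(dir, "tm_meta.csv"), row.names = FALSE)
  for (i in seq_along(stack)) {
    utils::write.table(Re(stack[[i]]$entries),
      file.path(dir, sprintf("tm_plane%03d_re.csv", i)),
      sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(Im(stack[[i]]$entries),
      file.path(dir, sprintf("tm_plane%03d_im.csv", i)),
      sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_tm_stack
#' @export
read_tm_stack <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "tm_meta.csv"))
  lapply(seq_len(nrow(meta)), function(i) {
    re <- as.matrix(utils::read.table(
      file.path(dir, sprintf("tm_plane%03d_re.csv", i)), sep = ","))
    im <- as.matrix(utils::read.table(
      file.path(dir, sprintf("tm_plane%03d_im.csv", i)), sep = ","))
    shape <- c(meta$rows[i], meta$cols[i])
    structure(list(
      entries = matrix(complex(real = re, imaginary = im), nrow = nrow(re)),
      n_inputs = meta$n_inputs[i], output_shape = shape,
      pixel_pitch = meta$pixel_pitch[i], core_diameter = meta$core_diameter[i],
      core_mask = core_mask_matrix(shape, meta$pixel_pitch[i], meta$core_diameter[i]),
      plane_z = meta$plane_z[i], seed = meta$seed[i]), class = "tmatrix")
  })
}
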