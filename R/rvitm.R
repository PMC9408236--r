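## RVITM estimation: Hadamard calibration-pattern construction, acquisition
## of intensity-only speckle measurements, the rvitm() estimator and its
## methods, the analytic oracle, focus-pattern selection, and multi-plane
## characterisation.

#' Build the Hadamard calibration pattern set
#'
#' Constructs the Sylvester Hadamard matrix `H` of order `N` and the two
#' binary matrices `H1 = (H + 1)/2` and `H2 = (-H + 1)/2`. The display
#' sequence is all columns of `H1` followed by all columns of `H2` (2N binary
#' patterns); the first `H1` pattern is all-ON and the first `H2` pattern is
#' all-OFF.
#'
#' @param N Hadamard order (number of micromirrors); a power of two >= 2.
#' @return an object of class `"hadamard_patterns"`: list with `N`, `H`,
#'   `H1`, `H2` and `display` (N x 2N matrix whose columns are the patterns
#'   in display order).
#' @examples
#' p <- build_hadamard_pattern_set(4)
#' all(p$H1 + p$H2 == 1)
#' @export
build_hadamard_pattern_set <- function(N) {
  if (!is_power_of_two(N) || N < 2)
    stop("N must be a power of two >= 2 for the Sylvester construction")
  H <- pracma::hadamard(as.integer(N))
  H1 <- (H + 1) / 2
  H2 <- (-H + 1) / 2
  structure(list(N = as.integer(N), H = H, H1 = H1, H2 = H2,
                 display = cbind(H1, H2)), class = "hadamard_patterns")
}

#' @export
print.hadamard_patterns <- function(x, ...) {
  cat(sprintf("Hadamard calibration set: order N = %d, %d display patterns\n",
              x$N, 2L * x$N))
  invisible(x)
}

#' Acquire a calibration measurement set
#'
#' Displays every calibration pattern through the (simulated) fibre and
#' records the output-plane intensity of each, in display order. This is the
#' intensity-only data from which the RVITM is estimated; the complex field
#' is never observed.
#'
#' @param tm a `"tmatrix"` (simulator stand-in for the physical fibre).
#' @param patterns a `"hadamard_patterns"` set with `N == tm$n_inputs`.
#' @param read_noise_sd,shot_scale camera-noise parameters, see
#'   [apply_camera_noise()]; both zero for a noiseless acquisition.
#' @param seed noise seed.
#' @return a `"speckle_measurements"`: list with `I` (pixels x 2N intensity
#'   matrix, columns in display order), `n_inputs`, `plane_z`,
#'   `output_shape`, `pixel_pitch`, `core_mask`.
#' @export
acquire_calibration <- function(tm, patterns, read_noise_sd = 0,
                                shot_scale = 0, seed = 1) {
  stopifnot(inherits(tm, "tmatrix"), inherits(patterns, "hadamard_patterns"))
  if (patterns$N != tm$n_inputs)
    stop("pattern length ", patterns$N, " does not match n_inputs ", tm$n_inputs)
  I <- Mod(tm$entries %*% patterns$display)^2
  if (read_noise_sd < 0 || shot_scale < 0)
    stop("noise parameters must be non-negative")
  if (read_noise_sd > 0 || shot_scale > 0)
    I <- add_intensity_noise(I, read_noise_sd, shot_scale, seed)
  structure(list(I = I, n_inputs = tm$n_inputs, plane_z = tm$plane_z,
                 output_shape = tm$output_shape, pixel_pitch = tm$pixel_pitch,
                 core_mask = tm$core_mask), class = "speckle_measurements")
}

#' Fit the real-valued intensity transmission matrix (RVITM)
#'
#' Estimates, for every output pixel m and micromirror n, the real-valued
#' transmission constant
#' `rvitm_mn = 2N * A_R(m) * A_mn * cos(theta_mn - phi_R(m))`
#' from intensity-only Hadamard measurements: the measurement matrix has the
#' all-ON column subtracted after doubling (`2 I_mk - I_m1`) and is
#' right-multiplied by `[H, -H]'`, which inverts the Hadamard pattern basis.
#' A positive entry means that switching the mirror ON interferes
#' constructively with the all-mirrors-ON reference field at that pixel, so
#' ranking a pixel's row selects mirrors for focusing without any phase
#' measurement.
#'
#' @param measurements a `"speckle_measurements"` from [acquire_calibration()]
#'   (2N columns, display order).
#' @param patterns the `"hadamard_patterns"` used for the acquisition.
#' @param keep_data keep the calibration intensities inside the fit (needed
#'   by [residuals.rvitm()] without re-supplying them); default FALSE to
#'   keep fits small.
#' @return an object of class `"rvitm"`: list with `values` (pixels x N real
#'   matrix), `n_inputs`, `plane_z`, `output_shape`, `pixel_pitch`,
#'   `core_mask`, `call`, and optionally `measurements`.
#' @seealso [analytic_rvitm_oracle()], [select_focus_pattern()]
#' @examples
#' tm <- generate_tm(4, c(1, 1), core_diameter = 2, seed = 1)
#' p <- build_hadamard_pattern_set(4)
#' fit <- rvitm(acquire_calibration(tm, p), p)
#' coef(fit)
#' @export
rvitm <- function(measurements, patterns, keep_data = FALSE) {
  stopifnot(inherits(measurements, "speckle_measurements"),
            inherits(patterns, "hadamard_patterns"))
  N <- patterns$N
  if (measurements$n_inputs != N)
    stop("measurement set was acquired with a different mirror count")
  if (ncol(measurements$I) != 2L * N)
    stop("expected ", 2L * N, " measurement columns (display order), got ",
         ncol(measurements$I))
  ## [H, -H]' inverts the pattern basis (up to the 2N scale retained here).
  basis_t <- rbind(t(patterns$H), -t(patterns$H))
  values <- (2 * measurements$I - measurements$I[, 1]) %*% basis_t
  out <- structure(list(values = values, n_inputs = N,
                        plane_z = measurements$plane_z,
                        output_shape = measurements$output_shape,
                        pixel_pitch = measurements$pixel_pitch,
                        core_mask = measurements$core_mask,
                        oracle = FALSE, call = match.call()),
                   class = "rvitm")
  if (keep_data) out$measurements <- measurements
  out
}

#' Analytic RVITM oracle from the ground-truth transmission matrix
#'
#' Evaluates `2N * A_R(m) * A_mn * cos(theta_mn - phi_R(m))` directly from
#' the simulator's complex transmission matrix, on the same scale as
#' [rvitm()]. Intended as an independent check of the intensity-only
#' estimator (the instrument could never compute this; only the simulator
#' can).
#'
#' @param tm a `"tmatrix"`.
#' @return an `"rvitm"` object with `oracle = TRUE`.
#' @export
analytic_rvitm_oracle <- function(tm) {
  stopifnot(inherits(tm, "tmatrix"))
  er <- rowSums(tm$entries)   # A_R * exp(i phi_R) per pixel
  values <- 2 * tm$n_inputs * Re(tm$entries * Conj(er))
  structure(list(values = values, n_inputs = tm$n_inputs,
                 plane_z = tm$plane_z, output_shape = tm$output_shape,
                 pixel_pitch = tm$pixel_pitch, core_mask = tm$core_mask,
                 oracle = TRUE, call = match.call()),
            class = "rvitm")
}

#' @export
print.rvitm <- function(x, ...) {
  cat(if (isTRUE(x$oracle)) "Analytic RVITM (oracle)\n" else
      "RVITM fit from intensity-only Hadamard calibration\n")
  cat(sprintf("  %d x %d pixels x %d micromirrors, plane z = %.3g um\n",
              x$output_shape[1], x$output_shape[2], x$n_inputs, x$plane_z))
  cat(sprintf("  value range [%.3g, %.3g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
coef.rvitm <- function(object, ...) object$values

#' @export
summary.rvitm <- function(object, ...) {
  v <- object$values[as.vector(object$core_mask), , drop = FALSE]
  s <- list(n_inputs = object$n_inputs, output_shape = object$output_shape,
            plane_z = object$plane_z, n_core_pixels = sum(object$core_mask),
            value_sd = stats::sd(v), frac_positive = mean(v > 0),
            oracle = isTRUE(object$oracle))
  class(s) <- "summary.rvitm"
  s
}

#' @export
print.summary.rvitm <- function(x, ...) {
  cat(sprintf(
    "RVITM%s: N = %d mirrors, %d x %d pixels (%d in-core), plane z = %.3g um\n",
    if (x$oracle) " (oracle)" else "", x$n_inputs,
    x$output_shape[1], x$output_shape[2], x$n_core_pixels, x$plane_z))
  cat(sprintf("  in-core value sd %.4g; fraction positive %.3f\n",
              x$value_sd, x$frac_positive))
  invisible(x)
}

#' Predicted intensities under the linear RVITM model
#'
#' The RVITM models output intensity linearly in the binary pattern
#' (`I ~ RVITM . pattern` up to the 2N estimation scale); the prediction is
#' the interference (cross-term) component of intensity that the model
#' captures, in the same arbitrary units as the calibration intensities.
#'
#' @param object an `"rvitm"`.
#' @param patterns binary pattern(s): a vector of length N, an N x K matrix of
#'   pattern columns, a `"hadamard_patterns"` set (its display sequence), or a
#'   `"focus_pattern"`.
#' @param ... unused.
#' @return pixels x K matrix of model intensities.
#' @export
predict.rvitm <- function(object, patterns, ...) {
  P <- if (inherits(patterns, "hadamard_patterns")) patterns$display
       else if (inherits(patterns, "focus_pattern")) matrix(patterns$mask, ncol = 1)
       else as.matrix(patterns)
  if (nrow(P) != object$n_inputs)
    stop("pattern length does not match the fitted mirror count")
  (object$values %*% P) / (2 * object$n_inputs)
}

#' Calibration residuals of the RVITM fit
#'
#' Measured minus model intensities over the calibration display sequence.
#'
#' @param object an `"rvitm"` fitted with `keep_data = TRUE`, or supply
#'   `measurements`.
#' @param measurements optional `"speckle_measurements"` to evaluate against.
#' @param patterns the calibration `"hadamard_patterns"`; defaults to
#'   rebuilding the Sylvester set of the fitted order.
#' @param ... unused.
#' @return pixels x 2N matrix of residual intensities.
#' @export
residuals.rvitm <- function(object, measurements = NULL, patterns = NULL, ...) {
  if (is.null(measurements)) measurements <- object$measurements
  if (is.null(measurements))
    stop("no stored calibration data; refit with keep_data = TRUE or supply measurements")
  if (is.null(patterns)) patterns <- build_hadamard_pattern_set(object$n_inputs)
  measurements$I - predict(object, patterns)
}

#' Plot an RVITM pixel row on the micromirror grid
#'
#' Displays the fitted transmission constants of one output pixel as an image
#' over the square DMD sub-region (row-major mirror order), or a histogram of
#' all in-core values when no pixel is given.
#'
#' @param x an `"rvitm"`.
#' @param target_pixel linear index or (row, col); NULL for the histogram.
#' @param ... passed to [graphics::image()] / [graphics::hist()].
#' @export
plot.rvitm <- function(x, target_pixel = NULL, ...) {
  if (is.null(target_pixel)) {
    graphics::hist(x$values[as.vector(x$core_mask), ],
                   main = "RVITM values (in-core pixels)", xlab = "rvitm",
                   ...)
  } else {
    px <- resolve_pixel(target_pixel, x$output_shape)
    s <- as.integer(round(sqrt(x$n_inputs)))
    m <- matrix(x$values[px$index, ], s, s, byrow = TRUE)
    graphics::image(t(m)[, s:1], main = sprintf("RVITM row, pixel %d", px$index),
                    ...)
  }
  invisible(x)
}

#' Select the optimal binary focusing pattern for a target pixel
#'
#' Ranks the micromirrors by their RVITM value at the target pixel and
#' switches ON the top fraction (default 30 %, `ceiling(on_fraction * N)`
#' mirrors); ties are broken towards the lowest mirror index. Because
#' selection is rank-based, any positive rescaling of the measured
#' intensities leaves the pattern unchanged.
#'
#' @param rvitm_fit an `"rvitm"`.
#' @param target_pixel linear index or (row, col) of the desired focus.
#' @param on_fraction fraction of mirrors to switch ON, in (0, 1].
#' @return a `"focus_pattern"`: list with `mask` (binary length-N vector,
#'   row-major mirror order), `target_pixel` (linear index), `on_fraction`,
#'   `n_on`.
#' @export
select_focus_pattern <- function(rvitm_fit, target_pixel, on_fraction = 0.30) {
  stopifnot(inherits(rvitm_fit, "rvitm"))
  if (!is.numeric(on_fraction) || on_fraction <= 0 || on_fraction > 1)
    stop("on_fraction must lie in (0, 1]")
  px <- resolve_pixel(target_pixel, rvitm_fit$output_shape)
  row <- rvitm_fit$values[px$index, ]
  n <- rvitm_fit$n_inputs
  k <- ceiling(on_fraction * n)
  ord <- order(-row, seq_len(n))   # descending value, ties by lowest index
  mask <- numeric(n)
  mask[ord[seq_len(k)]] <- 1
  structure(list(mask = mask, target_pixel = px$index,
                 on_fraction = on_fraction, n_on = k),
            class = "focus_pattern")
}

#' @export
print.focus_pattern <- function(x, ...) {
  cat(sprintf("Focus pattern: %d / %d mirrors ON (fraction %.2f), target pixel %d\n",
              x$n_on, length(x$mask), x$on_fraction, x$target_pixel))
  invisible(x)
}

#' Characterise a stack of focal planes
#'
#' Runs the full calibration (acquire + fit) for every plane of a
#' transmission-matrix stack; per-plane noise seeds are derived from the
#' master seed.
#'
#' @param tm_stack list of `"tmatrix"` from [generate_tm_stack()].
#' @param patterns shared `"hadamard_patterns"`.
#' @inheritParams acquire_calibration
#' @return list of `"rvitm"` fits in plane order.
#' @export
characterise_all_planes <- function(tm_stack, patterns, read_noise_sd = 0,
                                    shot_scale = 0, seed = 1) {
  if (inherits(tm_stack, "tmatrix")) tm_stack <- list(tm_stack)
  lapply(seq_along(tm_stack), function(i) {
    meas <- acquire_calibration(tm_stack[[i]], patterns, read_noise_sd,
                                shot_scale, seed = derive_seed(seed, i))
    rvitm(meas, patterns)
  })
}
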