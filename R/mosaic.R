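## Mosaicing: subpixel registration of consecutive frames by single-step
## upsampled-DFT cross-correlation, and running-average stitching onto a
## pre-allocated canvas. Placement offsets are quantised to 1/upsample pixel
## and realised by bilinear resampling of the subpixel residual.

frame_matrix <- function(frame) {
  if (inherits(frame, "pa_image"))
    list(m = frame$pixels, pitch = frame$pitch, mask = frame$mask * 1)
  else {
    m <- as.matrix(frame)
    list(m = m, pitch = 1, mask = array(1, dim(m)))
  }
}

## Signed DFT frequency indices 0, 1, ..., -1 for length n.
signed_freqs <- function(n) {
  f <- 0:(n - 1)
  f[f > n / 2] <- f[f > n / 2] - n
  f
}

## Evaluate the cross-correlation surface (inverse DFT of C) at arbitrary
## fractional lags r0 + (0:(np-1))/usf, c0 + ... via explicit DFT kernels.
dft_upsampled <- function(C, rows, cols) {
  M <- nrow(C); N <- ncol(C)
  Wr <- exp(2i * pi * outer(rows, signed_freqs(M)) / M)
  Wc <- exp(2i * pi * outer(signed_freqs(N), cols) / N)
  Re(Wr %*% C %*% Wc) / (M * N)
}

#' Subpixel translation between two frames
#'
#' Finds the translation maximising the circular cross-correlation of the
#' two frames, computed coarsely by FFT and then refined beyond `1/upsample`
#' pixel by evaluating the upsampled inverse DFT on a small neighbourhood of
#' the coarse peak (single-step local evaluation; no full-image
#' interpolation) with parabolic interpolation of the fine peak. The
#' correlation surface is normalised by the overlap of the two frames' valid
#' masks, which removes the systematic pull towards zero shift that the
#' shrinking overlap of plain (periodic) cross-correlation induces — without
#' this, a constant-velocity frame sequence accumulates a visible drift.
#' The returned displacement is the shift of `frame_b` relative to
#' `frame_a`: `frame_b ~ frame_a` translated by `(dy, dx)`.
#'
#' @param frame_a,frame_b `"pa_image"` objects or numeric matrices of equal
#'   size.
#' @param upsample upsampling factor kappa >= 1 (default 10); precision is
#'   1/kappa pixel.
#' @param min_confidence normalised correlation-peak threshold below which
#'   the result is flagged low-confidence (default 0.2).
#' @return a `"displacement"`: list with `dy`, `dx` (pixels), `dy_um`,
#'   `dx_um`, `confidence` (normalised correlation peak in \[0, 1\]),
#'   `low_confidence`.
#' @export
register_translation <- function(frame_a, frame_b, upsample = 10,
                                 min_confidence = 0.2) {
  a <- frame_matrix(frame_a); b <- frame_matrix(frame_b)
  if (!identical(dim(a$m), dim(b$m))) stop("frames must have the same shape")
  if (upsample < 1 || upsample != round(upsample))
    stop("upsample must be a positive integer")
  if (all(a$m == 0) || all(b$m == 0)) stop("cannot register an all-zero frame")
  M <- nrow(a$m); N <- ncol(a$m)
  C <- stats::fft(b$m) * Conj(stats::fft(a$m))
  Cm <- stats::fft(b$mask * 1) * Conj(stats::fft(a$mask * 1))
  cc <- Re(stats::fft(C, inverse = TRUE)) / (M * N)
  ov <- Re(stats::fft(Cm, inverse = TRUE)) / (M * N)   # overlapping valid px
  ccn <- cc / pmax(ov, 1e-9)
  ccn[ov < 0.25 * max(ov)] <- -Inf    # ignore small-overlap (wrapped) lags
  pk <- which(ccn == max(ccn), arr.ind = TRUE)[1, ]
  dy <- unname(pk[1]) - 1L; dx <- unname(pk[2]) - 1L
  if (dy > M / 2) dy <- dy - M
  if (dx > N / 2) dx <- dx - N
  peak_val <- cc[pk[1], pk[2]]
  if (upsample > 1) {
    ## refine on a +/- 1.5 px neighbourhood at 1/kappa spacing
    np <- as.integer(ceiling(1.5 * upsample)) * 2L + 1L
    rows <- dy + (seq_len(np) - (np + 1) / 2) / upsample
    cols <- dx + (seq_len(np) - (np + 1) / 2) / upsample
    raw <- dft_upsampled(C, rows, cols)
    surf <- raw / pmax(dft_upsampled(Cm, rows, cols), 1e-9)
    pk2 <- which(surf == max(surf), arr.ind = TRUE)[1, ]
    dy <- rows[pk2[1]]; dx <- cols[pk2[2]]
    ## parabolic interpolation of the fine peak removes the 1/kappa
    ## quantisation of the refinement lattice
    i <- pk2[1]; j <- pk2[2]
    if (i > 1 && i < np) {
      den <- surf[i - 1, j] - 2 * surf[i, j] + surf[i + 1, j]
      if (den < 0) dy <- dy + 0.5 * (surf[i - 1, j] - surf[i + 1, j]) / den / upsample
    }
    if (j > 1 && j < np) {
      den <- surf[i, j - 1] - 2 * surf[i, j] + surf[i, j + 1]
      if (den < 0) dx <- dx + 0.5 * (surf[i, j - 1] - surf[i, j + 1]) / den / upsample
    }
    peak_val <- raw[pk2[1], pk2[2]]
  }
  conf <- peak_val / sqrt(sum(a$m^2) * sum(b$m^2))
  structure(list(dy = dy, dx = dx, dy_um = dy * a$pitch, dx_um = dx * a$pitch,
                 confidence = conf, low_confidence = conf < min_confidence,
                 upsample = upsample),
            class = "displacement")
}

#' @export
print.displacement <- function(x, ...) {
  cat(sprintf("Displacement (dy, dx) = (%.3f, %.3f) px = (%.3f, %.3f) um; confidence %.3f%s\n",
              x$dy, x$dx, x$dy_um, x$dx_um, x$confidence,
              if (x$low_confidence) " (LOW)" else ""))
  invisible(x)
}

#' Create an empty mosaic canvas
#'
#' Pre-allocated accumulator and per-pixel visit counts; the rendered pixel
#' is accumulator/count where visited. `origin` is the (row, col) at which
#' pixel (1, 1) of a frame with zero offset is placed.
#'
#' @param shape canvas (rows, cols) in frame pixels.
#' @param pitch pixel pitch, micrometres.
#' @param origin placement origin (row, col); default centres a zero-offset
#'   frame of unknown size at the canvas centre later (see [stitch()]).
#' @param upsample placement quantisation factor kappa (offsets rounded to
#'   1/kappa pixel; default 10).
#' @return a `"mosaic_canvas"`.
#' @export
mosaic_canvas <- function(shape, pitch = 1, origin = c(1, 1), upsample = 10) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2, all(shape >= 1))
  structure(list(acc = matrix(0, shape[1], shape[2]),
                 cnt = matrix(0, shape[1], shape[2]),
                 pitch = pitch, origin = origin, upsample = upsample),
            class = "mosaic_canvas")
}

#' @export
print.mosaic_canvas <- function(x, ...) {
  cat(sprintf("Mosaic canvas %d x %d px (%.3g um pitch), %.0f px visited\n",
              nrow(x$acc), ncol(x$acc), x$pitch, sum(x$cnt > 0)))
  invisible(x)
}

## Shift an image by a fractional (fy, fx) in [0, 1) via bilinear
## resampling with zero padding; output gains one row/col.
bilinear_shift <- function(m, fy, fx) {
  nr <- nrow(m); nc <- ncol(m)
  g <- matrix(0, nr + 1L, nc + 1L)
  g[1:nr, 1:nc] <- g[1:nr, 1:nc] + m * (1 - fy) * (1 - fx)
  g[2:(nr + 1), 1:nc] <- g[2:(nr + 1), 1:nc] + m * fy * (1 - fx)
  g[1:nr, 2:(nc + 1)] <- g[1:nr, 2:(nc + 1)] + m * (1 - fy) * fx
  g[2:(nr + 1), 2:(nc + 1)] <- g[2:(nr + 1), 2:(nc + 1)] + m * fy * fx
  g
}

#' Stitch a frame onto a mosaic canvas
#'
#' Adds the frame's (masked) values into the accumulator at the cumulative
#' offset, quantised to `1/upsample` pixel: the integer part indexes the
#' canvas and the subpixel residual is realised by bilinear resampling of
#' the frame. Visit counts are incremented by the resampled mask, so the
#' rendered canvas is a running average over overlapping frames.
#'
#' @param canvas a [mosaic_canvas()].
#' @param frame a `"pa_image"` or matrix.
#' @param offset cumulative displacement of this frame (a `"displacement"`,
#'   or numeric (dy, dx) in pixels).
#' @return the updated canvas.
#' @export
stitch <- function(canvas, frame, offset = c(0, 0)) {
  stopifnot(inherits(canvas, "mosaic_canvas"))
  f <- frame_matrix(frame)
  off <- if (inherits(offset, "displacement")) c(offset$dy, offset$dx)
         else as.numeric(offset)
  q <- round(off * canvas$upsample) / canvas$upsample
  i0 <- floor(q); fr <- q - i0
  vals <- bilinear_shift(f$m * f$mask, fr[1], fr[2])
  wts <- bilinear_shift(f$mask, fr[1], fr[2])
  r <- canvas$origin[1] + i0[1] + seq_len(nrow(vals)) - 1L
  c_ <- canvas$origin[2] + i0[2] + seq_len(ncol(vals)) - 1L
  if (min(r) < 1 || max(r) > nrow(canvas$acc) ||
      min(c_) < 1 || max(c_) > ncol(canvas$acc))
    stop(sprintf(paste0("frame falls outside the canvas; required growth: ",
                        "rows [%d, %d] vs [1, %d], cols [%d, %d] vs [1, %d]"),
                 min(r), max(r), nrow(canvas$acc),
                 min(c_), max(c_), ncol(canvas$acc)))
  canvas$acc[r, c_] <- canvas$acc[r, c_] + vals
  canvas$cnt[r, c_] <- canvas$cnt[r, c_] + wts
  canvas
}

#' Render a mosaic canvas
#'
#' @param canvas a `"mosaic_canvas"`.
#' @return matrix of running-average values (zero where never visited).
#' @export
render_mosaic <- function(canvas) {
  stopifnot(inherits(canvas, "mosaic_canvas"))
  out <- canvas$acc
  vis <- canvas$cnt > 0
  out[vis] <- out[vis] / canvas$cnt[vis]
  out[!vis] <- 0
  out
}

#' Bounding box of the visited mosaic region
#'
#' @param canvas a `"mosaic_canvas"`.
#' @return c(height_um, width_um) of the visited bounding box.
#' @export
mosaic_extent <- function(canvas) {
  vis <- which(canvas$cnt > 0, arr.ind = TRUE)
  if (nrow(vis) == 0) return(c(0, 0))
  c(diff(range(vis[, 1])) + 1, diff(range(vis[, 2])) + 1) * canvas$pitch
}

#' Register and stitch an ordered frame sequence
#'
#' The first frame is placed at the origin; each subsequent frame is
#' registered against its predecessor, the displacements are accumulated,
#' and every frame is stitched at its cumulative offset (running-average
#' overlap). A low-confidence registration aborts with the frame index.
#'
#' [register_translation()] reports the shift of the scene *content*
#' between frames; the probe moves opposite to the content, so the stitching
#' offset (and the reported trajectory, which is the probe path over the
#' sample) accumulates the negated registration result.
#'
#' @param frames ordered list of `"pa_image"` objects or matrices (equal
#'   shapes).
#' @param upsample registration/placement upsampling factor (default 10).
#' @param min_confidence abort threshold on the normalised correlation peak
#'   (default 0.2).
#' @param canvas_shape canvas (rows, cols) in pixels; default 4x the frame.
#' @param origin placement origin of the first frame; default centres it.
#' @return list with `canvas` (a `"mosaic_canvas"`), `image` (rendered
#'   matrix) and `trajectory` (data.frame frame_index, dy_px, dx_px,
#'   cum_y_px, cum_x_px, cum_y_um, cum_x_um, confidence).
#' @export
run_mosaic <- function(frames, upsample = 10, min_confidence = 0.2,
                       canvas_shape = NULL, origin = NULL) {
  stopifnot(length(frames) >= 1)
  f1 <- frame_matrix(frames[[1]])
  if (is.null(canvas_shape)) canvas_shape <- 4L * dim(f1$m)
  if (is.null(origin))
    origin <- floor((canvas_shape - dim(f1$m)) / 2) + 1L
  canvas <- mosaic_canvas(canvas_shape, pitch = f1$pitch, origin = origin,
                          upsample = upsample)
  cum <- c(0, 0)
  traj <- data.frame(frame_index = seq_along(frames), dy_px = 0, dx_px = 0,
                     cum_y_px = 0, cum_x_px = 0, cum_y_um = 0, cum_x_um = 0,
                     confidence = NA_real_)
  canvas <- stitch(canvas, frames[[1]], cum)
  for (k in seq_along(frames)[-1]) {
    d <- register_translation(frames[[k - 1]], frames[[k]],
                              upsample = upsample,
                              min_confidence = min_confidence)
    if (d$low_confidence)
      stop("low-confidence registration at frame ", k,
           " (confidence ", signif(d$confidence, 3), ")")
    cum <- cum - c(d$dy, d$dx)
    canvas <- stitch(canvas, frames[[k]], cum)
    traj[k, c("dy_px", "dx_px")] <- -c(d$dy, d$dx)
    traj[k, c("cum_y_px", "cum_x_px")] <- cum
    traj[k, c("cum_y_um", "cum_x_um")] <- cum * f1$pitch
    traj$confidence[k] <- d$confidence
  }
  list(canvas = canvas, image = render_mosaic(canvas), trajectory = traj)
}
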