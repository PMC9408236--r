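## Raster-scan grid over a circular field of view, and the DMD-rate
## acquisition timing model.

#' Build a raster-scan grid over a circular field of view
#'
#' Square lattice with pitch `step`, one lattice point pinned to the FOV
#' centre, retaining points whose centre lies within the closed disc of
#' diameter `fov_diameter`. Positions are in raster (row-major) order: y
#' increases row by row, x increases within a row.
#'
#' @param fov_diameter field-of-view diameter, micrometres (default 100).
#' @param step scan step, micrometres.
#' @param center FOV centre (x, y), micrometres.
#' @param plane_zs focal-plane offsets for volumetric scans, micrometres;
#'   strictly increasing.
#' @return an object of class `"scan_grid"`: list with `positions`
#'   (data.frame x, y, ix, iy, order_index), `fov_diameter`, `step`,
#'   `center`, `plane_zs`, `nx`, `ny`, `xs`, `ys` (lattice axes) and `mask`
#'   (ny x nx logical, TRUE where a scan position exists).
#' @examples
#' nrow(make_scan_grid(100, 1)$positions)   # ~ pi * 50^2
#' @export
make_scan_grid <- function(fov_diameter = 100, step, center = c(0, 0),
                           plane_zs = 0) {
  if (step <= 0) stop("step must be positive")
  if (fov_diameter <= 0) stop("fov_diameter must be positive")
  if (length(plane_zs) > 1 && any(diff(plane_zs) <= 0))
    stop("plane_zs must be strictly increasing")
  r <- fov_diameter / 2
  k <- seq(-floor(r / step), floor(r / step))
  xs <- center[1] + k * step
  ys <- center[2] + k * step
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)  # x fastest: raster order
  keep <- (g$x - center[1])^2 + (g$y - center[2])^2 <= r^2 + 1e-9
  pos <- g[keep, , drop = FALSE]
  pos$ix <- match(pos$x, xs)
  pos$iy <- match(pos$y, ys)
  pos$order_index <- seq_len(nrow(pos))
  rownames(pos) <- NULL
  mask <- matrix(FALSE, length(ys), length(xs))
  mask[cbind(pos$iy, pos$ix)] <- TRUE
  structure(list(positions = pos, fov_diameter = fov_diameter, step = step,
                 center = center, plane_zs = plane_zs,
                 nx = length(xs), ny = length(ys), xs = xs, ys = ys,
                 mask = mask), class = "scan_grid")
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf("Raster scan grid: %d positions, FOV %.3g um, step %.3g um, %d plane(s)\n",
              nrow(x$positions), x$fov_diameter, x$step, length(x$plane_zs)))
  invisible(x)
}

#' Export a scan grid as CSV
#'
#' One row per (position, plane): x_um, y_um, plane_z_um, order_index.
#' @param grid a `"scan_grid"`.
#' @param path output CSV path.
#' @export
write_scan_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "scan_grid"))
  rows <- do.call(rbind, lapply(grid$plane_zs, function(z) {
    data.frame(x_um = grid$positions$x, y_um = grid$positions$y,
               plane_z_um = z, order_index = grid$positions$order_index)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Acquisition timing from the DMD display rate
#'
#' One optimal pattern is displayed per scan position, so a frame takes
#' `n_positions / dmd_rate_hz` seconds, a volume `n_planes` times that, and
#' the frame rate is `dmd_rate_hz / n_positions`.
#'
#' @param n_positions scan positions per frame.
#' @param n_planes number of focal planes (default 1).
#' @param dmd_rate_hz DMD pattern display rate, Hz (default 22700).
#' @return an `"acquisition_timing"` list: `frame_time_s`, `frame_rate_fps`,
#'   `volume_time_s`.
#' @examples
#' acquisition_timing(7850, 21)   # ~ 0.35 s frame, ~ 7.3 s volume
#' @export
acquisition_timing <- function(n_positions, n_planes = 1, dmd_rate_hz = 22700) {
  if (dmd_rate_hz <= 0) stop("dmd_rate_hz must be positive")
  if (n_positions < 0 || n_planes < 0) stop("counts must be non-negative")
  frame_time <- n_positions / dmd_rate_hz
  structure(list(frame_time_s = frame_time,
                 frame_rate_fps = dmd_rate_hz / n_positions,
                 volume_time_s = n_planes * frame_time),
            class = "acquisition_timing")
}

#' @export
print.acquisition_timing <- function(x, ...) {
  cat(sprintf("Frame %.3g s (%.3g fps); volume %.3g s\n",
              x$frame_time_s, x$frame_rate_fps, x$volume_time_s))
  invisible(x)
}
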