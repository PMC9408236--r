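## Digital absorption phantoms on voxel grids: USAF-style bar targets,
## carbon-fibre cylinders, and biconcave red-blood-cell discs.
##
## Conventions: x runs across columns, y down rows, z away from the fibre
## tip; the absorption array is indexed [y, x, z]; `pitch` is the lateral
## voxel pitch and `pitch_z` the axial pitch, both in micrometres; lateral
## coordinates are centred on (0, 0), z coordinates are absolute offsets
## from the tip.

new_absorber_map <- function(a, pitch, pitch_z, z0, kind) {
  structure(list(absorption = a, pitch = pitch, pitch_z = pitch_z,
                 z0 = z0, kind = kind), class = "absorber_map")
}

#' @export
print.absorber_map <- function(x, ...) {
  d <- dim(x$absorption)
  cat(sprintf(
    "Absorber map (%s): %d x %d x %d voxels, %.3g um lateral / %.3g um axial pitch, z0 = %.3g um\n",
    x$kind, d[1], d[2], d[3], x$pitch, x$pitch_z, x$z0))
  invisible(x)
}

## Voxel-centre axes of an absorber map.
phantom_axes <- function(ph) {
  d <- dim(ph$absorption)
  c(grid_axes(d[1:2], ph$pitch),
    list(z = ph$z0 + (seq_len(d[3]) - 1) * ph$pitch_z))
}

#' Bar resolution target phantom
#'
#' Parallel absorbing bars (binary absorption) in a single thin plane,
#' emulating one group of a resolution test target. Bars run along x; the
#' bar/gap structure repeats along y, centred on the grid.
#'
#' @param bar_width bar width, micrometres.
#' @param gap gap between bars, micrometres (default `bar_width`).
#' @param n_bars number of bars.
#' @param extent lateral extent (x, y) of the grid, micrometres.
#' @param pitch lateral voxel pitch, micrometres.
#' @param z depth of the target plane below the fibre tip, micrometres.
#' @return an `"absorber_map"` with one z slice.
#' @export
make_bar_target <- function(bar_width, gap = bar_width, n_bars = 1,
                            extent = c(50, 50), pitch = 0.5, z = 0) {
  if (bar_width <= 0 || gap < 0 || n_bars < 1) stop("invalid bar geometry")
  extent <- rep(extent, length.out = 2)
  total <- n_bars * bar_width + (n_bars - 1) * gap
  if (total > extent[2]) stop("bars exceed the grid extent (need ", total,
                              " um, have ", extent[2], " um)")
  ny <- round(extent[2] / pitch); nx <- round(extent[1] / pitch)
  ax <- grid_axes(c(ny, nx), pitch)
  a <- array(0, dim = c(ny, nx, 1))
  starts <- -total / 2 + (seq_len(n_bars) - 1) * (bar_width + gap)
  for (s in starts) {
    rows <- ax$y >= s - 1e-9 & ax$y < s + bar_width - 1e-9
    a[rows, , 1] <- 1
  }
  new_absorber_map(a, pitch, pitch, z, "bar_target")
}

#' Carbon-fibre phantom (absorbing cylinders)
#'
#' Cylinders of the given radius at 3D poses: each fibre's axis lies in a
#' horizontal plane at depth `z`, passes through lateral point (x, y) and
#' makes angle `angle` (radians) with the x axis. Poses are random
#' (deterministic given `seed`) unless supplied.
#'
#' @param n_fibres number of fibres.
#' @param radius fibre radius, micrometres (default 3.5).
#' @param extent lateral extent (x, y), micrometres.
#' @param pitch lateral voxel pitch, micrometres.
#' @param depth axial extent of the volume, micrometres.
#' @param pitch_z axial voxel pitch, micrometres.
#' @param z0 depth of the first voxel plane, micrometres.
#' @param poses optional data.frame(x, y, z, angle) overriding the random
#'   poses; z is absolute depth.
#' @param seed pose seed.
#' @return an `"absorber_map"` (binary absorption).
#' @export
make_carbon_fibre_phantom <- function(n_fibres = 2, radius = 3.5,
                                      extent = c(100, 100), pitch = 1,
                                      depth = 300, pitch_z = 2, z0 = 0,
                                      poses = NULL, seed = 1) {
  extent <- rep(extent, length.out = 2)
  if (is.null(poses)) {
    poses <- with_seed(seed, data.frame(
      x = stats::runif(n_fibres, -extent[1] / 4, extent[1] / 4),
      y = stats::runif(n_fibres, -extent[2] / 4, extent[2] / 4),
      z = z0 + depth * (seq_len(n_fibres) - 0.5) / n_fibres +
        stats::runif(n_fibres, -depth / (4 * n_fibres), depth / (4 * n_fibres)),
      angle = stats::runif(n_fibres, 0, pi)))
  }
  if (any(poses$z < z0 - radius) || any(poses$z > z0 + depth + radius))
    stop("fibre pose outside the volume depth range")
  ny <- round(extent[2] / pitch); nx <- round(extent[1] / pitch)
  nz <- round(depth / pitch_z)
  ax <- grid_axes(c(ny, nx), pitch)
  zs <- z0 + (seq_len(nz) - 1) * pitch_z
  a <- array(0, dim = c(ny, nx, nz))
  X <- matrix(ax$x, ny, nx, byrow = TRUE)
  Y <- matrix(ax$y, ny, nx)
  for (i in seq_len(nrow(poses))) {
    dx <- cos(poses$angle[i]); dy <- sin(poses$angle[i])
    vx <- X - poses$x[i]; vy <- Y - poses$y[i]
    ## lateral distance^2 to the axis line, decomposed along/perp in-plane
    t_par <- vx * dx + vy * dy
    lat2 <- vx^2 + vy^2 - t_par^2
    for (k in seq_len(nz)) {
      d2 <- lat2 + (zs[k] - poses$z[i])^2
      a[, , k] <- pmax(a[, , k], as.numeric(d2 <= radius^2))
    }
  }
  ph <- new_absorber_map(a, pitch, pitch_z, z0, "carbon_fibre")
  ph$poses <- poses
  ph
}

## Rotationally symmetric biconcave thickness profile (Evans-Fung style,
## micrometres), scaled to the requested diameter; centre thinner than rim.
rbc_thickness <- function(r, diameter) {
  scale <- diameter / 7.82
  rho <- r / (diameter / 2)
  t <- ifelse(rho >= 1, 0,
              sqrt(pmax(1 - rho^2, 0)) *
                (0.81 + 7.83 * rho^2 - 4.39 * rho^4) * scale)
  pmax(t, 0)
}

#' Red-blood-cell smear phantom
#'
#' Biconcave discs with a rotationally symmetric thickness profile (central
#' dimple: thinner at the centre than at the rim), placed at random
#' non-overlapping lateral positions by rejection sampling. Absorption in the
#' single z slice is the local cell thickness (micrometres), a thin-sample
#' projection of the cell.
#'
#' @param n_cells number of cells (0 gives an empty map).
#' @param cell_diameter cell diameter, micrometres (default 7.5).
#' @param extent lateral extent (x, y), micrometres.
#' @param pitch lateral voxel pitch, micrometres.
#' @param z depth of the smear plane, micrometres.
#' @param seed placement seed.
#' @param max_tries placement attempts before giving up.
#' @return an `"absorber_map"` with one z slice and a `centers` data.frame.
#' @export
make_rbc_phantom <- function(n_cells, cell_diameter = 7.5, extent = c(100, 100),
                             pitch = 0.5, z = 0, seed = 1, max_tries = 5000) {
  extent <- rep(extent, length.out = 2)
  R <- cell_diameter / 2
  if (n_cells > 0 && (extent[1] <= cell_diameter || extent[2] <= cell_diameter))
    stop("grid too small for the requested cells")
  centers <- with_seed(seed, {
    cx <- numeric(0); cy <- numeric(0); tries <- 0
    while (length(cx) < n_cells) {
      if (tries >= max_tries)
        stop("could not place ", n_cells, " non-overlapping cells after ",
             max_tries, " attempts")
      x <- stats::runif(1, -extent[1] / 2 + R, extent[1] / 2 - R)
      y <- stats::runif(1, -extent[2] / 2 + R, extent[2] / 2 - R)
      tries <- tries + 1
      if (all((x - cx)^2 + (y - cy)^2 >= cell_diameter^2)) {
        cx <- c(cx, x); cy <- c(cy, y)
      }
    }
    data.frame(x = cx, y = cy)
  })
  ny <- round(extent[2] / pitch); nx <- round(extent[1] / pitch)
  ax <- grid_axes(c(ny, nx), pitch)
  a <- array(0, dim = c(ny, nx, 1))
  X <- matrix(ax$x, ny, nx, byrow = TRUE)
  Y <- matrix(ax$y, ny, nx)
  for (i in seq_len(nrow(centers))) {
    r <- sqrt((X - centers$x[i])^2 + (Y - centers$y[i])^2)
    a[, , 1] <- a[, , 1] + rbc_thickness(r, cell_diameter)
  }
  ph <- new_absorber_map(a, pitch, pitch, z, "rbc")
  ph$centers <- centers
  ph
}
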