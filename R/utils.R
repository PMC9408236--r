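#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules: seed management, analytic-signal
## envelope, 1D Gaussian fitting, pixel-index handling.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so stochastic operations are reproducible without
#' side-effects on the session.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic per-stage / per-plane seed derivation from a master seed.
## Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + 104729 * as.double(index)
  as.integer(s %% 2147483629) + 1L
}

is_power_of_two <- function(n) {
  n == as.integer(n) && n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}

## Magnitude of the analytic signal (Hilbert envelope) of a real vector.
analytic_envelope <- function(x) {
  n <- length(x)
  if (n == 1L) return(abs(x))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

## Least-squares Gaussian fit y ~ a * exp(-(x - mu)^2 / (2 sigma^2)) + b,
## initialised from moments. Returns list(a, mu, sigma, b, fwhm).
fit_gaussian <- function(x, y, baseline = TRUE) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  b0 <- if (baseline) min(y) else 0
  w <- pmax(y - b0, 0)
  if (sum(w) <= 0) stop("Gaussian fit failed: profile has no mass above baseline")
  mu0 <- sum(x * w) / sum(w)
  s0 <- sqrt(sum((x - mu0)^2 * w) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(x)) / 6
  a0 <- max(y) - b0
  df <- data.frame(x = x, y = y)
  fit <- if (baseline) {
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * s^2)) + b,
      data = df, start = list(a = a0, mu = mu0, s = s0, b = b0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * s^2)),
      data = df, start = list(a = a0, mu = mu0, s = s0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  p <- as.list(stats::coef(fit))
  if (!baseline) p$b <- 0
  s <- abs(p$s)
  list(a = p$a, mu = p$mu, sigma = s, b = p$b, fwhm = 2 * sqrt(2 * log(2)) * s)
}

## Resolve a pixel reference given as either a linear (column-major) index or
## a (row, col) pair; returns list(index, row, col).
resolve_pixel <- function(pixel, shape) {
  nr <- shape[1]; nc <- shape[2]
  if (length(pixel) == 1L) {
    idx <- as.integer(pixel)
    if (idx < 1L || idx > nr * nc) stop("pixel index out of range")
    row <- ((idx - 1L) %% nr) + 1L
    col <- ((idx - 1L) %/% nr) + 1L
  } else if (length(pixel) == 2L) {
    row <- as.integer(pixel[1]); col <- as.integer(pixel[2])
    if (row < 1L || row > nr || col < 1L || col > nc)
      stop("pixel (row, col) out of range")
    idx <- (col - 1L) * nr + row
  } else stop("pixel must be a linear index or a (row, col) pair")
  list(index = idx, row = row, col = col)
}

## Pixel-centre coordinate axes (micrometres) for a grid centred on (0, 0).
grid_axes <- function(shape, pitch) {
  nr <- shape[1]; nc <- shape[2]
  list(
    y = (seq_len(nr) - (nr + 1) / 2) * pitch,
    x = (seq_len(nc) - (nc + 1) / 2) * pitch
  )
}

## Logical in-core mask (disc of diameter `core_diameter`) for a pixel grid.
core_mask_matrix <- function(shape, pitch, core_diameter) {
  ax <- grid_axes(shape, pitch)
  outer(ax$y^2, ax$x^2, `+`) <= (core_diameter / 2)^2
}
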