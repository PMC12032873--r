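# Internal helpers shared across modules: error conditions, raster/physical
# coordinate conventions, phase wrapping, bilinear sampling.

stop_densesim <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "densesim_error")))
}
err_geometry  <- function(msg) stop_densesim(msg, "densesim_geometry_error")
err_input     <- function(msg) stop_densesim(msg, "densesim_input_error")
err_config    <- function(msg) stop_densesim(msg, "densesim_config_error")
err_domain    <- function(msg) stop_densesim(msg, "densesim_domain_error")
err_parameter <- function(msg) stop_densesim(msg, "densesim_parameter_error")

#' Physical coordinates of pixel centers along one raster axis
#'
#' Pixel centers sit at (i + 0.5) * pixel_size for 0-based index i, and the
#' raster center is mapped to physical coordinate 0 (plus `origin`). The same
#' convention is used by every module so that anatomy, motion and k-space
#' positions agree to sub-pixel precision.
#'
#' @param n raster size (pixels)
#' @param pixel_size pixel edge length (mm)
#' @param origin physical coordinate of the raster center (mm)
#' @return numeric vector of length `n` (mm)
#' @keywords internal
pixel_centers <- function(n, pixel_size, origin = 0) {
  (seq_len(n) - 0.5 - n / 2) * pixel_size + origin
}

# Wrap values into (-pi, pi] (phase) or the analogous displacement interval.
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Wrap a value into (-P/2, P/2] for wrap period P.
wrap_period <- function(x, period) {
  y <- (x + period / 2) %% period - period / 2
  y[y == -period / 2] <- period / 2
  y
}

# Bilinear interpolation of a matrix field sampled at pixel centers.
# `z` is an n x n matrix with rows indexing y and columns indexing x;
# (xq, yq) are physical query coordinates (mm). Values outside the grid are
# clamped to the border. NA cells propagate to queries touching them.
bilinear_sample <- function(z, pixel_size, xq, yq, origin = c(0, 0)) {
  n_row <- nrow(z); n_col <- ncol(z)
  # continuous (1-based) fractional indices of query points
  fi <- (yq - origin[2]) / pixel_size + 0.5 + n_row / 2
  fj <- (xq - origin[1]) / pixel_size + 0.5 + n_col / 2
  fi <- pmin(pmax(fi, 1), n_row)
  fj <- pmin(pmax(fj, 1), n_col)
  i0 <- pmin(floor(fi), n_row - 1); j0 <- pmin(floor(fj), n_col - 1)
  di <- fi - i0; dj <- fj - j0
  idx <- function(i, j) z[cbind(i, j)]
  idx(i0, j0) * (1 - di) * (1 - dj) +
    idx(i0 + 1, j0) * di * (1 - dj) +
    idx(i0, j0 + 1) * (1 - di) * dj +
    idx(i0 + 1, j0 + 1) * di * dj
}

# Column-major linear indices of TRUE entries of a mask matrix.
mask_indices <- function(mask) which(mask)

# Package-level cache for expensive trajectory/DFT operators that depend only
# on acquisition geometry, reused across cases of a cohort.
.densesim_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .densesim_cache, inherits = FALSE)) {
    assign(key, build(), envir = .densesim_cache)
  }
  get(key, envir = .densesim_cache, inherits = FALSE)
}
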