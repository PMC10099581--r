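#' Generate a smooth synthetic resource layer
#'
#' Draws Gaussian white noise on the grid, low-pass filters it with a
#' (periodic) Gaussian kernel of standard deviation `smoothness` cells via
#' the FFT, and rescales the result to `[0, 1]`. Larger `smoothness` gives a
#' smoother, lower-variance field; the output is deterministic for a given
#' seed and parameter set. Used throughout for synthetic resource
#' landscapes standing in for habitat-quality maps.
#'
#' @param n_rows,n_cols grid dimensions (at least 2 each).
#' @param smoothness positive filter standard deviation in cell units.
#' @param seed integer RNG seed; the caller's RNG state is untouched.
#' @param cell_size,origin grid geometry, as in [raster_layer()].
#' @param name layer label.
#' @return A [raster_layer()] with values in `[0, 1]`.
#' @examples
#' r <- generate_resource_layer(50, 50, smoothness = 8, seed = 1)
#' range(r$values)
#' @export
generate_resource_layer <- function(n_rows, n_cols, smoothness = 10, seed = 1,
                                    cell_size = 1, origin = c(0, 0),
                                    name = "resource") {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 2L || n_cols < 2L)
    stopf("'n_rows' and 'n_cols' must be integers >= 2")
  if (!is_scalar_num(smoothness) || smoothness <= 0)
    stopf("'smoothness' must be a positive number")
  noise <- with_seed(seed, matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols))
  sm <- gaussian_blur(noise, smoothness)
  rng <- range(sm)
  vals <- if (rng[2] > rng[1]) (sm - rng[1]) / (rng[2] - rng[1])
          else matrix(0, n_rows, n_cols)
  raster_layer(vals, cell_size = cell_size, origin = origin, name = name)
}

# Periodic Gaussian low-pass filter via FFT.
gaussian_blur <- function(m, sd) {
  nr <- nrow(m); nc <- ncol(m)
  di <- pmin(0:(nr - 1), nr - 0:(nr - 1))  # wrapped distances
  dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  g <- exp(-outer(di^2, dj^2, "+") / (2 * sd^2))
  g <- g / sum(g)
  Re(stats::fft(stats::fft(m) * stats::fft(g), inverse = TRUE)) / (nr * nc)
}
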