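#' Regular-grid raster layer
#'
#' A minimal raster container for covariate layers, occurrence distributions
#' and utilisation distributions. Values are stored as an `n_rows x n_cols`
#' matrix whose first row is the *bottom* row of the grid, so that row index
#' increases with the y coordinate. Coordinates are continuous, in cell-size
#' units, with the origin at the lower-left corner of the grid: cell
#' `(i, j)` covers the half-open square
#' `[x0 + (j-1)*cs, x0 + j*cs) x [y0 + (i-1)*cs, y0 + i*cs)`.
#'
#' @param values numeric matrix of cell values (row 1 = bottom row); all
#'   entries must be finite.
#' @param cell_size positive length of a cell edge.
#' @param origin numeric length-2 vector `(x0, y0)`, the lower-left corner.
#' @param name label for the layer.
#' @return An object of class `raster_layer`.
#' @examples
#' r <- raster_layer(matrix(runif(12), 3, 4))
#' dim(r$values)
#' @export
raster_layer <- function(values, cell_size = 1, origin = c(0, 0),
                         name = "layer") {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) < 1L || ncol(values) < 1L)
    stopf("'values' must be a numeric matrix with at least one cell")
  if (any(!is.finite(values)))
    stopf("raster values must all be finite (no NA/NaN/Inf)")
  if (!is_scalar_num(cell_size) || cell_size <= 0)
    stopf("'cell_size' must be a positive number")
  if (length(origin) != 2L || any(!is.finite(origin)))
    stopf("'origin' must be a finite (x0, y0) pair")
  structure(
    list(values = unname(values), cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), name = as.character(name)[1L]),
    class = "raster_layer"
  )
}

#' @export
print.raster_layer <- function(x, ...) {
  cat(sprintf("<raster_layer '%s': %d x %d cells, cell_size %g, origin (%g, %g)>\n",
              x$name, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  cat(sprintf("  value range: [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.raster_layer <- function(x, ...) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  xs <- x$origin[1] + (seq_len(nc) - 0.5) * x$cell_size
  ys <- x$origin[2] + (seq_len(nr) - 0.5) * x$cell_size
  graphics::image(xs, ys, t(x$values), xlab = "x", ylab = "y",
                  main = x$name, useRaster = TRUE, ...)
  invisible(x)
}

#' Study area: grid geometry plus admissible cells
#'
#' Describes the bounded study area over which kernels are normalised
#' ("no go" boundary: no probability mass may leave it). By default every
#' grid cell is admissible.
#'
#' @param n_rows,n_cols grid dimensions (at least 1 each).
#' @param cell_size positive cell edge length.
#' @param origin lower-left corner `(x0, y0)`.
#' @param admissible logical vector over cells in column-major order (row
#'   index fastest), or `NULL` for all cells admissible.
#' @return An object of class `study_area`.
#' @export
study_area <- function(n_rows, n_cols, cell_size = 1, origin = c(0, 0),
                       admissible = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stopf("'n_rows' and 'n_cols' must be positive integers")
  if (!is_scalar_num(cell_size) || cell_size <= 0)
    stopf("'cell_size' must be a positive number")
  n_cell <- n_rows * n_cols
  if (is.null(admissible)) admissible <- rep(TRUE, n_cell)
  admissible <- as.logical(admissible)
  if (length(admissible) != n_cell || anyNA(admissible))
    stopf("'admissible' must be a logical vector with one entry per cell (%d)", n_cell)
  if (!any(admissible)) stopf("study area must contain at least one admissible cell")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), admissible = admissible),
    class = "study_area"
  )
}

#' @export
print.study_area <- function(x, ...) {
  cat(sprintf("<study_area: %d x %d cells (%d admissible), cell_size %g>\n",
              x$n_rows, x$n_cols, sum(x$admissible), x$cell_size))
  invisible(x)
}

#' Study area matching a raster layer's geometry
#'
#' @param layer a [raster_layer()].
#' @return A [study_area()] with the same grid, all cells admissible.
#' @export
as_study_area <- function(layer) {
  stopifnot(inherits(layer, "raster_layer"))
  study_area(nrow(layer$values), ncol(layer$values), layer$cell_size,
             layer$origin)
}

n_cells <- function(area) area$n_rows * area$n_cols

# Cell centres, an (n_rows*n_cols) x 2 matrix in column-major cell order.
cell_centres <- function(area) {
  i <- rep(seq_len(area$n_rows), times = area$n_cols)
  j <- rep(seq_len(area$n_cols), each = area$n_rows)
  cbind(x = area$origin[1] + (j - 0.5) * area$cell_size,
        y = area$origin[2] + (i - 0.5) * area$cell_size)
}

# Index (column-major) of the cell containing continuous point (x, y).
# Points on the top/right boundary belong to the last cell.
cell_of <- function(area, p) {
  j <- floor((p[1] - area$origin[1]) / area$cell_size) + 1
  i <- floor((p[2] - area$origin[2]) / area$cell_size) + 1
  j <- min(max(j, 1), area$n_cols)
  i <- min(max(i, 1), area$n_rows)
  as.integer((j - 1) * area$n_rows + i)
}

point_in_area <- function(area, p) {
  p[1] >= area$origin[1] && p[1] <= area$origin[1] + area$n_cols * area$cell_size &&
  p[2] >= area$origin[2] && p[2] <= area$origin[2] + area$n_rows * area$cell_size
}

# Cell values of a raster as a column-major vector aligned with a study area.
layer_values <- function(layer, area) {
  if (inherits(layer, "ud")) {
    check_same_grid(layer$area, area)
    return(layer$p)
  }
  stopifnot(inherits(layer, "raster_layer"))
  if (nrow(layer$values) != area$n_rows || ncol(layer$values) != area$n_cols)
    stopf("raster '%s' (%d x %d) does not match the study-area grid (%d x %d)",
          layer$name, nrow(layer$values), ncol(layer$values),
          area$n_rows, area$n_cols)
  as.vector(layer$values)
}

same_grid <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

check_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stopf("grids do not match (%d x %d vs %d x %d)",
                              a$n_rows, a$n_cols, b$n_rows, b$n_cols)
  invisible(TRUE)
}

# Vector (column-major cell order) -> raster_layer on the area's grid.
vector_as_raster <- function(v, area, name = "layer") {
  raster_layer(matrix(v, nrow = area$n_rows, ncol = area$n_cols),
               cell_size = area$cell_size, origin = area$origin, name = name)
}
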