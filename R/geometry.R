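#' Define a raster grid geometry
#'
#' All rasters in a landscape share one planar grid: `n_rows` x `n_cols`
#' square cells of side `cell_size` kilometres. Cell `(i, j)` has its center
#' at `(origin_x + (j - 0.5) * cell_size, origin_y + (i - 0.5) * cell_size)`,
#' i.e. row indices increase with the y coordinate. Coordinates are abstract
#' planar kilometres; no geodetic projection is attached.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param cell_size Cell side length in km (> 0).
#' @param origin_x,origin_y Planar coordinates (km) of the grid's lower-left
#'   corner.
#' @param nodata Sentinel written to disk for missing pixels; in memory
#'   missing pixels are `NA`.
#' @return An object of class `grid_geometry`.
#' @examples
#' geom <- grid_geometry(10, 10)
#' cell_area(geom)
#' @export
grid_geometry <- function(n_rows, n_cols, cell_size = 1, origin_x = 0,
                          origin_y = 0, nodata = -9999) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("n_rows and n_cols must be >= 1")
  if (!is.finite(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
         origin_x = origin_x, origin_y = origin_y, nodata = nodata),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d cells of %g km (%g x %g km extent)\n",
              x$n_rows, x$n_cols, x$cell_size,
              x$n_cols * x$cell_size, x$n_rows * x$cell_size))
  invisible(x)
}

#' Area of one grid cell in km^2
#' @param geometry A [grid_geometry()].
#' @return Cell area (km^2).
#' @export
cell_area <- function(geometry) geometry$cell_size^2

n_cells <- function(geometry) geometry$n_rows * geometry$n_cols

#' Cell-center coordinates
#'
#' @param geometry A [grid_geometry()].
#' @return List with `x` (length `n_cols`) and `y` (length `n_rows`)
#'   center coordinates in km.
#' @export
cell_centers <- function(geometry) {
  list(
    x = geometry$origin_x + (seq_len(geometry$n_cols) - 0.5) * geometry$cell_size,
    y = geometry$origin_y + (seq_len(geometry$n_rows) - 0.5) * geometry$cell_size
  )
}

# All pixel centers as an (n_rows*n_cols) x 2 matrix, column-major like the
# value matrices (row index varies fastest).
center_matrix <- function(geometry) {
  cc <- cell_centers(geometry)
  cbind(x = rep(cc$x, each = geometry$n_rows),
        y = rep(cc$y, times = geometry$n_cols))
}

#' Locate the pixel containing planar points
#'
#' @param geometry A [grid_geometry()].
#' @param x,y Point coordinates in km.
#' @return Data frame with integer `row` and `col`; `NA` for points outside
#'   the grid extent.
#' @export
point_to_pixel <- function(geometry, x, y) {
  col <- floor((x - geometry$origin_x) / geometry$cell_size) + 1
  row <- floor((y - geometry$origin_y) / geometry$cell_size) + 1
  bad <- col < 1 | col > geometry$n_cols | row < 1 | row > geometry$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

same_geometry <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol
}

stopifnot_geometry <- function(values, geometry, what = "raster") {
  if (!is.matrix(values) || nrow(values) != geometry$n_rows ||
      ncol(values) != geometry$n_cols) {
    stop(sprintf("%s does not match the grid geometry (%d x %d)",
                 what, geometry$n_rows, geometry$n_cols))
  }
  invisible(values)
}
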