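#' Euclidean distance-to-source raster
#'
#' Computes, for every pixel, the minimum Euclidean distance (km) from its
#' center to the nearest source. Sources may be given either as planar
#' points (e.g. settlements) or as a logical mask over the grid (e.g. water
#' pixels). Point sources are snapped to the center of the pixel that
#' contains them, so source pixels are exactly 0 and distances are always
#' center-to-center, consistent with the grid's km semantics.
#'
#' @param geometry A [grid_geometry()].
#' @param points Optional two-column matrix/data frame of source x, y (km).
#' @param mask Optional logical matrix (`n_rows` x `n_cols`); `TRUE` cells
#'   are sources.
#' @return Numeric matrix of distances in km.
#' @examples
#' g <- grid_geometry(10, 10)
#' d <- euclidean_distance_map(g, points = cbind(0.5, 0.5))
#' d[4, 5]  # 3-4-5 triangle from pixel (1,1): 5 km
#' @export
euclidean_distance_map <- function(geometry, points = NULL, mask = NULL) {
  if (is.null(points) && is.null(mask)) stop("supply points or mask")
  if (!is.null(mask)) {
    stopifnot_geometry(mask, geometry, "mask")
    idx <- which(mask)
    if (length(idx) == 0L) stop("source mask is empty")
    src <- center_matrix(geometry)[idx, , drop = FALSE]
  } else {
    points <- as.matrix(points)
    if (nrow(points) == 0L) stop("source point set is empty")
    px <- point_to_pixel(geometry, points[, 1], points[, 2])
    if (anyNA(px$row)) stop("source points fall outside the grid")
    cc <- cell_centers(geometry)
    src <- cbind(cc$x[px$col], cc$y[px$row])
  }
  ctr <- center_matrix(geometry)
  # chunked min-over-sources; memory stays bounded for large grids
  n <- nrow(ctr)
  out <- numeric(n)
  chunk <- max(1L, floor(4e6 / nrow(src)))
  for (start in seq(1L, n, by = chunk)) {
    i <- start:min(start + chunk - 1L, n)
    d2 <- outer(ctr[i, 1], src[, 1], "-")^2 + outer(ctr[i, 2], src[, 2], "-")^2
    out[i] <- sqrt(row_mins(d2))
  }
  matrix(out, geometry$n_rows, geometry$n_cols)
}

row_mins <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}
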