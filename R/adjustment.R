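#' Construct a density surface
#'
#' A single species-year raster of livestock density (head/km^2) plus its
#' grid geometry and processing stage.
#'
#' @param values Numeric matrix matching the geometry; `NA` outside the
#'   study area.
#' @param geometry A [grid_geometry()].
#' @param species,year Identity of the slice.
#' @param stage `"predicted"` or `"adjusted"`.
#' @return Object of class `density_surface`.
#' @export
density_surface <- function(values, geometry, species = NA_character_,
                            year = NA_integer_,
                            stage = c("predicted", "adjusted")) {
  stage <- match.arg(stage)
  stopifnot_geometry(values, geometry, "density surface")
  if (any(values < 0, na.rm = TRUE))
    stop("density surface has negative values")
  structure(
    list(values = values, geometry = geometry, species = species,
         year = year, stage = stage),
    class = "density_surface"
  )
}

#' @export
print.density_surface <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf(
    "<density_surface> %s %s %s: %d x %d px, mean %.3f head/km2 [%.3f, %.3f]\n",
    x$stage, x$species, x$year, x$geometry$n_rows, x$geometry$n_cols,
    mean(v), min(v), max(v)))
  invisible(x)
}

surface_values <- function(surface) {
  if (inherits(surface, "density_surface")) surface$values else surface
}

#' District totals of a density surface
#'
#' Sums density x pixel area over each district's pixels, giving the
#' predicted headcount total the dasymetric adjustment rescales against.
#'
#' @param surface A [density_surface()] or plain matrix.
#' @param zone Integer district-id matrix (same grid).
#' @param geometry Required if `surface` is a matrix.
#' @return Named numeric vector of heads per district id.
#' @export
zonal_total <- function(surface, zone, geometry = NULL) {
  if (inherits(surface, "density_surface")) geometry <- surface$geometry
  if (is.null(geometry)) stop("supply a geometry for matrix input")
  m <- surface_values(surface)
  stopifnot_geometry(m, geometry, "surface")
  stopifnot_geometry(zone, geometry, "zone raster")
  ok <- !is.na(zone) & !is.na(m)
  totals <- rowsum(m[ok] * cell_area(geometry), group = zone[ok])
  stats::setNames(totals[, 1], rownames(totals))
}

#' Mass-conserving dasymetric adjustment
#'
#' Rescales a predicted surface so district totals reproduce the census:
#' within district `j` every pixel is multiplied by `O_j / P_j`, where
#' `O_j` is the observed census total (heads) and `P_j` the predicted
#' total. Degenerate districts are handled explicitly: if `P_j = 0` but
#' `O_j > 0`, the observed total is spread uniformly over the district's
#' valid pixels (and flagged); if `O_j = 0` the district is set to zero.
#' The within-district relative pattern is otherwise untouched.
#'
#' @param surface Predicted [density_surface()] (non-negative).
#' @param observed Named vector of census totals `O_j` in heads, names =
#'   district ids.
#' @param zone Integer district-id matrix.
#' @return List with `surface` (stage `"adjusted"`) and `report` (data
#'   frame `district_id, observed, predicted, scale, residual, flag`).
#' @export
adjust_surface <- function(surface, observed, zone) {
  geom <- surface$geometry
  stopifnot_geometry(zone, geom, "zone raster")
  if (any(observed < 0, na.rm = TRUE))
    stop("negative observed census totals")
  ids <- sort(unique(zone[!is.na(zone)]))
  miss <- setdiff(as.character(ids), names(observed))
  if (length(miss))
    stop("no observed total for district(s): ", paste(miss, collapse = ", "))

  pred_tot <- zonal_total(surface, zone)
  a <- cell_area(geom)
  vals <- surface$values
  flags <- character(0)
  for (d in ids) {
    key <- as.character(d)
    o <- observed[[key]]
    p <- if (key %in% names(pred_tot)) pred_tot[[key]] else 0
    sel <- !is.na(zone) & zone == d & !is.na(vals)
    if (o == 0) {
      vals[sel] <- 0
    } else if (p > 0) {
      vals[sel] <- vals[sel] * (o / p)
    } else {
      vals[sel] <- o / (sum(sel) * a)  # uniform fallback, Eq. undefined
      flags <- c(flags, key)
    }
  }
  adjusted <- density_surface(vals, geom, species = surface$species,
                              year = surface$year, stage = "adjusted")
  report <- conservation_report(adjusted, observed, zone)
  report$flag <- ifelse(as.character(report$district_id) %in% flags,
                        "uniform_fallback", "")
  list(surface = adjusted, report = report)
}

conservation_report <- function(surface, observed, zone, tol = 1e-9) {
  totals <- zonal_total(surface, zone)
  ids <- sort(as.integer(names(totals)))
  obs <- observed[as.character(ids)]
  tot <- totals[as.character(ids)]
  data.frame(
    district_id = ids,
    observed = unname(obs),
    adjusted_total = unname(tot),
    residual = unname(abs(tot - obs) / pmax(obs, 1)),
    pass = unname(abs(tot - obs) / pmax(obs, 1) < tol)
  )
}

#' Verify district-total conservation of an adjusted surface
#'
#' Independently recomputes district totals of an adjusted surface and
#' compares them with the census: the relative residual
#' `|total - O_j| / max(O_j, 1)` must be below `tol` everywhere. This is
#' the pipeline's central contract (the pycnophylactic property).
#'
#' @param adjusted Adjusted [density_surface()].
#' @param observed Named vector of census totals (heads).
#' @param zone Integer district-id matrix.
#' @param tol Relative tolerance (default 1e-9).
#' @return Data frame `district_id, observed, adjusted_total, residual,
#'   pass`.
#' @export
verify_conservation <- function(adjusted, observed, zone, tol = 1e-9) {
  conservation_report(adjusted, observed, zone, tol = tol)
}

#' Census totals in heads for one species-year
#'
#' @param census Census table.
#' @param year,species Slice.
#' @return Named vector of headcounts by district id.
#' @export
census_totals <- function(census, year, species) {
  sub <- census[census$year == year & census$species == species, ]
  stats::setNames(sub$headcount, sub$district_id)
}
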