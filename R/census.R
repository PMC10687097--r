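#' District livestock densities from a census table
#'
#' Census headcounts become densities by dividing by the district area,
#' the response variable of the downscaling model (head/km^2).
#'
#' @param census Data frame with `district_id, year, species, headcount,
#'   area_km2`.
#' @return Data frame `district_id, year, species, density`.
#' @export
compute_density <- function(census) {
  check_census(census)
  bad <- !is.finite(census$area_km2) | census$area_km2 <= 0
  if (any(bad))
    stop("non-positive area for district(s): ",
         paste(unique(census$district_id[bad]), collapse = ", "))
  data.frame(
    district_id = census$district_id, year = census$year,
    species = census$species,
    density = census$headcount / census$area_km2
  )
}

check_census <- function(census, need_area = TRUE) {
  cols <- c("district_id", "year", "species", "headcount",
            if (need_area) "area_km2")
  missing <- setdiff(cols, names(census))
  if (length(missing))
    stop("census table missing column(s): ", paste(missing, collapse = ", "))
  if (any(census$headcount < 0, na.rm = TRUE))
    stop("negative headcounts in census table")
  key <- paste(census$district_id, census$year, census$species)
  if (anyDuplicated(key))
    stop("duplicate (district_id, year, species) records in census table")
  invisible(census)
}

#' Fill interior census gaps by linear interpolation
#'
#' Missing (district, year, species) headcounts inside the observed span
#' are linearly interpolated between the nearest flanking observed years
#' (the standard repair for short census outages, e.g. a missing year
#' bracketed by the years before and after). No extrapolation: a required
#' year outside a series' observed span is an error. Filled records carry
#' `interpolated = TRUE`.
#'
#' @param census Census data frame.
#' @param required_years Years the output must cover.
#' @return Census table with gap rows added and an `interpolated` flag.
#' @export
interpolate_missing_years <- function(census, required_years) {
  check_census(census)
  census$interpolated <- FALSE
  groups <- split(census,
                  list(census$district_id, census$species), drop = TRUE)
  filled <- lapply(groups, function(g) {
    have <- sort(g$year)
    miss <- setdiff(required_years, have)
    if (!length(miss)) return(g)
    outside <- miss[miss < min(have) | miss > max(have)]
    if (length(outside))
      stop(sprintf(
        "cannot interpolate year(s) %s for district %s (%s): no flanking observation",
        paste(outside, collapse = ", "), g$district_id[1], g$species[1]))
    o <- g[order(g$year), ]
    heads <- stats::approx(o$year, o$headcount, xout = miss)$y
    rbind(o, data.frame(
      district_id = g$district_id[1], year = miss, species = g$species[1],
      headcount = heads, area_km2 = g$area_km2[1], interpolated = TRUE
    ))
  })
  out <- do.call(rbind, filled)
  out <- out[order(out$district_id, out$species, out$year), ]
  rownames(out) <- NULL
  out
}

#' Merge census districts
#'
#' Administrative restructurings split or rename districts mid-series;
#' merging sums headcounts and areas of the affected districts under a new
#' id so every merged unit has a complete, comparable series. Densities of
#' a merged unit are recomputed from the summed quantities.
#'
#' @param census Census data frame.
#' @param merge_map Data frame `old_id, new_id`; districts absent from the
#'   map keep their id.
#' @return Merged census table.
#' @export
merge_districts <- function(census, merge_map) {
  check_census(census)
  if (!all(c("old_id", "new_id") %in% names(merge_map)))
    stop("merge_map needs columns old_id, new_id")
  id <- census$district_id
  hit <- match(id, merge_map$old_id)
  id[!is.na(hit)] <- merge_map$new_id[hit[!is.na(hit)]]

  # districts being combined must cover identical year x species sets
  for (nid in unique(merge_map$new_id)) {
    olds <- merge_map$old_id[merge_map$new_id == nid]
    olds <- intersect(olds, census$district_id)
    if (length(olds) < 2) next
    keysets <- lapply(olds, function(o) {
      sub <- census[census$district_id == o, ]
      sort(paste(sub$year, sub$species))
    })
    ref <- keysets[[1]]
    for (k in seq_along(keysets)[-1]) {
      gaps <- c(setdiff(ref, keysets[[k]]), setdiff(keysets[[k]], ref))
      if (length(gaps))
        stop(sprintf("districts merged into %s disagree on records: %s",
                     nid, paste(gaps, collapse = "; ")))
    }
  }

  agg <- stats::aggregate(
    cbind(headcount, area_km2) ~ new_id + year + species,
    data = data.frame(census, new_id = id), FUN = sum)
  out <- data.frame(
    district_id = agg$new_id, year = agg$year, species = agg$species,
    headcount = agg$headcount, area_km2 = agg$area_km2
  )
  out <- out[order(out$district_id, out$species, out$year), ]
  rownames(out) <- NULL
  out
}

#' Rasterize district densities onto the zone grid
#'
#' Every pixel of a district carries the district's census density for the
#' requested year and species; pixels outside all zones stay `NA`.
#'
#' @param densities Output of [compute_density()].
#' @param zone Integer district-id matrix.
#' @param geometry A [grid_geometry()].
#' @param year,species Which slice to rasterize.
#' @return Density matrix (head/km^2).
#' @export
rasterize_density <- function(densities, zone, geometry, year, species) {
  stopifnot_geometry(zone, geometry, "zone raster")
  sub <- densities[densities$year == year & densities$species == species, ]
  ids <- sort(unique(zone[!is.na(zone)]))
  missing <- setdiff(ids, sub$district_id)
  if (length(missing))
    stop(sprintf("no density for district(s) %s in %s/%s",
                 paste(missing, collapse = ", "), species, year))
  lut <- stats::setNames(sub$density, sub$district_id)
  out <- matrix(NA_real_, geometry$n_rows, geometry$n_cols)
  valid <- !is.na(zone)
  out[valid] <- unname(lut[as.character(zone[valid])])
  out
}

#' District areas implied by the zone raster
#'
#' @param zone Integer district-id matrix.
#' @param geometry A [grid_geometry()].
#' @return Named vector of areas (km^2) per district id.
#' @export
district_areas <- function(zone, geometry) {
  ids <- sort(unique(zone[!is.na(zone)]))
  counts <- vapply(ids, function(d) sum(zone == d, na.rm = TRUE), integer(1))
  stats::setNames(counts * cell_area(geometry), ids)
}
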