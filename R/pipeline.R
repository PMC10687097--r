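species_prefix <- c(small_ruminant = "sr", horse = "hr")

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text raster format readable by any GIS: a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed
#' by rows north to south. `NA` cells are written as the geometry's nodata
#' sentinel.
#'
#' @param values Numeric matrix matching `geometry`.
#' @param geometry A [grid_geometry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, geometry, path) {
  stopifnot_geometry(values, geometry, "raster")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", geometry$n_cols),
    sprintf("nrows %d", geometry$n_rows),
    sprintf("xllcorner %.10g", geometry$origin_x),
    sprintf("yllcorner %.10g", geometry$origin_y),
    sprintf("cellsize %.10g", geometry$cell_size),
    sprintf("NODATA_value %.10g", geometry$nodata)
  ), con)
  v <- values
  v[is.na(v)] <- geometry$nodata
  # internal row 1 is the southern edge; ascii grids list north first
  for (i in rev(seq_len(geometry$n_rows)))
    writeLines(paste(formatC(v[i, ], format = "g", digits = 17),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] (or any ESRI ASCII
#'   grid).
#' @return List with `values` (matrix, nodata as `NA`) and `geometry`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  header <- lines[1:6]
  get <- function(key) {
    hit <- grep(paste0("^", key, "\\b"), header, ignore.case = TRUE)
    if (!length(hit)) stop("malformed ascii grid header: missing ", key)
    as.numeric(strsplit(trimws(header[hit[1]]), "\\s+")[[1]][2])
  }
  geom <- grid_geometry(get("nrows"), get("ncols"), get("cellsize"),
                        get("xllcorner"), get("yllcorner"),
                        nodata = get("NODATA_value"))
  rows <- lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, rows)
  if (nrow(m) != geom$n_rows || ncol(m) != geom$n_cols)
    stop("ascii grid body does not match its header dimensions")
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m[m == geom$nodata] <- NA_real_
  list(values = m, geometry = geom)
}

#' Write a species-year density raster
#'
#' Files are named by a species acronym (`sr` for small ruminants, `hr`
#' for horses) joined to the year by an underscore, e.g. `sr_2015.asc`.
#'
#' @param surface A [density_surface()].
#' @param species,year Identity (defaults taken from the surface).
#' @param dir Output directory.
#' @return The written path.
#' @export
write_density_raster <- function(surface, species = surface$species,
                                 year = surface$year, dir = ".") {
  if (!species %in% names(species_prefix))
    stop("unknown species: ", species)
  path <- file.path(dir, sprintf("%s_%s.asc", species_prefix[[species]],
                                 year))
  write_ascii_grid(surface$values, surface$geometry, path)
  path
}

#' Read a density raster written by [write_density_raster()]
#'
#' @param path Raster path.
#' @param species,year,stage Metadata to attach.
#' @return A [density_surface()].
#' @export
read_density_raster <- function(path, species = NA_character_,
                                year = NA_integer_, stage = "adjusted") {
  g <- read_ascii_grid(path)
  density_surface(g$values, g$geometry, species = species, year = year,
                  stage = stage)
}

write_trend_rasters <- function(ts, geometry, species, dir) {
  prefix <- species_prefix[[species]]
  paths <- character(0)
  for (band in c("tau", "slope", "p")) {
    p <- file.path(dir, sprintf("%s_trend_%s.asc", prefix, band))
    write_ascii_grid(ts[[band]], geometry, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, sprintf("%s_trend_mask.asc", prefix))
  write_ascii_grid(ts$mask + 0, geometry, p)
  c(paths, p)
}

#' Write a landscape's inputs to a directory
#'
#' Emits the zone raster and predictor layers as ESRI ASCII grids, the
#' settlement table and census as CSV, and a JSON manifest recording the
#' grid geometry, years, covariates and generator seed.
#'
#' @param landscape A landscape with predictors.
#' @param dir Output directory (created if needed).
#' @param census Optional census table to write alongside.
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir, census = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geom <- landscape$geometry
  write_ascii_grid(landscape$zone, geom, file.path(dir, "zone.asc"))
  utils::write.csv(landscape$settlements,
                   file.path(dir, "settlements.csv"), row.names = FALSE)
  pdir <- file.path(dir, "predictors")
  dir.create(pdir, showWarnings = FALSE)
  for (yr in names(landscape$predictors))
    for (nm in names(landscape$predictors[[yr]]))
      write_ascii_grid(landscape$predictors[[yr]][[nm]], geom,
                       file.path(pdir, sprintf("%s_%s.asc", yr, nm)))
  if (!is.null(census))
    utils::write.csv(census, file.path(dir, "census.csv"),
                     row.names = FALSE)
  manifest <- list(
    geometry = unclass(geom),
    years = as.integer(names(landscape$predictors)),
    covariates = covariate_names(),
    seed = landscape$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load landscape inputs from a directory
#'
#' Reads a manifest-described input tree (zone raster, predictor layers,
#' settlement table, census CSV) and validates every layer against the
#' manifest grid; layers on a different grid are rejected, never silently
#' resampled.
#'
#' @param dir Directory written by [write_landscape()] (or assembled by
#'   hand to the same layout).
#' @return List with `landscape` and `census` (`NULL` if absent).
#' @export
load_inputs <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  g <- manifest$geometry
  geom <- grid_geometry(g$n_rows, g$n_cols, g$cell_size, g$origin_x,
                        g$origin_y, g$nodata)
  offenders <- character(0)
  read_layer <- function(path) {
    r <- read_ascii_grid(path)
    if (!same_geometry(r$geometry, geom))
      offenders <<- c(offenders, basename(path))
    r$values
  }
  zone <- read_layer(file.path(dir, "zone.asc"))
  predictors <- lapply(as.character(manifest$years), function(yr) {
    stats::setNames(lapply(manifest$covariates, function(nm)
      read_layer(file.path(dir, "predictors",
                           sprintf("%s_%s.asc", yr, nm)))),
      manifest$covariates)
  })
  names(predictors) <- as.character(manifest$years)
  if (length(offenders))
    stop("layer(s) do not match the manifest grid: ",
         paste(offenders, collapse = ", "))

  settlements <- utils::read.csv(file.path(dir, "settlements.csv"))
  need <- c("settlement_id", "x", "y", "population", "district_id")
  missing <- setdiff(need, names(settlements))
  if (length(missing))
    stop("settlement table missing column(s): ",
         paste(missing, collapse = ", "))

  census <- NULL
  cpath <- file.path(dir, "census.csv")
  if (file.exists(cpath)) {
    census <- utils::read.csv(cpath)
    if (!"area_km2" %in% names(census)) {
      # areas fall back to the zone raster so census densities and zonal
      # sums share one area definition
      zn <- matrix(as.integer(zone), geom$n_rows)
      areas <- district_areas(zn, geom)
      census$area_km2 <- unname(areas[as.character(census$district_id)])
    }
    check_census(census)
  }
  landscape <- structure(
    list(geometry = geom, zone = matrix(as.integer(zone), geom$n_rows),
         settlements = settlements, predictors = predictors, truth = NULL,
         seed = manifest$seed),
    class = "landscape"
  )
  list(landscape = landscape, census = census)
}

#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run. Synthetic-landscape parameters
#' are used unless `input_dir` points at a directory readable by
#' [load_inputs()].
#'
#' @param years Contiguous sorted years (default 2000:2019).
#' @param species Subset of `c("small_ruminant", "horse")`.
#' @param selection_year Year of the buffer x split selection experiment
#'   (default 2015).
#' @param k Settlements per district (default 10).
#' @param buffer_km,train_fraction Sampling design used when the
#'   experiment stage is skipped (defaults 10 km, 0.9).
#' @param run_experiment Run the 12-model experiment and adopt its winner
#'   (default `TRUE`).
#' @param retune_per_year Re-tune hyperparameters for every year rather
#'   than once on the selection year (default `FALSE`).
#' @param alpha Significance level of the trend mask.
#' @param trend_stage Run trends on `"adjusted"` (default) or
#'   `"predicted"` surfaces.
#' @param grouping Train/test grouping, see [split_train_test()].
#' @param mtry_grid,ntree_grid,cv_folds,cv_repeats Tuning controls.
#' @param n_districts,n_rows,n_cols,n_settlements Synthetic landscape
#'   size.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory.
#' @param input_dir Optional pre-built input tree.
#' @return List of class `run_config`.
#' @export
run_config <- function(years = 2000:2019,
                       species = c("small_ruminant", "horse"),
                       selection_year = 2015,
                       k = 10, buffer_km = 10, train_fraction = 0.9,
                       run_experiment = TRUE, retune_per_year = FALSE,
                       alpha = 0.05, trend_stage = "adjusted",
                       grouping = "point",
                       mtry_grid = c(2, 4, 7, 13),
                       ntree_grid = c(250, 500),
                       cv_folds = 10, cv_repeats = 5,
                       n_districts = 24, n_rows = 200, n_cols = 200,
                       n_settlements = 12,
                       seed = 42, out_dir = tempfile("livestockgrid_run_"),
                       input_dir = NULL) {
  if (is.unsorted(years) || !all(diff(years) == 1))
    stop("years must be sorted and contiguous")
  bad <- setdiff(species, names(species_prefix))
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  if (!selection_year %in% years)
    stop("selection_year must be one of years")
  structure(as.list(environment()), class = "run_config")
}

#' Run the full downscaling pipeline
#'
#' End to end: landscape (synthetic or loaded), census densities, the
#' buffer x split selection experiment for the selection year, per
#' species-year tuning/fitting/prediction, mass-conserving adjustment,
#' per-species trend surfaces, and all output files (rasters, fit reports,
#' experiment grid, manifest, log). Deterministic for a fixed config seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list: `out_dir`, `landscape`, `census`,
#'   `experiment` (grid or `NULL`), `design` (chosen buffer/split),
#'   `surfaces` (adjusted [density_surface()]s by species/year),
#'   `predicted` (unadjusted), `reports` (conservation reports),
#'   `fit_reports` (per-year test metrics), `trends` (per species), `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  if (!is.null(config$input_dir)) {
    inputs <- load_inputs(config$input_dir)
    landscape <- inputs$landscape
    census <- inputs$census
    if (is.null(census)) stop("input_dir provides no census.csv")
  } else {
    landscape <- default_landscape(
      seed = config$seed, years = config$years,
      n_districts = config$n_districts, n_rows = config$n_rows,
      n_cols = config$n_cols, n_settlements = config$n_settlements)
    census <- aggregate_truth_to_census(landscape)
    note("synthetic landscape: %d districts, %d x %d grid, seed %d",
         config$n_districts, config$n_rows, config$n_cols, config$seed)
  }
  densities <- compute_density(census)
  if ("interpolated" %in% names(census) && any(census$interpolated))
    note("census contains %d interpolated records",
         sum(census$interpolated))

  n_per_district <- table(landscape$settlements$district_id)
  short <- names(n_per_district)[n_per_district < config$k]
  if (length(short))
    note("district(s) with fewer than k=%d settlements: %s", config$k,
         paste(short, collapse = ", "))

  experiment <- NULL
  design <- list(buffer_km = config$buffer_km,
                 train_fraction = config$train_fraction,
                 split = split_label(config$train_fraction))
  if (config$run_experiment) {
    experiment <- run_experiment_grid(
      landscape, census, config$selection_year, config$species[1],
      k = config$k, mtry_grid = config$mtry_grid,
      ntree_grid = config$ntree_grid, cv_folds = config$cv_folds,
      cv_repeats = config$cv_repeats, grouping = config$grouping,
      seed = sub_seed(config$seed, 11L))
    utils::write.csv(experiment,
                     file.path(config$out_dir, sprintf(
                       "experiment_grid_%s_%s.csv",
                       config$species[1], config$selection_year)),
                     row.names = FALSE)
    design <- select_best_model(experiment)
    note("selection experiment winner: %g km buffer, %s split",
         design$buffer_km, design$split)
  }

  surfaces <- predicted <- reports <- trends <- list()
  fit_reports <- list()
  for (sp in config$species) {
    sp_seed <- sub_seed(config$seed, match(sp, names(species_prefix)))
    tuned <- NULL
    sp_surfaces <- list()
    sp_predicted <- list()
    sp_reports <- list()
    for (yi in seq_along(config$years)) {
      yr <- config$years[yi]
      samples <- build_sample_set(landscape, densities, yr, sp,
                                  k = config$k,
                                  buffer_km = design$buffer_km)
      split <- split_train_test(samples, design$train_fraction,
                                seed = sub_seed(sp_seed, yi, 1L),
                                grouping = config$grouping)
      if (is.null(tuned) || config$retune_per_year)
        tuned <- tune_hyperparameters(
          split$train, config$mtry_grid, config$ntree_grid,
          config$cv_folds, config$cv_repeats,
          seed = sub_seed(sp_seed, yi, 2L))
      surface <- fit_and_predict(split$train, tuned, landscape, yr,
                                 seed = sub_seed(sp_seed, yi, 3L))
      model <- attr(surface, "model")
      test_stats <- fit_statistics(split$test$response,
                                   predict(model, split$test))
      obs <- census_totals(census, yr, sp)
      adj <- adjust_surface(surface, obs, landscape$zone)
      fb <- adj$report$district_id[adj$report$flag == "uniform_fallback"]
      if (length(fb))
        note("%s %s: uniform fallback in district(s) %s", sp, yr,
             paste(fb, collapse = ", "))
      write_density_raster(adj$surface, dir = config$out_dir)
      sp_surfaces[[as.character(yr)]] <- adj$surface
      sp_predicted[[as.character(yr)]] <- surface
      sp_reports[[as.character(yr)]] <- adj$report
      fit_reports[[length(fit_reports) + 1L]] <- data.frame(
        species = sp, year = yr, buffer_km = design$buffer_km,
        split = design$split, mtry = tuned$mtry, ntree = tuned$ntree,
        cv_r2 = tuned$cv[["r2"]], cv_rmse = tuned$cv[["rmse"]],
        cv_mae = tuned$cv[["mae"]],
        test_r2 = test_stats[["r2"]], test_rmse = test_stats[["rmse"]],
        test_mae = test_stats[["mae"]],
        n_train = nrow(split$train), n_test = nrow(split$test)
      )
    }
    stack <- if (config$trend_stage == "adjusted") sp_surfaces
             else sp_predicted
    trends[[sp]] <- trend_surface(stack, times = config$years,
                                  alpha = config$alpha)
    write_trend_rasters(trends[[sp]], landscape$geometry, sp,
                        config$out_dir)
    surfaces[[sp]] <- sp_surfaces
    predicted[[sp]] <- sp_predicted
    reports[[sp]] <- sp_reports
  }
  fit_report <- do.call(rbind, fit_reports)
  utils::write.csv(fit_report, file.path(config$out_dir, "fit_report.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "livestockgrid",
    config = unclass(config)[setdiff(names(config), "out_dir")],
    geometry = unclass(landscape$geometry),
    design = design,
    files = sort(list.files(config$out_dir))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))

  invisible(list(
    out_dir = config$out_dir, landscape = landscape, census = census,
    experiment = experiment, design = design, surfaces = surfaces,
    predicted = predicted, reports = reports, fit_report = fit_report,
    trends = trends, log = log_lines
  ))
}
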