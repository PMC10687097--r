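#' Names of the 13 predictor covariates
#'
#' The covariate set mirrors the social-environmental predictors used for
#' livestock-density downscaling: climate (precipitation, temperature,
#' vapour-pressure deficit, solar radiation, soil moisture, snow depth),
#' vegetation proxies (leaf-area index, net primary productivity),
#' socioeconomic fields (human population density, nighttime light),
#' topography (elevation) and proximity (distance to settlements and to
#' water bodies).
#'
#' @return Character vector of 13 layer names.
#' @export
covariate_names <- function() {
  c("precipitation", "temperature", "vpd", "solar_radiation",
    "soil_moisture", "snow_depth", "population_density", "nighttime_light",
    "elevation", "dist_settlement", "dist_water", "lai", "npp")
}

# layers redrawn every year; the rest are static
dynamic_covariates <- function() {
  c("precipitation", "temperature", "vpd", "solar_radiation",
    "soil_moisture", "snow_depth", "lai", "npp")
}

#' Generate a synthetic district landscape
#'
#' Builds the administrative skeleton the downscaling pipeline assumes:
#' a zone raster partitioning the grid into contiguous districts (Voronoi
#' tessellation of uniformly random seed pixels) and a settlement table.
#' Settlements are scattered around each district's centroid (Gaussian, sd =
#' 1/4 of the district's equivalent radius, rejection-sampled into the
#' district) with log-normal populations, reproducing the clustered,
#' heavy-tailed settlement structure of real census regions.
#'
#' @param n_districts Number of districts (>= 2).
#' @param geometry A [grid_geometry()].
#' @param n_settlements_per_district Settlements per district (>= 1).
#' @param seed Integer seed; identical seeds give bit-identical landscapes.
#' @param pop_meanlog,pop_sdlog Log-normal population parameters
#'   (defaults: median 500 inhabitants, sigma 1.2).
#' @return An object of class `landscape` with elements `geometry`,
#'   `zone` (integer matrix of district ids), `settlements` (data frame
#'   `settlement_id,x,y,population,district_id`), and empty `predictors`
#'   and `truth` slots.
#' @export
generate_landscape <- function(n_districts, geometry,
                               n_settlements_per_district = 12,
                               seed = 1,
                               pop_meanlog = log(500), pop_sdlog = 1.2) {
  if (n_districts < 2) stop("n_districts must be >= 2")
  if (n_settlements_per_district < 1)
    stop("n_settlements_per_district must be >= 1")
  if (n_cells(geometry) < n_districts * n_settlements_per_district)
    stop(sprintf(
      "geometry too small: %d cells cannot host %d districts of >= %d pixels",
      n_cells(geometry), n_districts, n_settlements_per_district))

  with_seed(seed, {
    ctr <- center_matrix(geometry)
    seeds_idx <- sample.int(n_cells(geometry), n_districts)
    seeds_xy <- ctr[seeds_idx, , drop = FALSE]
    zone <- matrix(NA_integer_, geometry$n_rows, geometry$n_cols)
    chunk <- max(1L, floor(4e6 / n_districts))
    for (start in seq(1L, nrow(ctr), by = chunk)) {
      i <- start:min(start + chunk - 1L, nrow(ctr))
      d2 <- outer(ctr[i, 1], seeds_xy[, 1], "-")^2 +
        outer(ctr[i, 2], seeds_xy[, 2], "-")^2
      zone[i] <- max.col(-d2, ties.method = "first")
    }
    counts <- tabulate(zone, nbins = n_districts)
    if (any(counts < n_settlements_per_district))
      stop(sprintf(
        "geometry too small: district %d has %d pixels, need >= %d",
        which.min(counts), min(counts), n_settlements_per_district))

    settlements <- do.call(rbind, lapply(seq_len(n_districts), function(d) {
      idx <- which(zone == d)
      cx <- mean(ctr[idx, 1]); cy <- mean(ctr[idx, 2])
      radius <- sqrt(length(idx) * cell_area(geometry) / pi)
      pts <- matrix(NA_real_, n_settlements_per_district, 2)
      for (s in seq_len(n_settlements_per_district)) {
        for (try in 1:1000) {
          x <- rnorm(1, cx, radius / 4); y <- rnorm(1, cy, radius / 4)
          px <- point_to_pixel(geometry, x, y)
          if (!is.na(px$row) && zone[px$row, px$col] == d) break
          x <- NA
        }
        if (is.na(x)) {  # fall back to a random pixel of the district
          j <- idx[sample.int(length(idx), 1)]
          x <- ctr[j, 1]; y <- ctr[j, 2]
        }
        pts[s, ] <- c(x, y)
      }
      data.frame(x = pts[, 1], y = pts[, 2], district_id = d)
    }))
    settlements$population <- pmax(1, round(rlnorm(nrow(settlements),
                                                   pop_meanlog, pop_sdlog)))
    settlements <- data.frame(
      settlement_id = seq_len(nrow(settlements)),
      x = settlements$x, y = settlements$y,
      population = settlements$population,
      district_id = settlements$district_id
    )

    structure(
      list(geometry = geometry, zone = zone, settlements = settlements,
           predictors = NULL, truth = NULL, seed = seed),
      class = "landscape"
    )
  })
}

#' @export
print.landscape <- function(x, ...) {
  yrs <- names(x$predictors)
  cat(sprintf("<landscape> %d x %d km grid, %d districts, %d settlements\n",
              x$geometry$n_rows * x$geometry$cell_size,
              x$geometry$n_cols * x$geometry$cell_size,
              length(unique(x$settlements$district_id)),
              nrow(x$settlements)))
  if (!is.null(yrs))
    cat(sprintf("  predictors: %d layers x years %s-%s\n",
                length(x$predictors[[1]]), yrs[1], yrs[length(yrs)]))
  if (!is.null(x$truth))
    cat(sprintf("  truth: %s\n", paste(names(x$truth), collapse = ", ")))
  invisible(x)
}

# Smoothed standardized Gaussian random field: white noise convolved with a
# separable Gaussian kernel of the given correlation length (km), then
# scaled to mean 0, sd 1.
gaussian_field <- function(geometry, length_scale, seed) {
  with_seed(seed, {
    w <- matrix(rnorm(n_cells(geometry)), geometry$n_rows, geometry$n_cols)
    sm <- smooth_matrix(w, length_scale / geometry$cell_size)
    (sm - mean(sm)) / stats::sd(sm)
  })
}

# separable Gaussian blur with kernel sd in pixels (dense weight matrices;
# grids here are at most a few hundred cells per side)
smooth_matrix <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  k_for <- function(n) {
    d <- outer(seq_len(n), seq_len(n), "-")
    k <- exp(-d^2 / (2 * sigma_px^2))
    k / rowSums(k)
  }
  k_for(nrow(m)) %*% m %*% t(k_for(ncol(m)))
}

# sum of per-settlement Gaussian kernels scaled by population (units: per km^2)
settlement_kernel_field <- function(geometry, settlements, kernel_sd) {
  ctr <- center_matrix(geometry)
  out <- numeric(nrow(ctr))
  for (s in seq_len(nrow(settlements))) {
    d2 <- (ctr[, 1] - settlements$x[s])^2 + (ctr[, 2] - settlements$y[s])^2
    out <- out + settlements$population[s] *
      exp(-d2 / (2 * kernel_sd^2)) / (2 * pi * kernel_sd^2)
  }
  matrix(out, geometry$n_rows, geometry$n_cols)
}

#' Generate the 13 annual predictor layers
#'
#' Fills the landscape's predictor stack for the requested years. Climate
#' and vegetation layers (precipitation, temperature, vpd, solar_radiation,
#' soil_moisture, snow_depth, lai, npp) are spatially autocorrelated
#' Gaussian fields superimposed on a layer-specific planar gradient: the
#' gradient direction is fixed per layer (continental gradients such as
#' the south-north temperature gradient do not change orientation between
#' years) while the autocorrelated anomaly is redrawn each year from
#' year-specific sub-seeds. `gradient_weight` sets the share of spatial
#' standard deviation carried by the gradient (default 0.7, gradients
#' first-order as they are over continental census regions).
#' Elevation is a static smoothed field plus a linear gradient.
#' Population density and nighttime light are static sums of per-settlement
#' Gaussian kernels scaled by settlement population. Distance layers are
#' Euclidean distance maps to settlements and to a static synthetic water
#' mask (the top 2% of a smoothed field).
#'
#' @param landscape A [generate_landscape()] result.
#' @param years Integer vector of years.
#' @param length_scale Correlation length (km) of the anomaly fields
#'   (default 60, smooth at the district scale).
#' @param gradient_weight Fraction of each dynamic layer's spatial sd
#'   contributed by its fixed planar gradient, in `[0, 1)`.
#' @param seed Integer seed.
#' @return The landscape with `predictors[[year]][[name]]` matrices filled.
#' @export
generate_predictors <- function(landscape, years, length_scale = 60,
                                gradient_weight = 0.7, seed = 1) {
  if (length_scale <= 0) stop("length_scale must be > 0")
  if (gradient_weight < 0 || gradient_weight >= 1)
    stop("gradient_weight must be in [0, 1)")
  geom <- landscape$geometry
  st <- landscape$settlements

  elevation <- gaussian_field(geom, length_scale, sub_seed(seed, 900L)) +
    outer(seq_len(geom$n_rows), seq_len(geom$n_cols),
          function(i, j) (i + j) / (geom$n_rows + geom$n_cols))
  pop_density <- settlement_kernel_field(geom, st, kernel_sd = 3)
  nightlight <- settlement_kernel_field(geom, st, kernel_sd = 2)^0.5
  dist_settlement <- euclidean_distance_map(geom, points = st[, c("x", "y")])
  water_field <- gaussian_field(geom, length_scale, sub_seed(seed, 901L))
  water_mask <- water_field >= stats::quantile(water_field, 0.98)
  dist_water <- euclidean_distance_map(geom, mask = water_mask)

  static <- list(
    population_density = pop_density, nighttime_light = nightlight,
    elevation = elevation, dist_settlement = dist_settlement,
    dist_water = dist_water
  )
  dyn <- dynamic_covariates()
  # one continental gradient orientation shared by all dynamic layers:
  # climate and vegetation drivers are physically coupled and co-vary
  # along the same large-scale gradient, they are not independent planes
  theta <- with_seed(sub_seed(seed, 800L), stats::runif(1, 0, 2 * pi))
  plane <- outer(seq_len(geom$n_rows) * sin(theta),
                 seq_len(geom$n_cols) * cos(theta), "+")
  plane <- (plane - mean(plane)) / stats::sd(plane)
  w <- gradient_weight
  predictors <- lapply(seq_along(years), function(yi) {
    layers <- c(
      stats::setNames(lapply(seq_along(dyn), function(li) {
        sqrt(1 - w^2) * gaussian_field(geom, length_scale,
                                       sub_seed(seed, yi, li)) +
          w * plane
      }), dyn),
      static
    )
    layers[covariate_names()]
  })
  names(predictors) <- as.character(years)
  landscape$predictors <- predictors
  landscape$water_mask <- water_mask
  landscape
}

#' Generate latent true density surfaces
#'
#' The latent base density is a log-linear response to the standardized
#' predictors multiplied by a settlement-proximity factor that decays to a
#' remote-grazing background level:
#' \deqn{D_0 = s \exp(\beta^T z) [b + (1 - b) \exp(-d_{settlement}/\lambda)]}
#' where `z` are the first year's predictor layers standardized over the
#' grid (settlement-kernel layers log-transformed first, they are
#' heavy-tailed), `s` a species-level scale (head/km^2), `\lambda` the
#' decay length (km) and `b` the background fraction: densities peak
#' around settlements (daily grazing radius) but remote pastures retain a
#' share of the local density because larger herds graze far from
#' villages. Year `t` (indexed from 0) is `D_0 (1 + trend_slope * t)` plus
#' white Gaussian noise, clipped at 0. The clipped fraction per layer is
#' stored in the `clip_rate` attribute.
#'
#' @param landscape Landscape with predictors already generated.
#' @param years Years (must be a subset of the predictor years).
#' @param beta Named coefficient vector over [covariate_names()]; missing
#'   names default to 0.
#' @param trend_slope Relative trend per year (scalar or per-species named
#'   vector); 0.02 means +2% of base density per year.
#' @param noise_sd Noise sd in head/km^2 (scalar or per-species).
#' @param scale Species base scale(s), head/km^2.
#' @param decay_length Settlement decay length, km (> 0).
#' @param background Remote-grazing background fraction `b` in `[0, 1]`
#'   (default 0.3).
#' @param species Character vector of species names.
#' @param seed Integer seed.
#' @return The landscape with `truth[[species]][[year]]` matrices filled.
#' @export
generate_truth <- function(landscape, years,
                           beta = default_truth_beta(),
                           trend_slope = 0.02,
                           noise_sd = c(small_ruminant = 2, horse = 0.2),
                           scale = c(small_ruminant = 15, horse = 1.5),
                           decay_length = 10,
                           background = 0.3,
                           species = names(scale),
                           seed = 1) {
  if (is.null(landscape$predictors)) stop("generate predictors first")
  if (decay_length <= 0) stop("decay_length must be > 0")
  years_chr <- as.character(years)
  if (!all(years_chr %in% names(landscape$predictors)))
    stop("predictors missing for some requested years")

  full_beta <- stats::setNames(numeric(13), covariate_names())
  if (is.null(names(beta)) && length(beta) == 13) {
    full_beta[] <- beta
  } else {
    unknown <- setdiff(names(beta), covariate_names())
    if (length(unknown)) stop("unknown covariates in beta: ",
                              paste(unknown, collapse = ", "))
    full_beta[names(beta)] <- beta
  }
  noise_sd <- rep_named(noise_sd, species)
  scale <- rep_named(scale, species)
  trend_slope <- rep_named(trend_slope, species)

  base_year <- names(landscape$predictors)[1]
  # settlement-kernel fields are heavy-tailed; log before z-scoring so the
  # exponential link yields realistic densities instead of city blow-ups
  skewed <- c("population_density", "nighttime_light")
  z <- lapply(covariate_names(), function(nm) {
    v <- landscape$predictors[[base_year]][[nm]]
    if (nm %in% skewed) v <- log1p(v)
    s <- stats::sd(v)
    if (s == 0) v * 0 else (v - mean(v)) / s
  })
  if (background < 0 || background > 1)
    stop("background must be in [0, 1]")
  lin <- Reduce(`+`, Map(function(m, b) m * b, z, full_beta))
  decay <- background + (1 - background) *
    exp(-landscape$predictors[[base_year]][["dist_settlement"]] /
          decay_length)

  truth <- lapply(species, function(sp) {
    d0 <- pmax(scale[sp] * exp(lin) * decay, 0)
    out <- lapply(seq_along(years), function(yi) {
      t_idx <- years[yi] - years[1]
      m <- d0 * (1 + trend_slope[sp] * t_idx)
      if (noise_sd[sp] > 0) {
        m <- m + with_seed(
          sub_seed(seed, match(sp, species), yi),
          matrix(rnorm(length(m), 0, noise_sd[sp]), nrow(m), ncol(m)))
      }
      clipped <- mean(m < 0)
      m <- pmax(m, 0)
      attr(m, "clip_rate") <- clipped
      m
    })
    names(out) <- years_chr
    out
  })
  names(truth) <- species
  landscape$truth <- truth
  landscape$truth_base <- lapply(stats::setNames(species, species),
                                 function(sp) pmax(scale[sp] * exp(lin) * decay, 0))
  landscape
}

#' Default log-linear coefficients of the latent density surface
#'
#' Substantial weights on the climate, vegetation and socioeconomic
#' drivers that dominate real livestock distributions (temperature,
#' precipitation, vegetation proxies, population density, nighttime
#' light), a negative weight on elevation, and zero elsewhere: the latent
#' density is primarily covariate-driven, the structural premise of
#' covariate-based dasymetric downscaling. The settlement effect enters
#' through the explicit distance-decay factor, so `dist_settlement`
#' carries no additional log-linear weight.
#'
#' @return Named numeric vector over [covariate_names()].
#' @export
default_truth_beta <- function() {
  c(precipitation = 0.3, temperature = 0.4, vpd = 0.15,
    solar_radiation = 0.15, population_density = 0.5,
    nighttime_light = 0.4, elevation = -0.4, lai = 0.25, npp = 0.25)
}

rep_named <- function(x, species) {
  if (is.null(names(x))) {
    stats::setNames(rep_len(x, length(species)), species)
  } else {
    if (!all(species %in% names(x)))
      stop("missing species in parameter vector: ",
           paste(setdiff(species, names(x)), collapse = ", "))
    x[species]
  }
}

#' Aggregate latent truth surfaces to a district census table
#'
#' Produces the district x year x species headcount table that the
#' pipeline later disaggregates: headcount is the exact sum of density x
#' pixel area over the district's pixels, and the district area is pixel
#' count x pixel area, so census and raster share one area definition.
#'
#' @param landscape Landscape with truth surfaces.
#' @param round_counts Round headcounts to integers (default `FALSE`,
#'   exact real-valued counts).
#' @return A data frame (`district_id, year, species, headcount, area_km2`).
#' @export
aggregate_truth_to_census <- function(landscape, round_counts = FALSE) {
  if (is.null(landscape$truth)) stop("landscape has no truth surfaces")
  zone <- landscape$zone
  a <- cell_area(landscape$geometry)
  ids <- sort(unique(zone[!is.na(zone)]))
  areas <- tabulate(zone, nbins = max(ids))[ids] * a
  rows <- list()
  for (sp in names(landscape$truth)) {
    for (yr in names(landscape$truth[[sp]])) {
      m <- landscape$truth[[sp]][[yr]]
      totals <- rowsum(as.vector(m[!is.na(zone)]) * a,
                       group = zone[!is.na(zone)])
      heads <- totals[match(ids, as.integer(rownames(totals))), 1]
      if (round_counts) heads <- round(heads)
      rows[[length(rows) + 1L]] <- data.frame(
        district_id = ids, year = as.integer(yr), species = sp,
        headcount = heads, area_km2 = areas
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference synthetic landscape
#'
#' The package's reference configuration: 24 districts on a 200 x 200 grid
#' of 1 km cells, 12 settlements per district, 20 annual predictor stacks
#' (2000-2019) and latent truth surfaces for small ruminants and horses
#' with a +2%/yr injected trend.
#'
#' @param seed Integer seed (default 42).
#' @param years Years to simulate.
#' @param n_districts,n_rows,n_cols,n_settlements Landscape dimensions.
#' @param ... Passed on to [generate_truth()].
#' @return A fully populated `landscape`.
#' @export
default_landscape <- function(seed = 42, years = 2000:2019,
                              n_districts = 24, n_rows = 200, n_cols = 200,
                              n_settlements = 12, ...) {
  geom <- grid_geometry(n_rows, n_cols, cell_size = 1)
  ls <- generate_landscape(n_districts, geom, n_settlements, seed = seed)
  ls <- generate_predictors(ls, years, seed = sub_seed(seed, 1L))
  generate_truth(ls, years, seed = sub_seed(seed, 2L), ...)
}
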