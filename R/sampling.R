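#' Select the most populous settlements of each district
#'
#' Pseudo-sampling design: each district contributes its `k` largest
#' settlements by human population (all of them if fewer than `k` exist).
#' Population ties are broken by ascending `settlement_id` so the selection
#' is deterministic.
#'
#' @param settlements Settlement table (`settlement_id, x, y, population,
#'   district_id`).
#' @param k Settlements per district (>= 1).
#' @param district_ids Optional full set of district ids; districts with no
#'   settlements trigger a warning and contribute no points.
#' @return Subset of `settlements`.
#' @export
select_top_settlements <- function(settlements, k, district_ids = NULL) {
  if (k < 1) stop("k must be >= 1")
  if (!is.null(district_ids)) {
    empty <- setdiff(district_ids, settlements$district_id)
    if (length(empty))
      warning("district(s) without settlements contribute no samples: ",
              paste(empty, collapse = ", "))
  }
  picked <- lapply(split(settlements, settlements$district_id), function(g) {
    g <- g[order(-g$population, g$settlement_id), ]
    g[seq_len(min(k, nrow(g))), ]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

#' Extract covariate features at settlements or within buffers
#'
#' With `buffer_km = 0` each settlement gets the value of the pixel that
#' contains it; with a positive radius it gets the mean over all valid
#' pixels whose centers lie within the circular buffer. Buffers are
#' physical discs representing daily livestock movement range and are not
#' clipped at district borders.
#'
#' @param landscape Landscape with predictors for `year`.
#' @param selected Settlement table (typically [select_top_settlements()]).
#' @param year Year whose predictor stack to use.
#' @param buffer_km One of 0, 2, 5, 10 (km).
#' @return A `sample_set` data frame: ids, year, `buffer_km`, one column
#'   per covariate, and an empty `response` column.
#' @export
extract_features <- function(landscape, selected, year, buffer_km = 0) {
  if (!buffer_km %in% c(0, 2, 5, 10))
    stop("buffer_km must be one of 0, 2, 5, 10")
  yr <- as.character(year)
  if (is.null(landscape$predictors[[yr]]))
    stop("no predictors for year ", year)
  geom <- landscape$geometry
  layers <- landscape$predictors[[yr]]
  px <- point_to_pixel(geom, selected$x, selected$y)
  if (anyNA(px$row)) stop("settlement(s) outside the grid")

  feats <- matrix(NA_real_, nrow(selected), length(covariate_names()),
                  dimnames = list(NULL, covariate_names()))
  if (buffer_km == 0) {
    idx <- cbind(px$row, px$col)
    for (nm in covariate_names()) feats[, nm] <- layers[[nm]][idx]
  } else {
    cc <- cell_centers(geom)
    r_px <- ceiling(buffer_km / geom$cell_size)
    for (s in seq_len(nrow(selected))) {
      rows <- max(1, px$row[s] - r_px):min(geom$n_rows, px$row[s] + r_px)
      cols <- max(1, px$col[s] - r_px):min(geom$n_cols, px$col[s] + r_px)
      d2 <- outer((cc$y[rows] - selected$y[s])^2,
                  (cc$x[cols] - selected$x[s])^2, "+")
      inside <- d2 <= buffer_km^2
      if (!any(inside))
        stop("buffer holds no valid pixels for settlement ",
             selected$settlement_id[s])
      for (nm in covariate_names()) {
        v <- layers[[nm]][rows, cols, drop = FALSE][inside]
        v <- v[is.finite(v)]
        if (!length(v))
          stop("buffer holds no valid pixels for settlement ",
               selected$settlement_id[s])
        feats[s, nm] <- mean(v)
      }
    }
  }
  out <- data.frame(
    sample_id = seq_len(nrow(selected)),
    settlement_id = selected$settlement_id,
    district_id = selected$district_id,
    year = year, species = NA_character_, buffer_km = buffer_km,
    feats, response = NA_real_
  )
  class(out) <- c("sample_set", "data.frame")
  out
}

#' Attach the district census density as the sample response
#'
#' Every sample of a district carries the district's density for its year
#' and species: the design has no sub-district response information, so
#' within-district response variance is zero by construction.
#'
#' @param samples A `sample_set`.
#' @param densities Output of [compute_density()].
#' @param species Species to attach.
#' @return The samples with `response` and `species` filled.
#' @export
attach_response <- function(samples, densities, species) {
  sub <- densities[densities$species == species, ]
  key <- paste(samples$district_id, samples$year)
  hit <- match(key, paste(sub$district_id, sub$year))
  if (anyNA(hit)) {
    miss <- unique(key[is.na(hit)])
    stop("no census density for (district, year): ",
         paste(miss, collapse = "; "))
  }
  samples$response <- sub$density[hit]
  samples$species <- species
  samples
}

#' Split samples into training and test sets
#'
#' `grouping = "point"` assigns rows uniformly at random; `grouping =
#' "district"` keeps whole districts on one side, which avoids the leakage
#' caused by identical responses at a district's points. The split is
#' disjoint, exhaustive, and deterministic for a fixed seed, with
#' `round(train_fraction * n)` training rows (district grouping gets as
#' close as its blocks allow).
#'
#' @param samples A `sample_set` (>= 10 rows).
#' @param train_fraction Fraction in (0, 1), typically 0.7/0.8/0.9.
#' @param seed Integer seed.
#' @param grouping `"point"` (default) or `"district"`.
#' @return List with `train` and `test` sample sets.
#' @export
split_train_test <- function(samples, train_fraction, seed,
                             grouping = c("point", "district")) {
  grouping <- match.arg(grouping)
  n <- nrow(samples)
  if (n < 10) stop("need at least 10 samples to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n_train <- round(train_fraction * n)
  with_seed(seed, {
    if (grouping == "point") {
      idx <- sample.int(n, n_train)
    } else {
      ds <- unique(samples$district_id)
      if (length(ds) < 2) stop("district grouping needs >= 2 districts")
      ds <- sample(ds)
      sizes <- cumsum(vapply(ds, function(d) sum(samples$district_id == d),
                             integer(1)))
      cut <- which.min(abs(sizes - n_train))
      idx <- which(samples$district_id %in% ds[seq_len(cut)])
    }
    list(train = samples[idx, , drop = FALSE],
         test = samples[-idx, , drop = FALSE])
  })
}

#' Build a complete sample set for one year and species
#'
#' Convenience wrapper: top-`k` settlement selection, feature extraction at
#' the chosen buffer, and response attachment from the census densities.
#'
#' @param landscape Landscape with predictors.
#' @param densities Output of [compute_density()].
#' @param year,species Slice to sample.
#' @param k Settlements per district.
#' @param buffer_km Buffer radius (0, 2, 5, 10 km).
#' @return A `sample_set` ready for [density_rf()].
#' @export
build_sample_set <- function(landscape, densities, year, species,
                             k = 10, buffer_km = 10) {
  sel <- select_top_settlements(landscape$settlements, k,
                                district_ids = sort(unique(
                                  landscape$zone[!is.na(landscape$zone)])))
  samples <- extract_features(landscape, sel, year, buffer_km)
  attach_response(samples, densities, species)
}
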