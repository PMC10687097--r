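test_that("zone raster partitions the grid into the requested districts", {
  geom <- grid_geometry(10, 10)
  ls <- generate_landscape(2, geom, n_settlements_per_district = 2, seed = 7)
  expect_false(anyNA(ls$zone))
  expect_setequal(unique(as.vector(ls$zone)), c(1L, 2L))
  # district areas sum to the full grid
  expect_equal(sum(district_areas(ls$zone, geom)), 100)

  ls2 <- generate_landscape(2, geom, n_settlements_per_district = 2, seed = 7)
  expect_identical(ls, ls2)
})

test_that("settlement counts, placement and populations follow the design", {
  geom <- grid_geometry(80, 80)
  ls <- generate_landscape(10, geom, n_settlements_per_district = 12,
                           seed = 3)
  st <- ls$settlements
  expect_equal(nrow(st), 120)
  expect_equal(as.integer(table(st$district_id)), rep(12L, 10))
  expect_false(anyDuplicated(st$settlement_id) > 0)
  expect_true(all(st$population >= 1))
  # every settlement sits inside its own district's pixels
  px <- point_to_pixel(geom, st$x, st$y)
  expect_equal(ls$zone[cbind(px$row, px$col)], st$district_id)
})

test_that("a geometry too small for the districts is rejected", {
  expect_error(generate_landscape(30, grid_geometry(5, 5), 2, seed = 1),
               "too small")
  expect_error(generate_landscape(1, grid_geometry(10, 10), 2, seed = 1),
               ">= 2")
})

test_that("predictor stacks carry the 13 named covariates with static and dynamic layers", {
  ls <- test_landscape()
  yrs <- names(ls$predictors)
  expect_named(ls$predictors[[1]], covariate_names())
  # static layers identical across years, dynamic layers redrawn
  expect_identical(ls$predictors[[yrs[1]]]$elevation,
                   ls$predictors[[yrs[2]]]$elevation)
  expect_identical(ls$predictors[[yrs[1]]]$dist_water,
                   ls$predictors[[yrs[3]]]$dist_water)
  expect_false(identical(ls$predictors[[yrs[1]]]$precipitation,
                         ls$predictors[[yrs[2]]]$precipitation))
  expect_true(all(vapply(ls$predictors[[1]], function(m) all(is.finite(m)),
                         logical(1))))
})

test_that("distance to settlement vanishes at the settlement's own pixel", {
  ls <- test_landscape()
  px <- point_to_pixel(ls$geometry, ls$settlements$x, ls$settlements$y)
  d <- ls$predictors[[1]]$dist_settlement[cbind(px$row, px$col)]
  expect_equal(d, rep(0, nrow(ls$settlements)))
})

test_that("euclidean distance map matches the 3-4-5 triangle and zero at sources", {
  geom <- grid_geometry(10, 10)
  mask <- matrix(FALSE, 10, 10); mask[1, 1] <- TRUE
  d <- euclidean_distance_map(geom, mask = mask)
  expect_equal(d[1, 1], 0)
  expect_equal(d[4, 5], 5)   # 3 rows, 4 cols away
  expect_equal(d[5, 4], 5)
  expect_error(euclidean_distance_map(geom, mask = matrix(FALSE, 10, 10)),
               "empty")
})

test_that("euclidean distance map equals brute force on random grids", {
  set.seed(11)
  for (trial in 1:12) {
    nr <- sample(5:50, 1); nc <- sample(5:50, 1)
    cs <- sample(c(0.5, 1, 2), 1)
    geom <- grid_geometry(nr, nc, cell_size = cs)
    mask <- matrix(runif(nr * nc) < 0.03, nr, nc)
    if (!any(mask)) mask[sample(nr, 1), sample(nc, 1)] <- TRUE
    expect_equal(euclidean_distance_map(geom, mask = mask),
                 brute_force_distance(geom, mask), tolerance = 1e-12)
  }
})

test_that("truth surfaces honour degenerate noise and trend settings", {
  ls <- test_landscape()
  # no noise, no trend: all years identical
  l0 <- generate_truth(ls, 2014:2016, trend_slope = 0, noise_sd = 0,
                       seed = 5)
  tt <- l0$truth$small_ruminant
  expect_equal(as.vector(tt[["2014"]]), as.vector(tt[["2016"]]))
  # noiseless linear trend: per-pixel OLS slope is exactly slope * D0
  l1 <- generate_truth(ls, 2014:2016, trend_slope = 0.05, noise_sd = 0,
                       seed = 5)
  st <- l1$truth$small_ruminant
  d0 <- st[["2014"]]
  y <- cbind(as.vector(st[["2014"]]), as.vector(st[["2015"]]),
             as.vector(st[["2016"]]))
  ols <- apply(y, 1, function(v) coef(lm(v ~ I(0:2)))[2])
  expect_equal(ols, as.vector(d0) * 0.05, tolerance = 1e-9,
               ignore_attr = TRUE)
  # beta = 0 and huge decay length: spatially constant base density
  l2 <- generate_truth(ls, 2015, beta = numeric(0), noise_sd = 0,
                       decay_length = 1e9, background = 0, seed = 5)
  v <- as.vector(l2$truth$small_ruminant[["2015"]])
  expect_lt(diff(range(v)) / mean(v), 1e-6)
  expect_error(generate_truth(ls, 2015, decay_length = -1), "decay_length")
})

test_that("aggregating truth to census matches masked sums and areas", {
  ls <- test_landscape()
  cen <- aggregate_truth_to_census(ls)
  a <- cell_area(ls$geometry)
  for (d in unique(cen$district_id)) {
    m <- ls$truth$small_ruminant[["2015"]]
    expect_equal(
      cen$headcount[cen$district_id == d & cen$year == 2015 &
                      cen$species == "small_ruminant"],
      sum(m[ls$zone == d]) * a)
  }
  expect_equal(unique(cen$area_km2[cen$district_id == 1]),
               unname(district_areas(ls$zone, ls$geometry)["1"]))
  # uniform truth: headcount = density * area
  lu <- ls
  lu$truth <- list(small_ruminant = list(
    "2015" = matrix(2, ls$geometry$n_rows, ls$geometry$n_cols)))
  cu <- aggregate_truth_to_census(lu)
  expect_equal(cu$headcount, 2 * cu$area_km2)
})

test_that("rasterize then re-aggregate is the identity on census densities", {
  ls <- test_landscape()
  cen <- aggregate_truth_to_census(ls)
  dens <- compute_density(cen)
  r <- rasterize_density(dens, ls$zone, ls$geometry, 2015, "horse")
  # re-aggregate: per-district totals must reproduce the headcounts
  tot <- zonal_total(r, ls$zone, ls$geometry)
  sub <- cen[cen$year == 2015 & cen$species == "horse", ]
  expect_equal(unname(tot[as.character(sub$district_id)]), sub$headcount,
               tolerance = 1e-9)
})
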