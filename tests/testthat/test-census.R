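test_that("density is headcount over area, with zero-area rejection", {
  cen <- data.frame(district_id = 1:2, year = 2000,
                    species = "small_ruminant",
                    headcount = c(20, 0), area_km2 = c(10, 7))
  d <- compute_density(cen)
  expect_equal(d$density, c(2, 0))

  set.seed(4)
  big <- expand.grid(district_id = 1:200, year = 2000:2019,
                     species = "horse", stringsAsFactors = FALSE)
  big$headcount <- runif(nrow(big), 0, 1e5)
  big$area_km2 <- rep(runif(200, 100, 5000), times = 20)
  expect_equal(compute_density(big)$density, big$headcount / big$area_km2)

  cen$area_km2[2] <- 0
  expect_error(compute_density(cen), "district")
})

test_that("interior census gaps are filled linearly and flagged", {
  cen <- data.frame(district_id = 1, year = c(1999, 2001),
                    species = "small_ruminant",
                    headcount = c(100, 200), area_km2 = 50)
  out <- interpolate_missing_years(cen, 1999:2001)
  expect_equal(out$headcount[out$year == 2000], 150)
  expect_true(out$interpolated[out$year == 2000])
  expect_false(any(out$interpolated[out$year != 2000]))

  cen2 <- data.frame(district_id = 1, year = c(1999, 2002),
                     species = "horse",
                     headcount = c(90, 180), area_km2 = 10)
  out2 <- interpolate_missing_years(cen2, 1999:2002)
  expect_equal(out2$headcount[order(out2$year)], c(90, 120, 150, 180))
})

test_that("interpolation is exact on affine series and refuses extrapolation", {
  set.seed(9)
  for (trial in 1:5) {
    a <- runif(1, 50, 500); b <- runif(1, -5, 20)
    years <- 2000:2010
    cen <- data.frame(district_id = 1, year = years, species = "horse",
                      headcount = a + b * (years - 2000), area_km2 = 100)
    drop <- sample(2:10, 4)
    out <- interpolate_missing_years(cen[-drop, ], years)
    out <- out[order(out$year), ]
    expect_equal(out$headcount, a + b * (years - 2000), tolerance = 1e-9)
  }
  cen <- data.frame(district_id = 1, year = 2001:2003, species = "horse",
                    headcount = 1:3, area_km2 = 1)
  expect_error(interpolate_missing_years(cen, 2000:2003), "flanking")
  # no gaps: unchanged apart from the flag column
  full <- interpolate_missing_years(cen, 2001:2003)
  expect_equal(full$headcount, cen$headcount)
  expect_false(any(full$interpolated))
})

test_that("district merges sum heads and areas and conserve totals", {
  cen <- data.frame(district_id = c(1, 2), year = 2000, species = "horse",
                    headcount = c(10, 30), area_km2 = c(5, 15))
  out <- merge_districts(cen, data.frame(old_id = c(1, 2), new_id = 9))
  expect_equal(out$headcount, 40)
  expect_equal(out$area_km2, 20)
  expect_equal(compute_density(out)$density, 2)

  # identity map leaves the table unchanged
  idm <- merge_districts(cen, data.frame(old_id = integer(0),
                                         new_id = integer(0)))
  expect_equal(idm[order(idm$district_id), c("district_id", "headcount")],
               cen[, c("district_id", "headcount")], ignore_attr = TRUE)

  # random table vs aggregate-sum oracle; totals conserved
  set.seed(2)
  big <- expand.grid(district_id = 1:10, year = 2000:2002,
                     species = "small_ruminant", stringsAsFactors = FALSE)
  big$headcount <- runif(nrow(big), 0, 1000)
  big$area_km2 <- rep(runif(10, 10, 100), times = 3)
  map <- data.frame(old_id = c(1, 2, 5, 6, 7), new_id = c(101, 101, 105, 105, 105))
  merged <- merge_districts(big, map)
  expect_equal(sum(merged$headcount), sum(big$headcount))
  expect_equal(sum(merged$area_km2[merged$year == 2000]),
               sum(big$area_km2[big$year == 2000]))
  oracle <- aggregate(headcount ~ year,
                      data = big[big$district_id %in% c(1, 2), ], FUN = sum)
  got <- merged[merged$district_id == 101, ]
  expect_equal(got$headcount[order(got$year)],
               oracle$headcount[order(oracle$year)])
})

test_that("merging districts with mismatched records is an error", {
  cen <- data.frame(district_id = c(1, 1, 2), year = c(2000, 2001, 2000),
                    species = "horse", headcount = 1:3, area_km2 = 1)
  expect_error(merge_districts(cen, data.frame(old_id = 1:2, new_id = 9)),
               "disagree")
})

test_that("rasterized densities are piecewise constant and invertible", {
  geom <- grid_geometry(8, 8)
  zone <- matrix(rep(c(1L, 2L), each = 32), 8, 8)
  dens <- data.frame(district_id = 1:2, year = 2000, species = "horse",
                     density = c(2, 5))
  r <- rasterize_density(dens, zone, geom, 2000, "horse")
  expect_setequal(unique(r[zone == 1]), 2)
  expect_setequal(unique(r[zone == 2]), 5)
  # zonal means recover the input densities exactly
  expect_equal(unname(zonal_total(r, zone, geom) /
                        district_areas(zone, geom)), c(2, 5))
  expect_error(rasterize_density(dens[1, ], zone, geom, 2000, "horse"),
               "district")
})
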