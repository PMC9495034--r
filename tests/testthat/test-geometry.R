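test_that("slope of a plane equals 100 * gradient norm everywhere", {
  flat <- plane_raster(0, 0, c = 42)
  expect_equal(unname(slope_percent(flat)$values),
               matrix(0, 8, 10))

  expect_equal(unname(slope_percent(plane_raster(0.1, 0))$values),
               matrix(10, 8, 10))

  # ||(0.3, 0.4)|| = 0.5; for a plane one-sided border differences are exact
  # too, so the analytic value holds at every cell
  expect_equal(unname(slope_percent(plane_raster(0.3, 0.4))$values),
               matrix(50, 8, 10))

  # brute-force central-difference oracle on a random surface (interior)
  set.seed(42)
  g <- grid_spec(0, 0, 2, 6, 7)
  z <- matrix(rnorm(42), 6, 7)
  r <- raster_layer(g, z)
  sl <- slope_percent(r)$values
  for (i in 2:5) for (j in 2:6) {
    gx <- (z[i, j + 1] - z[i, j - 1]) / 4
    gy <- (z[i - 1, j] - z[i + 1, j]) / 4
    expect_equal(sl[i, j], 100 * sqrt(gx^2 + gy^2))
  }

  expect_error(slope_percent(raster_layer(grid_spec(0, 0, 1, 2, 2),
                                          matrix(0, 2, 2))),
               "3x3")
})

test_that("insolation classes follow downhill azimuth with a flat cutoff", {
  flat <- plane_raster(0, 0)
  cls <- insolation_class(flat, slope_percent(flat))
  expect_true(all(cls$categories[cls$values] == "Flat"))

  # z = 0.2 * y rises northward: downhill azimuth 180 deg -> South
  north_rise <- plane_raster(0, 0.2)
  cls <- insolation_class(north_rise, slope_percent(north_rise))
  expect_true(all(cls$categories[cls$values] == "South"))

  # slope 5% < 10% threshold: Flat despite a nonzero gradient
  gentle <- plane_raster(0.05, 0)
  cls <- insolation_class(gentle, slope_percent(gentle))
  expect_true(all(cls$categories[cls$values] == "Flat"))

  # slope exactly at the threshold gets an aspect class (falls westward);
  # the slope layer is constructed with exact 10s to pin the boundary rule
  west_rise <- plane_raster(0.2, 0)
  exact10 <- raster_layer(west_rise$grid, matrix(10, 8, 10))
  cls <- insolation_class(west_rise, exact10)
  expect_true(all(cls$categories[cls$values] == "West"))

  other <- plane_raster(0, 0, n_rows = 4, n_cols = 4)
  expect_error(insolation_class(north_rise, slope_percent(other)), "grid")
})

test_that("distance to water matches the per-cell brute force exactly", {
  g <- grid_spec(0, 0, 10, 4, 5)
  # cell centroid of row 4 (south), col 4 is (35, 5); water there -> 0
  d <- distance_to_water(g, c(35, 5))
  expect_equal(d$values[4, 4], 0)

  # 3-4-5 triangle: centroid of row 1, col 3 of this grid is (25, 35);
  # water at (-5, -5) puts it 30 m east and 40 m north -> 50 m
  g2 <- grid_spec(0, 0, 10, 4, 4)
  d2 <- distance_to_water(g2, c(-5, -5))
  expect_equal(d2$values[1, 3], 50)

  set.seed(7)
  g3 <- grid_spec(runif(1, -50, 50), runif(1, -50, 50), 7, 6, 9)
  wp <- c(runif(1, -100, 100), runif(1, -100, 100))
  d4 <- distance_to_water(g3, wp)
  ctr <- cell_centers(g3)
  for (i in seq_len(6)) for (j in seq_len(9))
    expect_identical(d4$values[i, j],
                     sqrt((ctr$x[j] - wp[1])^2 + (ctr$y[i] - wp[2])^2))
})

test_that("plot summaries average the disc and respect categorical layers", {
  g <- grid_spec(0, 0, 10, 6, 6)
  const <- raster_layer(g, matrix(3.7, 6, 6))
  expect_equal(plot_summary(const, 30, 30, radius = 5), 3.7)

  # plot entirely inside one cell
  set.seed(1)
  vals <- matrix(runif(36, 0, 100), 6, 6)
  r <- raster_layer(g, vals)
  expect_equal(plot_summary(r, 15, 15, radius = 3), vals[5, 2])

  # disc straddling two big cells valued 0 and 10 symmetrically -> 5
  g2 <- grid_spec(0, 0, 50, 1, 2)
  r2 <- raster_layer(g2, matrix(c(0, 10), 1, 2))
  expect_equal(plot_summary(r2, 50, 25, radius = 5), 5)

  # categorical majority
  cat_r <- raster_layer(g, matrix(c(1, 2)[1 + (col(vals) > 3)], 6, 6),
                        categories = c("oak", "grass"))
  expect_equal(plot_summary(cat_r, 15, 15, radius = 4), "oak")

  expect_error(plot_summary(r, 1000, 1000, radius = 5), "intersect")
})

test_that("factor binning is a half-open partition matching the field sets", {
  expect_equal(bin_factor(4.9, factor_bins("slope")), "<5%")
  expect_equal(bin_factor(c(5, 10, 20, 19.99), factor_bins("slope")),
               c("5-10%", "10-20%", ">20%", "10-20%"))
  expect_equal(bin_factor(100, factor_bins("distance_to_water")),
               "100-200 m")
  expect_equal(bin_factor(0, factor_bins("canopy")), "0%")
  expect_equal(bin_factor(c(0.01, 25, 50), factor_bins("canopy")),
               c("0-25%", "25-50%", ">50%"))
  expect_error(bin_factor(NaN, factor_bins("slope")), "finite")
  expect_error(bin_factor(NA_real_, factor_bins("canopy")), "finite")

  # partition property: every finite value lands in exactly one category
  set.seed(3)
  for (fac in c("slope", "canopy", "distance_to_water")) {
    b <- factor_bins(fac)
    v <- abs(rnorm(500, 50, 60))
    lab <- bin_factor(v, b)
    expect_true(all(lab %in% b$labels))
    expect_equal(length(lab), 500)
  }
})

test_that("weekly weather aggregation means and sums align to census weeks", {
  d <- data.frame(date = as.Date("2021-02-15") + 0:6,
                  tavg = 1:7, tmax = 11:17, tmin = -3:3,
                  rain = c(0, 0, 5, 0, 0, 2, 0),
                  rh = rep(60, 7), radiation = rep(150, 7), wind = rep(2, 7))
  w <- weekly_weather(d, "2021-02-15")
  expect_equal(nrow(w), 1)
  expect_equal(w$tavg, 4)
  expect_equal(w$rain, 7)
  expect_true(w$complete)

  # identical days replicated over a week: means unchanged, rain summed
  d2 <- d
  d2[, c("tavg", "tmax", "tmin", "rain")] <- list(5, 15, 1, 3)
  w2 <- weekly_weather(d2, "2021-02-15")
  expect_equal(w2$tavg, 5)
  expect_equal(w2$rain, 21)

  # missing days flagged
  w3 <- weekly_weather(d[1:5, ], "2021-02-15")
  expect_false(w3$complete)
  expect_equal(w3$n_days, 5L)
})

test_that("weekly NDVI averages scenes and carries gap weeks forward", {
  px <- 4
  expect_error(weekly_ndvi(as.Date(character()),
                           matrix(0, 0, px), "2021-02-15", 3), "no NDVI")
  dates <- as.Date("2021-02-15") + c(1, 4, 15)
  vals <- rbind(rep(0.2, px), rep(0.4, px), rep(0.5, px))
  w <- weekly_ndvi(dates, vals, "2021-02-15", 3)
  expect_equal(w$values[1, ], rep(0.3, px))   # mean of two scenes
  expect_equal(w$values[3, ], rep(0.5, px))   # single scene
  expect_equal(w$values[2, ], rep(0.3, px))   # gap: carried forward
  expect_equal(w$filled, c(FALSE, TRUE, FALSE))
})

test_that("block aggregation is the exact 2x2 child mean", {
  g <- grid_spec(0, 0, 5, 4, 4)
  v <- matrix(1:16, 4, 4)
  agg <- block_aggregate(raster_layer(g, v), 2)
  expect_equal(agg$grid$cell_size, 10)
  expect_equal(agg$values[1, 1], mean(v[1:2, 1:2]))
  expect_equal(agg$values[2, 2], mean(v[3:4, 3:4]))
  expect_error(block_aggregate(raster_layer(grid_spec(0, 0, 5, 3, 4),
                                            matrix(0, 3, 4)), 2),
               "divisible")
})

test_that("point-in-polygon includes the boundary and paddock validates", {
  poly <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_true(point_in_polygon(5, 5, poly))
  expect_true(point_in_polygon(0, 5, poly))    # on an edge
  expect_true(point_in_polygon(10, 10, poly))  # on a vertex
  expect_false(point_in_polygon(10.01, 5, poly))
  expect_false(point_in_polygon(-1e-6, 5, poly))

  expect_error(paddock(poly, c(50, 50)), "water")
  p <- paddock(poly, c(5, 5))
  expect_equal(p$area, 100)
})
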