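test_that("thresholds split 1000 distinct speeds at exactly 57.5%", {
  thr <- fit_thresholds(1:1000)
  lab <- classify_behavior(1:1000, thr)
  expect_equal(sum(lab == "resting"), 575)
  expect_equal(sum(lab == "walking"), 25)
  expect_equal(sum(lab == "grazing"), 400)

  expect_error(fit_thresholds(1:99), "at least 100")
  expect_error(classify_behavior(-1, thr), "negative")

  # percentile monotonicity: adding a huge speed cannot decrease t2
  thr2 <- fit_thresholds(c(1:1000, 1e6))
  expect_gte(thr2$t2, thr$t2)
})

test_that("classification boundaries give the upper class the tie", {
  thr <- fit_thresholds(1:1000)
  expect_equal(classify_behavior(0, thr), "resting")
  expect_equal(classify_behavior(thr$t1, thr), "grazing")
  expect_equal(classify_behavior(thr$t2, thr), "walking")

  # degenerate all-equal pool: t1 = t2, everything >= t2 -> walking
  thr3 <- fit_thresholds(rep(2.5, 200))
  expect_equal(thr3$t1, thr3$t2)
  expect_true(all(classify_behavior(rep(2.5, 10), thr3) == "walking"))
})

test_that("pooled label fractions track the percentile construction", {
  set.seed(31)
  speeds <- rlnorm(5000, 0, 1)
  thr <- fit_thresholds(speeds)
  lab <- classify_behavior(speeds, thr)
  frac <- table(lab) / length(lab)
  expect_equal(unname(frac[["resting"]]), 0.575, tolerance = 1e-3)
  expect_equal(unname(frac[["grazing"]]), 0.400, tolerance = 1e-3)
  expect_equal(unname(frac[["walking"]]), 0.025, tolerance = 1e-3)
})

test_that("activity profiles average segment lengths per slot", {
  segs <- data.frame(slot = rep(1:47, 2), length_m = 10,
                     device_id = "A")
  prof <- activity_profile(segs)
  expect_equal(nrow(prof), 48)
  expect_true(all(prof$mean_length_m[prof$slot <= 47] == 10))
  expect_equal(prof$n[prof$slot == 48], 0)

  # one animal, one day: the profile is that day's lengths mapped to slots
  set.seed(5)
  lens <- runif(47, 0, 100)
  one <- data.frame(slot = 1:47, length_m = lens, device_id = "A")
  prof1 <- activity_profile(one)
  expect_equal(prof1$mean_length_m[prof1$slot <= 47], lens)

  # two groups produce per-slot Welch p-values
  two <- rbind(data.frame(slot = rep(1:48, each = 5),
                          length_m = rnorm(240, 10, 1), g = "winter"),
               data.frame(slot = rep(1:48, each = 5),
                          length_m = rnorm(240, 60, 1), g = "summer"))
  prof2 <- activity_profile(two, group = two$g)
  expect_true(all(prof2$p_value < 0.01))
})

test_that("synthetic diurnal schedule peaks during grazing bouts", {
  s <- small_study()
  pp <- preprocess_fixes(s$fixes[, c("device_id", "timestamp", "x", "y")],
                         s$pad$paddock)
  prof <- activity_profile(pp$segments)
  hrs <- (prof$slot - 1) / 2
  bout <- (hrs >= 6 & hrs < 10) | (hrs >= 17 & hrs < 21)
  rest <- (hrs >= 0 & hrs < 5) | (hrs >= 11 & hrs < 16)
  expect_gt(mean(prof$mean_length_m[bout], na.rm = TRUE),
            2 * mean(prof$mean_length_m[rest], na.rm = TRUE))
})

test_that("herd dispersal is the distance to the positional centroid", {
  ts <- as.POSIXct("2021-02-15 10:00:00", tz = "UTC")
  same <- data.frame(device_id = c("A", "B", "C"), timestamp = ts,
                     x = 5, y = 5)
  d <- herd_dispersal(same)
  expect_equal(d$records$distance_m, c(0, 0, 0))

  two <- data.frame(device_id = c("A", "B"), timestamp = ts,
                    x = c(0, 2), y = 0)
  d2 <- herd_dispersal(two)
  expect_equal(d2$records$distance_m, c(1, 1))
  expect_equal(d2$records$herd_mean_m, c(1, 1))

  # four animals on unit-square corners: all sqrt(0.5) from the center
  sq <- data.frame(device_id = c("A", "B", "C", "D"), timestamp = ts,
                   x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  d3 <- herd_dispersal(sq)
  expect_equal(d3$records$distance_m, rep(sqrt(0.5), 4))

  # timestamps missing an animal are skipped and logged
  mix <- rbind(sq, data.frame(device_id = "A", timestamp = ts + 1800,
                              x = 0, y = 0))
  d4 <- herd_dispersal(mix, devices = c("A", "B", "C", "D"))
  expect_equal(length(d4$skipped), 1)
  expect_equal(nrow(d4$records), 4)
})

test_that("dispersal is invariant under rigid motions", {
  set.seed(8)
  ts <- as.POSIXct("2021-02-15 10:00:00", tz = "UTC")
  pts <- data.frame(device_id = LETTERS[1:5], timestamp = ts,
                    x = runif(5, 0, 100), y = runif(5, 0, 100))
  base <- herd_dispersal(pts)$records$distance_m
  for (k in 1:5) {
    th <- runif(1, 0, 2 * pi); dx <- runif(1, -50, 50)
    dy <- runif(1, -50, 50)
    rot <- pts
    rot$x <- cos(th) * pts$x - sin(th) * pts$y + dx
    rot$y <- sin(th) * pts$x + cos(th) * pts$y + dy
    expect_equal(herd_dispersal(rot)$records$distance_m, base)
  }
})

test_that("the herd bunches to rest and spreads to graze", {
  s <- small_study()
  pp <- preprocess_fixes(s$fixes[, c("device_id", "timestamp", "x", "y")],
                         s$pad$paddock)
  d <- herd_dispersal(pp$fixes)
  hr <- as.integer(format(d$records$timestamp, "%H"))
  graz <- hr %in% c(6:9, 17:20)
  rest <- hr %in% c(0:5, 11:16)
  expect_gt(mean(d$records$herd_mean_m[graz]),
            mean(d$records$herd_mean_m[rest]))
})

test_that("seasons map dates to the meteorological calendar", {
  expect_equal(season_of(as.Date(c("2021-02-15", "2021-04-01",
                                   "2021-07-02", "2021-10-01",
                                   "2021-12-25"))),
               c("winter", "spring", "summer", "autumn", "winter"))
})
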