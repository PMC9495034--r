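# Seeded generator for a complete synthetic grazing study: paddock and
# environment layers, correlated random-walk cattle trajectories with a
# diurnal behavior schedule, GPS observation with dropout and error
# injection, daily weather, and presence-driven dung deposition with a
# weekly plot census. Ground truth is retained for recovery tests.

#' Configuration of the synthetic study
#'
#' Defaults emulate the study design the pipeline targets: 7 collared animals,
#' 19 weekly dung censuses starting 15 Feb 2021, a 23.1 ha paddock (660 x 350
#' m) with a single water trough at the southeastern end, 90 circular sampling
#' plots of 5 m radius roughly 50 m apart, 30-min GPS fixes with dropout, and
#' dung deposition that is highest while resting, decays with distance to
#' water and is reduced under tree canopy.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_animals,n_weeks,fix_interval,step_min Herd size, study length
#'   (weeks), GPS fix interval (min) and trajectory resolution (min).
#' @param paddock_width,paddock_height Fence rectangle (m); defaults give
#'   exactly 23.1 ha.
#' @param dem_cell,env_cell DEM and environment-layer cell sizes (m).
#' @param n_plots,plot_radius,plot_min_separation Sampling-plot layout (m).
#' @param start_date First census day (week 1, ISO date).
#' @param dropout_prob Per-fix probability that no fix is transmitted.
#' @param gps_error_prob Per-fix probability of a gross positional error
#'   placing the fix outside the fence.
#' @param timestamp_jitter_min Uniform timestamp jitter (+/- min) mimicking
#'   unsynchronized devices.
#' @param speeds Named mean speeds (m/min) for resting/grazing/walking;
#'   must be increasing.
#' @param turn_sd Turning-angle SD (radians) per state.
#' @param cohesion Per-state heading weight toward the herd centroid
#'   (resting > walking > grazing: cattle bunch up to rest and spread out to
#'   graze).
#' @param speed_sdlog Lognormal SD of per-step speed multipliers.
#' @param grazing_bouts List of `c(start_hour, end_hour)` diurnal grazing
#'   bouts (two by default: morning and afternoon/evening).
#' @param state_probs_bout,state_probs_rest Resting/grazing/walking state
#'   probabilities per 30-min interval inside and outside grazing bouts.
#' @param water_attract_max,water_temp_mid,water_temp_scale Water-attraction
#'   heading weight: a logistic ramp of weekly mean temperature,
#'   `w = max * plogis((T - mid)/scale)`, spanning roughly 15 to 22 degrees C.
#' @param canopy_mean Target mean canopy cover (%) of the paddock.
#' @param dung_rates Expected dung events per 30-min step by state
#'   (resting > grazing > walking).
#' @param dung_dw_decay Exponential decay of dung intensity with distance to
#'   water (per m).
#' @param dung_canopy_beta Log-linear canopy-cover effect on dung intensity
#'   (per unit cover fraction; negative reduces deposition under trees).
#' @param dung_scatter_sd SD (m) of the scatter of an event around the
#'   animal's position.
#' @param hotspot_plots Integer plot ids whose discs get an engineered
#'   deposition boost (planted hotspots; empty by default).
#' @param hotspot_multiplier Rate multiplier inside planted hotspot plots.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_animals = 7L, n_weeks = 19L,
                       fix_interval = 30L, step_min = 1L,
                       paddock_width = 660, paddock_height = 350,
                       dem_cell = 5, env_cell = 10,
                       n_plots = 90L, plot_radius = 5,
                       plot_min_separation = 50,
                       start_date = "2021-02-15",
                       dropout_prob = 0.12, gps_error_prob = 0.01,
                       timestamp_jitter_min = 2L,
                       speeds = c(resting = 0.4, grazing = 3, walking = 12),
                       turn_sd = c(resting = 1.5, grazing = 0.8,
                                   walking = 0.3),
                       cohesion = c(resting = 0.25, grazing = 0.04,
                                    walking = 0.10),
                       speed_sdlog = 0.3,
                       grazing_bouts = list(c(6, 10), c(17, 21)),
                       state_probs_bout = c(0.05, 0.85, 0.10),
                       state_probs_rest = c(0.90, 0.07, 0.03),
                       water_attract_max = 0.25,
                       water_temp_mid = 18.5, water_temp_scale = 1.2,
                       canopy_mean = 24.7,
                       dung_rates = c(resting = 0.55, grazing = 0.28,
                                      walking = 0.08),
                       dung_dw_decay = 0.002, dung_canopy_beta = -0.8,
                       dung_scatter_sd = 2,
                       hotspot_plots = integer(0),
                       hotspot_multiplier = 40) {
  stopifnot(dropout_prob >= 0, dropout_prob <= 1,
            gps_error_prob >= 0, gps_error_prob <= 1,
            length(speeds) == 3, all(diff(unname(speeds)) > 0),
            abs(sum(state_probs_bout) - 1) < 1e-9,
            abs(sum(state_probs_rest) - 1) < 1e-9,
            all(dung_rates >= 0), fix_interval %% step_min == 0)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# smooth random field as a sum of Gaussian bumps evaluated on cell centers
smooth_field <- function(grid, n_bumps, amp_range, width_range,
                         base_gradient = c(0, 0)) {
  ctr <- cell_centers(grid)
  X <- outer(rep(1, grid$n_rows), ctr$x)
  Y <- outer(ctr$y, rep(1, grid$n_cols))
  z <- base_gradient[1] * X + base_gradient[2] * Y
  W <- grid$n_cols * grid$cell_size; H <- grid$n_rows * grid$cell_size
  for (k in seq_len(n_bumps)) {
    cx <- stats::runif(1, 0, W); cy <- stats::runif(1, 0, H)
    amp <- stats::runif(1, amp_range[1], amp_range[2])
    wid <- stats::runif(1, width_range[1], width_range[2])
    z <- z + amp * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * wid^2))
  }
  z
}

#' Generate the synthetic paddock, plots and environment layers
#'
#' Builds a rectangular fence of the target area with the water trough at the
#' southeastern end, a smooth random DEM (5 m cells) from which slope and
#' insolation are derived, a canopy-cover field calibrated to the target mean
#' cover, a distance-to-water raster (10 m cells), and the sampling-plot
#' layout. Plots are placed on a jittered hexagonal lattice, which guarantees
#' the minimum pairwise separation at a packing density that independent
#' random placement cannot reach. Per-plot covariates are computed with
#' [plot_summary()].
#'
#' @param config A [sim_config()].
#' @return List with `paddock`, `plots` (data frame with layout and
#'   covariates) and `layers` (named [raster_layer()] list: `dem` at 5 m;
#'   `slope`, `insolation`, `aspect`, `canopy`, `dist_water` at 10 m).
#' @export
gen_paddock <- function(config) {
  set.seed(config$seed + 101L)
  W <- config$paddock_width; H <- config$paddock_height
  fence <- cbind(c(0, W, W, 0), c(0, 0, H, H))
  water <- c(W - 15, 15)  # southeastern end (x east, y north)
  pad <- paddock(fence, water)

  g5 <- grid_spec(0, 0, config$dem_cell, H / config$dem_cell,
                  W / config$dem_cell)
  # gentle broad relief plus a few sharper knolls: yields a slope mix with a
  # sizeable flat (<10%) fraction, a dominant 10-20% class and some >20%
  dem5 <- raster_layer(g5, smooth_field(g5, 6, c(6, 15), c(120, 250),
                                        base_gradient = c(0.02, 0.03)) +
                           smooth_field(g5, 3, c(6, 12), c(40, 70)))
  slope5 <- slope_percent(dem5)
  fact <- config$env_cell / config$dem_cell
  dem10 <- block_aggregate(dem5, fact)
  slope10 <- block_aggregate(slope5, fact)
  insol10 <- insolation_class(dem10, slope10)
  aspect10 <- aspect_azimuth(dem10)
  # canopy: smooth clump field, shifted/clipped so the paddock mean matches
  # the target cover while keeping a sizeable treeless fraction
  f <- smooth_field(dem10$grid, 40, c(-1, 1.6), c(30, 90))
  f <- (f - mean(f)) / stats::sd(f)
  target <- config$canopy_mean
  obj <- function(q) mean(pmin(100, pmax(0, 250 * (f - q)))) - target
  q <- stats::uniroot(obj, c(-4, 4))$root
  canopy10 <- raster_layer(dem10$grid, pmin(pmax(250 * (f - q), 0), 100))
  dist10 <- distance_to_water(dem10$grid, water)

  plots <- place_plots(config, W, H)
  plots$slope <- vapply(seq_len(nrow(plots)), function(i)
    plot_summary(slope10, plots$x[i], plots$y[i], plots$radius[i]), 0)
  plots$insolation <- vapply(seq_len(nrow(plots)), function(i)
    plot_summary(insol10, plots$x[i], plots$y[i], plots$radius[i]), "")
  plots$insolation_deg <- vapply(seq_len(nrow(plots)), function(i)
    plot_insolation_deg(aspect10, slope10, plots$x[i], plots$y[i],
                        plots$radius[i]), 0)
  plots$canopy <- vapply(seq_len(nrow(plots)), function(i)
    plot_summary(canopy10, plots$x[i], plots$y[i], plots$radius[i]), 0)
  plots$dist_water <- vapply(seq_len(nrow(plots)), function(i)
    plot_summary(dist10, plots$x[i], plots$y[i], plots$radius[i]), 0)

  list(paddock = pad, plots = plots,
       layers = list(dem = dem5, slope = slope10, insolation = insol10,
                     aspect = aspect10, canopy = canopy10,
                     dist_water = dist10))
}

# jittered hexagonal lattice placement honoring the minimum separation
place_plots <- function(config, W, H) {
  sep <- config$plot_min_separation
  spacing <- sep + 2  # jitter of +/-0.5 m per coordinate keeps pairs >= sep
  margin <- 12
  dy <- spacing * sqrt(3) / 2
  ys <- seq(margin, H - margin, by = dy)
  pts <- do.call(rbind, lapply(seq_along(ys), function(k) {
    off <- if (k %% 2 == 0) spacing / 2 else 0
    xs <- seq(margin + off, W - margin, by = spacing)
    cbind(xs, ys[k])
  }))
  pts <- pts + matrix(stats::runif(length(pts), -0.5, 0.5), ncol = 2)
  if (nrow(pts) < config$n_plots)
    stop("cannot place ", config$n_plots, " plots with ", sep,
         " m separation; reduce n_plots or the separation")
  pts <- pts[sample(nrow(pts), config$n_plots), , drop = FALSE]
  pts <- pts[order(pts[, 2], pts[, 1]), , drop = FALSE]
  data.frame(plot_id = seq_len(config$n_plots),
             x = pts[, 1], y = pts[, 2], radius = config$plot_radius)
}

# mean downhill azimuth (deg) over non-flat subcells of a plot; 0 when the
# plot is entirely flat (no insolation effect)
plot_insolation_deg <- function(aspect, slope, x, y, radius, subcell = 0.5) {
  s <- seq(-radius + subcell / 2, radius - subcell / 2, by = subcell)
  pts <- expand.grid(dx = s, dy = s)
  pts <- pts[pts$dx^2 + pts$dy^2 <= radius^2, ]
  sl <- values_at(slope, x + pts$dx, y + pts$dy)
  az <- values_at(aspect, x + pts$dx, y + pts$dy)
  keep <- !is.na(sl) & !is.na(az) & sl >= 10
  if (!any(keep)) return(0)
  a <- az[keep] * pi / 180
  (atan2(mean(sin(a)), mean(cos(a))) * 180 / pi) %% 360
}

#' Generate daily weather for the study period
#'
#' A warming Mediterranean late-winter-to-summer trend (weekly means climbing
#' from about 10 to 26 degrees C) with daily noise, decreasing rain frequency,
#' decreasing humidity and increasing radiation.
#'
#' @param config A [sim_config()].
#' @return Daily data frame with the columns [weekly_weather()] expects.
#' @export
gen_weather <- function(config) {
  set.seed(config$seed + 102L)
  n_days <- config$n_weeks * 7L
  date <- as.Date(config$start_date) + seq_len(n_days) - 1L
  frac <- (seq_len(n_days) - 1) / max(1, n_days - 1)
  tavg <- 10 + 16 * frac + stats::rnorm(n_days, 0, 1.8)
  rainy <- stats::rbinom(n_days, 1, pmax(0.05, 0.35 - 0.28 * frac))
  data.frame(
    date = date,
    tavg = tavg,
    tmax = tavg + 6 + stats::rnorm(n_days, 0, 0.8),
    tmin = tavg - 5 + stats::rnorm(n_days, 0, 0.8),
    rain = rainy * stats::rgamma(n_days, shape = 0.7, scale = 8),
    rh = pmin(95, pmax(25, 75 - 25 * frac + stats::rnorm(n_days, 0, 3))),
    radiation = 120 + 180 * frac + stats::rnorm(n_days, 0, 15),
    wind = stats::rlnorm(n_days, log(2.5), 0.3))
}

#' Generate synthetic NDVI scenes
#'
#' Cloud-free scenes roughly every 5 days on the 10-m grid: a spatial base
#' pattern (greener under canopy late in the season) with a seasonal decline
#' of the pasture signal from green winter/spring growth toward summer
#' senescence, plus scene noise.
#'
#' @param config A [sim_config()].
#' @param pad Output of [gen_paddock()].
#' @return List with `dates` and `values` (matrix scenes x pixels, pixels in
#'   raster row-major order of the 10-m grid).
#' @export
gen_ndvi <- function(config, pad) {
  set.seed(config$seed + 106L)
  n_days <- config$n_weeks * 7L
  offs <- seq(2, n_days - 1, by = 5)
  dates <- as.Date(config$start_date) + offs
  canopy <- as.vector(pad$layers$canopy$values) / 100
  frac <- offs / n_days
  vals <- t(vapply(seq_along(offs), function(i) {
    grass <- 0.65 - 0.35 * frac[i]
    tree <- 0.55 + 0.05 * frac[i]   # evergreen oaks keep their greenness
    px <- (1 - canopy) * grass + canopy * tree
    pmin(0.95, pmax(0.05, px + stats::rnorm(length(px), 0, 0.02)))
  }, numeric(length(canopy))))
  list(dates = dates, values = vals)
}

#' Per-plot weekly NDVI
#'
#' Averages the weekly per-pixel NDVI over each sampling plot disc.
#'
#' @param ndvi_wk Output of [weekly_ndvi()].
#' @param grid The 10-m [grid_spec()] the NDVI pixels live on.
#' @param plots Plot data frame.
#' @return Data frame `plot_id`, `week`, `ndvi`.
#' @export
plot_ndvi <- function(ndvi_wk, grid, plots) {
  out <- list()
  for (w in seq_len(nrow(ndvi_wk$values))) {
    lyr <- raster_layer(grid, matrix(ndvi_wk$values[w, ], grid$n_rows,
                                     grid$n_cols))
    v <- vapply(seq_len(nrow(plots)), function(i)
      plot_summary(lyr, plots$x[i], plots$y[i], plots$radius[i]), 0)
    out[[w]] <- data.frame(plot_id = plots$plot_id, week = w, ndvi = v)
  }
  do.call(rbind, out)
}

#' Generate ground-truth cattle trajectories
#'
#' Per animal, a 1-min-resolution correlated random walk whose behavioral
#' state (resting/grazing/walking) is drawn per 30-min interval from a
#' diurnal schedule with two grazing bouts. Step lengths follow the state's
#' speed distribution; headings are biased toward the water trough with a
#' weight that increases with weekly mean temperature; positions reflect at
#' the fence.
#'
#' @param config A [sim_config()].
#' @param pad Output of [gen_paddock()].
#' @param weather Weekly weather (from [weekly_weather()] on [gen_weather()]
#'   output); only `tavg` per week is used. NULL disables water attraction.
#' @return Ground-truth list: matrices `x`, `y`, `state`
#'   (`n_steps x n_animals`), `minute` (0-based), plus metadata.
#' @export
gen_trajectories <- function(config, pad, weather = NULL) {
  set.seed(config$seed + 103L)
  n_days <- config$n_weeks * 7L
  steps_per_day <- as.integer(1440 / config$step_min)
  n_steps <- n_days * steps_per_day
  n_int_day <- as.integer(1440 / config$fix_interval)
  n_int <- n_days * n_int_day

  hour <- (((seq_len(n_int) - 1) %% n_int_day) * config$fix_interval) / 60
  in_bout <- Reduce(`|`, lapply(config$grazing_bouts, function(b)
    hour >= b[1] & hour < b[2]))
  state_int <- matrix(0L, n_int, config$n_animals)
  for (a in seq_len(config$n_animals)) {
    p <- ifelse(in_bout, 1, 0)
    state_int[, a] <- ifelse(p == 1,
      sample.int(3L, n_int, replace = TRUE, prob = config$state_probs_bout),
      sample.int(3L, n_int, replace = TRUE, prob = config$state_probs_rest))
  }
  expand <- rep(seq_len(n_int), each = config$fix_interval / config$step_min)
  state <- state_int[expand, , drop = FALSE]

  week_of_step <- ((seq_len(n_steps) - 1) %/% (7L * steps_per_day)) + 1L
  if (!is.null(weather)) {
    tw <- weather$tavg[match(week_of_step, weather$week)]
    tw[is.na(tw)] <- mean(weather$tavg)
    attract <- config$water_attract_max *
      stats::plogis((tw - config$water_temp_mid) / config$water_temp_scale)
  } else {
    attract <- rep(0, n_steps)
  }

  W <- config$paddock_width; H <- config$paddock_height
  x0 <- stats::runif(config$n_animals, 0.2 * W, 0.8 * W)
  y0 <- stats::runif(config$n_animals, 0.2 * H, 0.8 * H)
  p <- crw_paths(state, unname(config$speeds), unname(config$turn_sd),
                 config$speed_sdlog, attract, unname(config$cohesion),
                 pad$paddock$water_point[1], pad$paddock$water_point[2],
                 W, H, x0, y0, config$step_min)
  list(x = p$x, y = p$y, state = state,
       minute = (seq_len(n_steps) - 1) * config$step_min,
       animals = sprintf("A%02d", seq_len(config$n_animals)),
       start_date = as.Date(config$start_date), step_min = config$step_min,
       config = config)
}

#' Sample GPS fixes from ground-truth paths
#'
#' Samples each animal's path every `fix_interval` minutes with per-fix
#' Bernoulli dropout, uniform timestamp jitter, and a small probability of a
#' gross error that displaces the reported position outside the fence.
#' Injected errors are flagged in the `error_injected` column so filter
#' recall is measurable exactly.
#'
#' @param config A [sim_config()].
#' @param truth Output of [gen_trajectories()].
#' @return Fix data frame: `device_id`, `timestamp` (POSIXct UTC), `x`, `y`,
#'   `error_injected`.
#' @export
gen_gps <- function(config, truth) {
  set.seed(config$seed + 104L)
  n_steps <- nrow(truth$x)
  fix_min <- seq(0, n_steps * config$step_min - 1, by = config$fix_interval)
  W <- config$paddock_width; H <- config$paddock_height
  out <- vector("list", config$n_animals)
  origin <- as.POSIXct(paste(truth$start_date, "00:00:00"), tz = "UTC")
  for (a in seq_len(config$n_animals)) {
    jit <- if (config$timestamp_jitter_min > 0)
      sample(seq(-config$timestamp_jitter_min, config$timestamp_jitter_min),
             length(fix_min), replace = TRUE) else 0L
    tmin <- pmin(pmax(fix_min + jit, 0), n_steps * config$step_min - 1)
    idx <- tmin %/% config$step_min + 1L
    keep <- stats::rbinom(length(idx), 1, 1 - config$dropout_prob) == 1
    x <- truth$x[idx, a]; y <- truth$y[idx, a]
    err <- stats::rbinom(length(idx), 1, config$gps_error_prob) == 1
    if (any(err)) {
      for (i in which(err)) {
        side <- which.min(c(x[i], W - x[i], y[i], H - y[i]))
        push <- stats::runif(1, 2, 30)
        if (side == 1) x[i] <- -push else if (side == 2) x[i] <- W + push
        else if (side == 3) y[i] <- -push else y[i] <- H + push
      }
    }
    out[[a]] <- data.frame(
      device_id = truth$animals[a],
      timestamp = origin + tmin * 60,
      x = x, y = y, error_injected = err)[keep, ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate dung events and the weekly plot census
#'
#' Per 30-min step and animal, events are Poisson with rate
#' `base(state) * exp(-decay * dist_water) * exp(beta * canopy)`, multiplied
#' inside planted hotspot plots; each event is placed at the animal's position
#' with a small scatter. The weekly census counts events inside each plot
#' disc.
#'
#' @param config A [sim_config()].
#' @param truth Output of [gen_trajectories()].
#' @param pad Output of [gen_paddock()].
#' @return List with `events` (animal, week, minute, x, y) and `census`
#'   (complete `plot_id x week` grid of counts).
#' @export
gen_dung <- function(config, truth, pad) {
  set.seed(config$seed + 105L)
  stride <- config$fix_interval / config$step_min
  idx <- seq(1, nrow(truth$x), by = stride)
  week <- ((truth$minute[idx]) %/% (7L * 1440L)) + 1L
  rates <- unname(config$dung_rates)
  hs <- pad$plots[pad$plots$plot_id %in% config$hotspot_plots, , drop = FALSE]
  ev <- vector("list", config$n_animals)
  for (a in seq_len(config$n_animals)) {
    x <- truth$x[idx, a]; y <- truth$y[idx, a]
    st <- truth$state[idx, a]
    dw <- values_at(pad$layers$dist_water, x, y)
    cc <- values_at(pad$layers$canopy, x, y) / 100
    dw[is.na(dw)] <- mean(dw, na.rm = TRUE)
    cc[is.na(cc)] <- 0
    lambda <- rates[st] * exp(-config$dung_dw_decay * dw) *
      exp(config$dung_canopy_beta * cc)
    if (nrow(hs)) {
      in_hs <- rep(FALSE, length(x))
      for (i in seq_len(nrow(hs)))
        in_hs <- in_hs | ((x - hs$x[i])^2 + (y - hs$y[i])^2 <= hs$radius[i]^2)
      lambda[in_hs] <- lambda[in_hs] * config$hotspot_multiplier
    }
    n <- stats::rpois(length(lambda), lambda)
    if (sum(n) == 0) { ev[[a]] <- NULL; next }
    rep_i <- rep(seq_along(n), n)
    ex <- x[rep_i] + stats::rnorm(sum(n), 0, config$dung_scatter_sd)
    ey <- y[rep_i] + stats::rnorm(sum(n), 0, config$dung_scatter_sd)
    inside <- point_in_polygon(ex, ey, pad$paddock$fence)
    ex[!inside] <- x[rep_i][!inside]
    ey[!inside] <- y[rep_i][!inside]
    ev[[a]] <- data.frame(animal = truth$animals[a], week = week[rep_i],
                          minute = truth$minute[idx][rep_i], x = ex, y = ey)
  }
  events <- do.call(rbind, ev)
  if (is.null(events))
    events <- data.frame(animal = character(), week = integer(),
                         minute = numeric(), x = numeric(), y = numeric())
  rownames(events) <- NULL
  census <- census_from_events(events, pad$plots, config$n_weeks)
  list(events = events, census = census)
}

#' Choose plots for planted dung hotspots
#'
#' The study's engineered hotspots emulate the field observation that dung
#' hotspots form on well-visited plots moderately close to the water trough
#' (50-150 m): the rule picks the band plot with the highest realized fix
#' count and pairs it with the nearest band plot of the same 4-plot unit
#' (falling back to the nearest band plot overall), so the pair sits in one
#' high-traffic aggregation unit like the two adjacent hotspot plots of a
#' real paddock.
#'
#' @param plots Plot data frame with covariates (needs `dist_water`).
#' @param fix_totals Named vector of per-plot total fix counts (names =
#'   plot ids), e.g. from [count_fixes()] totals.
#' @param band Distance-to-water band (m) eligible for planting.
#' @return Integer vector of two plot ids.
#' @export
select_hotspot_plots <- function(plots, fix_totals, band = c(50, 150)) {
  in_band <- plots$dist_water >= band[1] & plots$dist_water <= band[2]
  bp <- plots[in_band, , drop = FALSE]
  if (nrow(bp) < 2) stop("fewer than two plots in the hotspot band")
  ft <- fix_totals[as.character(bp$plot_id)]
  ft[is.na(ft)] <- 0
  top <- bp$plot_id[which.max(ft)]
  groups <- group_plots(plots, 4)
  unit <- groups$unit_id[groups$plot_id == top]
  partners <- bp[bp$plot_id != top, , drop = FALSE]
  same_unit <- partners$plot_id %in%
    groups$plot_id[!is.na(groups$unit_id) & groups$unit_id %in% unit]
  if (any(same_unit)) partners <- partners[same_unit, , drop = FALSE]
  d2 <- (partners$x - bp$x[bp$plot_id == top])^2 +
        (partners$y - bp$y[bp$plot_id == top])^2
  c(top, partners$plot_id[which.min(d2)])
}

#' Count dung events inside each plot per week
#'
#' @param events Dung event data frame (`week`, `x`, `y`).
#' @param plots Plot data frame (`plot_id`, `x`, `y`, `radius`).
#' @param n_weeks Number of study weeks (complete output grid).
#' @return Data frame `plot_id`, `week`, `count`.
#' @export
census_from_events <- function(events, plots, n_weeks) {
  grid <- expand.grid(plot_id = plots$plot_id, week = seq_len(n_weeks))
  grid$count <- 0L
  if (nrow(events)) {
    for (i in seq_len(nrow(plots))) {
      d2 <- (events$x - plots$x[i])^2 + (events$y - plots$y[i])^2
      sel <- d2 <= plots$radius[i]^2
      if (any(sel)) {
        tab <- table(factor(events$week[sel], levels = seq_len(n_weeks)))
        grid$count[grid$plot_id == plots$plot_id[i]] <-
          grid$count[grid$plot_id == plots$plot_id[i]] + as.integer(tab)
      }
    }
  }
  grid[order(grid$week, grid$plot_id), c("plot_id", "week", "count")]
}

#' Generate a complete synthetic study
#'
#' Runs the full generator chain (paddock, weather, trajectories, GPS
#' sampling, dung deposition) under the configuration seed. Optionally writes
#' all pipeline input files to a directory.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory for interchange files.
#' @return List with `config`, `pad` (paddock/plots/layers), `weather_daily`,
#'   `weather_weekly`, `truth`, `fixes`, `dung`.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  pad <- gen_paddock(config)
  weather_daily <- gen_weather(config)
  weather_weekly <- weekly_weather(weather_daily, config$start_date,
                                   config$n_weeks)
  truth <- gen_trajectories(config, pad, weather_weekly)
  fixes <- gen_gps(config, truth)
  dung <- gen_dung(config, truth, pad)
  ndvi <- gen_ndvi(config, pad)
  ndvi_weekly <- weekly_ndvi(ndvi$dates, ndvi$values, config$start_date,
                             config$n_weeks)
  res <- list(config = config, pad = pad, weather_daily = weather_daily,
              weather_weekly = weather_weekly, truth = truth, fixes = fixes,
              dung = dung, ndvi = ndvi, ndvi_weekly = ndvi_weekly)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fixes(fixes[, c("device_id", "timestamp", "x", "y")],
                file.path(out_dir, "fixes.csv"))
    write_layout(pad$paddock, pad$plots, file.path(out_dir, "layout.geojson"))
    for (nm in c("slope", "canopy", "dist_water"))
      write_raster(pad$layers[[nm]], file.path(out_dir, paste0(nm, ".asc")))
    write_weather(weather_daily, file.path(out_dir, "weather.csv"))
    write_census(dung$census, file.path(out_dir, "census.csv"))
    utils::write.csv(dung$events, file.path(out_dir, "dung_events.csv"),
                     row.names = FALSE)
  }
  res
}
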