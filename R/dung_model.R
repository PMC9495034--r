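# Stepwise regression of weekly per-plot dung counts on animal-presence
# indicators and environmental covariates, with spatial (1 vs 4 plots) and
# temporal (1 vs 6 weeks) aggregation, 70/30 temporal and spatial
# validation, correlation scans and hotspot detection.

#' Assemble the plot-week modelling table
#'
#' Joins the weekly dung census, the presence indicators (total and
#' resting-only), per-plot static covariates and weekly weather/NDVI into
#' one row per plot and week, using the short covariate codes CC (canopy
#' cover fraction), DW (distance to water, m), IN (insolation azimuth, deg),
#' NDVI, SL (slope, %), TA (weekly mean temperature) and TM (weekly max
#' temperature).
#'
#' @param census Data frame `plot_id`, `week`, `count`.
#' @param presence Presence table (behavior = "all") from [presence_table()].
#' @param plots Plot data frame with covariates (`slope`, `insolation_deg`,
#'   `canopy`, `dist_water`).
#' @param weather Weekly weather from [weekly_weather()].
#' @param presence_resting Optional presence table restricted to resting
#'   behavior (adds `fix_resting`, `segment_resting`, `time_resting`).
#' @param ndvi_weekly Optional per-plot weekly NDVI: data frame `plot_id`,
#'   `week`, `ndvi`.
#' @return Model table data frame.
#' @export
build_model_table <- function(census, presence, plots, weather,
                              presence_resting = NULL, ndvi_weekly = NULL) {
  pres <- presence[presence$behavior == "all",
                   c("plot_id", "week", "fix_count", "segment_count",
                     "time_min")]
  names(pres) <- c("plot_id", "week", "fix", "segment", "time")
  tab <- merge(census, pres, by = c("plot_id", "week"), all.x = TRUE)
  names(tab)[names(tab) == "count"] <- "dung"
  if (!is.null(presence_resting)) {
    pr <- presence_resting[presence_resting$behavior == "resting",
                           c("plot_id", "week", "fix_count",
                             "segment_count", "time_min")]
    names(pr) <- c("plot_id", "week", "fix_resting", "segment_resting",
                   "time_resting")
    tab <- merge(tab, pr, by = c("plot_id", "week"), all.x = TRUE)
  }
  cov <- data.frame(plot_id = plots$plot_id, CC = plots$canopy / 100,
                    DW = plots$dist_water, IN = plots$insolation_deg,
                    SL = plots$slope)
  tab <- merge(tab, cov, by = "plot_id")
  tab <- merge(tab, data.frame(week = weather$week, TA = weather$tavg,
                               TM = weather$tmax), by = "week")
  if (!is.null(ndvi_weekly))
    tab <- merge(tab, ndvi_weekly, by = c("plot_id", "week"), all.x = TRUE)
  num <- setdiff(names(tab), c("plot_id", "week"))
  for (cc in num) tab[[cc]][is.na(tab[[cc]])] <- 0
  tab[order(tab$week, tab$plot_id), ]
}

#' Group plots into spatial units of four mutual neighbors
#'
#' Greedy deterministic pairing: the lowest-id unassigned plot seeds a group
#' together with its three nearest unassigned plots (ties broken by id).
#' Leftover plots (when `n` is not divisible by the group size) form a
#' flagged incomplete group that modelling excludes.
#'
#' @param plots Plot data frame (`plot_id`, `x`, `y`).
#' @param size Plots per group (default 4).
#' @return Data frame `plot_id`, `unit_id` (NA for leftovers), `complete`.
#' @export
group_plots <- function(plots, size = 4) {
  ord <- order(plots$plot_id)
  ids <- plots$plot_id[ord]; px <- plots$x[ord]; py <- plots$y[ord]
  unit <- rep(NA_integer_, length(ids))
  g <- 0L
  remaining <- seq_along(ids)
  while (length(remaining) >= size) {
    seed <- remaining[1]
    d <- sqrt((px[remaining] - px[seed])^2 + (py[remaining] - py[seed])^2)
    pick <- remaining[order(d, ids[remaining])][seq_len(size)]
    g <- g + 1L
    unit[pick] <- g
    remaining <- setdiff(remaining, pick)
  }
  data.frame(plot_id = ids, unit_id = unit, complete = !is.na(unit))
}

#' Aggregate the model table over spatial and temporal units
#'
#' Spatial unit 4 groups plots via [group_plots()]; temporal unit 6 maps
#' weeks into consecutive 6-week blocks aligned to week 1, dropping the
#' incomplete trailing block. Counts and presence indicators are summed,
#' covariates averaged. With units of 1 the table is returned unchanged
#' (apart from unit columns).
#'
#' @param tab Model table from [build_model_table()].
#' @param plots Plot data frame.
#' @param spatial_unit Plots per spatial unit (1 or 4 in the study design).
#' @param temporal_unit Weeks per temporal block (1 or 6 in the study
#'   design).
#' @return List: `table` (aggregated, with `unit_id` and `block`), `groups`
#'   (plot-to-unit map), `plots_per_unit`, `weeks_per_unit`,
#'   `dropped_weeks`, `dropped_plots`.
#' @export
aggregate_units <- function(tab, plots, spatial_unit = 1,
                            temporal_unit = 1) {
  stopifnot(spatial_unit >= 1, temporal_unit >= 1)
  sum_cols <- intersect(c("dung", "fix", "segment", "time", "fix_resting",
                          "segment_resting", "time_resting"), names(tab))
  mean_cols <- intersect(c("CC", "DW", "IN", "NDVI", "SL", "TA", "TM"),
                         names(tab))
  t2 <- tab
  dropped_plots <- integer(0); dropped_weeks <- integer(0)
  if (spatial_unit > 1) {
    groups <- group_plots(plots, spatial_unit)
    t2 <- merge(t2, groups, by = "plot_id")
    dropped_plots <- groups$plot_id[!groups$complete]
    t2 <- t2[t2$complete, ]
  } else {
    groups <- data.frame(plot_id = plots$plot_id,
                         unit_id = plots$plot_id, complete = TRUE)
    t2$unit_id <- t2$plot_id
  }
  if (temporal_unit > 1) {
    t2$block <- (t2$week - 1L) %/% temporal_unit + 1L
    wk_per_block <- tapply(t2$week, t2$block,
                           function(w) length(unique(w)))
    complete_blocks <- as.integer(names(wk_per_block))[
      wk_per_block == temporal_unit]
    dropped_weeks <- unique(t2$week[!(t2$block %in% complete_blocks)])
    t2 <- t2[t2$block %in% complete_blocks, ]
  } else {
    t2$block <- t2$week
  }
  key <- list(unit_id = t2$unit_id, block = t2$block)
  sums <- stats::aggregate(t2[sum_cols], key, sum)
  means <- stats::aggregate(t2[mean_cols], key, mean)
  out <- merge(sums, means, by = c("unit_id", "block"))
  list(table = out[order(out$block, out$unit_id), ],
       groups = groups,
       plots_per_unit = spatial_unit, weeks_per_unit = temporal_unit,
       dropped_weeks = sort(dropped_weeks), dropped_plots = dropped_plots)
}

#' Bidirectional stepwise ordinary least squares
#'
#' Variables enter while their partial-F p-value is below `entry` and leave
#' while it exceeds `stay` (the defaults 0.05/0.10 mirror classic
#' statistical-package stepwise dialects). The GPS presence indicator may be
#' offered both as its total and its resting-only version; whichever enters
#' better is kept and the other is blocked, so at most one GPS variable is in
#' the model. If nothing enters, an intercept-only fit is returned and
#' flagged.
#'
#' @param data Model table (possibly aggregated).
#' @param response Response column (default `"dung"`).
#' @param gps Character vector of competing GPS variable columns (e.g.
#'   `c("fix", "fix_resting")`), or NULL for a covariates-only model.
#' @param covariates Candidate covariate columns.
#' @param entry,stay Partial-F entry and removal p-value thresholds.
#' @return A `dung_model_fit` list: `model` (lm), `terms`, `coefficients`,
#'   `r2`, `gps_used` (NA if none), `intercept_only`.
#' @export
stepwise_fit <- function(data, response = "dung",
                         gps = NULL,
                         covariates = c("CC", "DW", "IN", "NDVI", "SL",
                                        "TA", "TM"),
                         entry = 0.05, stay = 0.10) {
  covariates <- intersect(covariates, names(data))
  gps <- intersect(gps, names(data))
  cands <- c(gps, covariates)
  if (nrow(data) < 10)
    stop("too few observations for stepwise regression")
  if (nrow(data) < 10 * length(cands))
    warning("fewer than 10 observations per candidate variable")
  # drop degenerate candidates
  cands <- cands[vapply(cands, function(v) stats::var(data[[v]]) > 0,
                        logical(1))]
  gps <- intersect(gps, cands)
  current <- character(0)
  for (iter in seq_len(50)) {
    changed <- FALSE
    allowed <- setdiff(cands, current)
    if (any(gps %in% current)) allowed <- setdiff(allowed, gps)
    fit <- stats::lm(stats::reformulate(c("1", current), response),
                     data = data)
    if (length(allowed)) {
      a1 <- stats::add1(fit, test = "F",
                        scope = stats::reformulate(c(current, allowed)))
      pv <- stats::setNames(a1[["Pr(>F)"]], rownames(a1))[allowed]
      pv <- pv[is.finite(pv)]
      if (length(pv) && min(pv) < entry) {
        current <- c(current, names(pv)[which.min(pv)])
        changed <- TRUE
      }
    }
    if (length(current)) {
      fit <- stats::lm(stats::reformulate(c("1", current), response),
                       data = data)
      d1 <- stats::drop1(fit, test = "F")
      pv <- d1[["Pr(>F)"]][-1]
      names(pv) <- rownames(d1)[-1]
      pv <- pv[is.finite(pv)]
      if (length(pv) && max(pv) > stay) {
        worst <- names(pv)[which.max(pv)]
        current <- setdiff(current, worst)
        cands <- setdiff(cands, worst)   # block re-entry, prevents cycling
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fit <- stats::lm(stats::reformulate(c("1", current), response),
                   data = data)
  structure(list(model = fit, terms = current,
                 coefficients = stats::coef(fit),
                 r2 = summary(fit)$r.squared,
                 gps_used = if (any(gps %in% current))
                   intersect(gps, current) else NA_character_,
                 intercept_only = length(current) == 0),
            class = "dung_model_fit")
}

#' @export
print.dung_model_fit <- function(x, ...) {
  cat("stepwise dung model:",
      if (x$intercept_only) "(intercept only)" else
        paste(x$terms, collapse = " + "),
      sprintf("| R2 = %.3f\n", x$r2))
  invisible(x)
}

#' Calibrate and validate a dung model on a 70/30 split
#'
#' Temporal scheme: the first 70% (floored) of the temporal units calibrate
#' and the remainder validate (19 weeks split as 1-13 vs 14-19). Spatial
#' scheme: a seeded uniform random 70/30 partition of the spatial units.
#' MAEs are mean absolute errors normalized per plot and week (unit MAE
#' divided by plots-per-unit times weeks-per-unit).
#'
#' @param agg Output of [aggregate_units()] (or a compatible list with
#'   `table`, `plots_per_unit`, `weeks_per_unit`).
#' @param scheme `"temporal"` or `"spatial"`.
#' @param frac Calibration fraction (default 0.7).
#' @param seed Seed for the spatial partition.
#' @param ... Passed to [stepwise_fit()] (`gps`, `covariates`, ...).
#' @return List: `fit`, `mae_cal`, `mae_val` (per plot-week), `n_cal`,
#'   `n_val`, `scheme`, `cal_units`/`cal_blocks`.
#' @export
split_validate <- function(agg, scheme = c("temporal", "spatial"),
                           frac = 0.7, seed = 1L, ...) {
  scheme <- match.arg(scheme)
  tab <- agg$table
  norm <- agg$plots_per_unit * agg$weeks_per_unit
  if (scheme == "temporal") {
    blocks <- sort(unique(tab$block))
    n_cal <- floor(frac * length(blocks))
    if (n_cal < 1 || n_cal >= length(blocks))
      stop("temporal split leaves an empty side")
    cal_sel <- tab$block %in% blocks[seq_len(n_cal)]
    split_ids <- blocks[seq_len(n_cal)]
  } else {
    units <- sort(unique(tab$unit_id))
    n_cal <- floor(frac * length(units))
    if (n_cal < 1 || n_cal >= length(units))
      stop("spatial split leaves an empty side")
    set.seed(seed)
    cal_units <- sort(sample(units, n_cal))
    cal_sel <- tab$unit_id %in% cal_units
    split_ids <- cal_units
  }
  cal <- tab[cal_sel, ]; val <- tab[!cal_sel, ]
  fit <- stepwise_fit(cal, ...)
  pred_cal <- stats::predict(fit$model, newdata = cal)
  pred_val <- stats::predict(fit$model, newdata = val)
  list(fit = fit,
       mae_cal = mean(abs(cal$dung - pred_cal)) / norm,
       mae_val = mean(abs(val$dung - pred_val)) / norm,
       n_cal = nrow(cal), n_val = nrow(val), scheme = scheme,
       split_ids = split_ids)
}

#' Correlation scans between dung and presence
#'
#' Pearson correlations between per-plot dung counts and a presence
#' indicator: per single week, per cumulative week prefix (counts summed
#' from week 1), and per spatial aggregation level over the whole period.
#' Zero-variance sides yield NA and are flagged.
#'
#' @param tab Model table (`plot_id`, `week`, `dung` and the indicator).
#' @param indicator Presence column (default `"fix"`).
#' @param plots Plot data frame (needed for spatial aggregation levels).
#' @param agg_levels Spatial levels to scan (default `c(1, 4)`).
#' @return List of data frames: `per_week`, `cumulative`, `spatial`.
#' @export
correlation_scan <- function(tab, indicator = "fix", plots = NULL,
                             agg_levels = c(1, 4)) {
  safe_cor <- function(x, y) {
    if (length(x) < 3 || stats::var(x) == 0 || stats::var(y) == 0)
      return(NA_real_)
    stats::cor(x, y)
  }
  weeks <- sort(unique(tab$week))
  per_week <- data.frame(week = weeks, r = vapply(weeks, function(w) {
    s <- tab[tab$week == w, ]
    safe_cor(s$dung, s[[indicator]])
  }, 0))
  cum <- data.frame(up_to_week = weeks, r = vapply(weeks, function(w) {
    s <- tab[tab$week <= w, ]
    d <- tapply(s$dung, s$plot_id, sum)
    f <- tapply(s[[indicator]], s$plot_id, sum)
    safe_cor(as.numeric(d), as.numeric(f))
  }, 0))
  spatial <- NULL
  if (!is.null(plots)) {
    spatial <- data.frame(agg = agg_levels, r = NA_real_)
    for (k in seq_along(agg_levels)) {
      lev <- agg_levels[k]
      if (lev == 1) {
        d <- tapply(tab$dung, tab$plot_id, sum)
        f <- tapply(tab[[indicator]], tab$plot_id, sum)
      } else {
        gg <- group_plots(plots, lev)
        m <- merge(tab, gg[gg$complete, ], by = "plot_id")
        d <- tapply(m$dung, m$unit_id, sum)
        f <- tapply(m[[indicator]], m$unit_id, sum)
      }
      spatial$r[k] <- safe_cor(as.numeric(d), as.numeric(f))
    }
  }
  list(per_week = per_week, cumulative = cum, spatial = spatial)
}

#' Flag predicted dung hotspots
#'
#' A unit is a hotspot when its predicted count exceeds the threshold
#' (default 100 droppings, the scale of a 4-plot/6-week unit). A relative
#' rule (`predicted > rel_factor * median`) is available instead.
#'
#' @param predictions Data frame with `unit_id` and `predicted`.
#' @param threshold Absolute threshold (default 100).
#' @param relative Use the relative rule instead.
#' @param rel_factor Multiplier on the median for the relative rule.
#' @return Data frame `unit_id`, `predicted`, `threshold`, `is_hotspot`.
#' @export
detect_hotspots <- function(predictions, threshold = 100, relative = FALSE,
                            rel_factor = 5) {
  thr <- if (relative) rel_factor * stats::median(predictions$predicted)
         else threshold
  data.frame(unit_id = predictions$unit_id,
             predicted = predictions$predicted,
             threshold = thr,
             is_hotspot = predictions$predicted > thr)
}
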