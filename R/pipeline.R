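# Orchestration: run the full analysis chain (simulate or read inputs,
# preprocess, behavior, presence, selection, model) with one root seed,
# writing every interchange table and a run manifest with input digests so
# identical configurations reproduce identical outputs.

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Root seed; the synthetic generator and the spatial validation
#'   split derive their seeds from it.
#' @param sim A [sim_config()] (its seed is overridden by `seed`).
#' @param simulate Generate the study inputs (TRUE) or read them from
#'   `input_dir` (FALSE).
#' @param input_dir Directory with pipeline inputs when `simulate = FALSE`
#'   (files as written by [simulate_study()]).
#' @param gps_variables GPS indicators to scan in the model stage.
#' @param spatial_units,temporal_units Aggregation levels to scan.
#' @param hotspot_threshold Predicted-count hotspot threshold.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = sim_config(seed = seed),
                            simulate = TRUE, input_dir = NULL,
                            gps_variables = c("none", "fix", "segment",
                                              "time"),
                            spatial_units = c(1, 4),
                            temporal_units = c(1, 6),
                            hotspot_threshold = 100) {
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 simulate = simulate, input_dir = input_dir,
                 gps_variables = gps_variables,
                 spatial_units = spatial_units,
                 temporal_units = temporal_units,
                 hotspot_threshold = hotspot_threshold),
            class = "pipeline_config")
}

#' Behavior label per fix
#'
#' Each fix inherits the behavior label of the trajectory segment starting at
#' it; a day's last fix inherits the preceding segment's label.
#'
#' @param fixes Resampled fix data frame.
#' @param segments Segment data frame with a `behavior` column.
#' @return Character vector of labels aligned with `fixes` rows.
#' @export
fix_behavior_labels <- function(fixes, segments) {
  key_f <- paste(fixes$device_id, fixes$timestamp)
  key_s <- paste(segments$device_id, segments$t_start)
  lab <- segments$behavior[match(key_f, key_s)]
  miss <- which(is.na(lab))
  if (length(miss)) {
    end_key <- paste(segments$device_id,
                     segments$t_start + segments$duration_min * 60)
    lab[miss] <- segments$behavior[match(key_f[miss], end_key)]
  }
  lab
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or ingest) / preprocess / behavior / presence /
#' selection / model in order, writes all stage outputs as delimited text
#' under `config$out_dir`, and returns the in-memory results plus a run
#' manifest (config echo, file digests, per-stage row counts). Identical
#' configuration and seed reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with all stage results and `manifest`.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  # --- inputs -------------------------------------------------------------
  if (config$simulate) {
    input_dir <- file.path(out, "inputs")
    study <- simulate_study(config$sim, out_dir = input_dir)
    pad <- study$pad
    fixes_raw <- study$fixes[, c("device_id", "timestamp", "x", "y")]
    census <- study$dung$census
    weather_daily <- study$weather_daily
    ndvi_weekly <- plot_ndvi(study$ndvi_weekly,
                             study$pad$layers$canopy$grid, study$pad$plots)
    names(ndvi_weekly)[names(ndvi_weekly) == "ndvi"] <- "NDVI"
    dung_points <- study$dung$events
    layers <- pad$layers
    plots <- pad$plots
    start_date <- config$sim$start_date
    n_weeks <- config$sim$n_weeks
  } else {
    input_dir <- config$input_dir
    if (is.null(input_dir)) stop("input_dir required when simulate = FALSE")
    layout <- read_layout(file.path(input_dir, "layout.geojson"))
    pad <- NULL
    plots <- layout$plots
    fixes_raw <- read_fixes(file.path(input_dir, "fixes.csv"))
    census <- read_census(file.path(input_dir, "census.csv"))
    weather_daily <- read_weather(file.path(input_dir, "weather.csv"))
    layers <- list(
      slope = read_raster(file.path(input_dir, "slope.asc")),
      canopy = read_raster(file.path(input_dir, "canopy.asc")),
      dist_water = read_raster(file.path(input_dir, "dist_water.asc")))
    ev_path <- file.path(input_dir, "dung_events.csv")
    dung_points <- if (file.exists(ev_path))
      utils::read.csv(ev_path) else NULL
    ndvi_weekly <- NULL
    start_date <- min(as.Date(fixes_raw$timestamp))
    n_weeks <- max(census$week)
    pad_fence <- layout$paddock
    pad <- list(paddock = pad_fence, plots = plots, layers = layers)
    # derive covariates if the layout lacks them
    if (!"slope" %in% names(plots)) {
      plots$slope <- vapply(seq_len(nrow(plots)), function(i)
        plot_summary(layers$slope, plots$x[i], plots$y[i],
                     plots$radius[i]), 0)
      plots$canopy <- vapply(seq_len(nrow(plots)), function(i)
        plot_summary(layers$canopy, plots$x[i], plots$y[i],
                     plots$radius[i]), 0)
      plots$dist_water <- vapply(seq_len(nrow(plots)), function(i)
        plot_summary(layers$dist_water, plots$x[i], plots$y[i],
                     plots$radius[i]), 0)
      plots$insolation_deg <- 0
      pad$plots <- plots
    }
  }
  weather_weekly <- weekly_weather(weather_daily, start_date, n_weeks)
  counts$fixes_raw <- nrow(fixes_raw)

  # --- preprocess ---------------------------------------------------------
  pp <- preprocess_fixes(fixes_raw, pad$paddock)
  counts$fixes_rejected <- nrow(pp$rejected)
  counts$days_excluded <- sum(!pp$ledger$included)
  counts$fixes_resampled <- nrow(pp$fixes)
  write_fixes(pp$fixes, file.path(out, "fixes_resampled.csv"))
  utils::write.csv(pp$ledger, file.path(out, "day_ledger.csv"),
                   row.names = FALSE)

  # --- behavior -----------------------------------------------------------
  thr <- fit_thresholds(pp$segments$speed_m_min)
  pp$segments$behavior <- classify_behavior(pp$segments$speed_m_min, thr)
  seg_out <- pp$segments
  seg_out$t_start <- format(seg_out$t_start, "%Y-%m-%dT%H:%M:%S",
                            tz = "UTC")
  utils::write.csv(seg_out, file.path(out, "segments.csv"),
                   row.names = FALSE)
  season <- season_of(pp$segments$date)
  profile <- activity_profile(pp$segments, group = season)
  utils::write.csv(profile, file.path(out, "activity_profile.csv"),
                   row.names = FALSE)
  disp <- herd_dispersal(pp$fixes)
  utils::write.csv(disp$records, file.path(out, "dispersal.csv"),
                   row.names = FALSE)

  # --- presence -----------------------------------------------------------
  fix_lab <- fix_behavior_labels(pp$fixes, pp$segments)
  pres <- presence_table(pp$fixes, pp$segments, plots, start_date,
                         fix_behavior = fix_lab,
                         segment_behavior = pp$segments$behavior)
  utils::write.csv(pres, file.path(out, "presence.csv"), row.names = FALSE)
  counts$presence_rows <- nrow(pres)

  # --- selection ----------------------------------------------------------
  sel <- NULL
  if (!is.null(dung_points) && all(c("slope", "canopy", "dist_water")
                                   %in% names(layers))) {
    fix_pts <- data.frame(x = pp$fixes$x, y = pp$fixes$y,
                          week = week_index(pp$fixes$timestamp, start_date))
    dg_pts <- data.frame(x = dung_points$x, y = dung_points$y,
                         week = dung_points$week)
    lay <- layers
    if (is.null(lay$insolation)) lay$insolation <- NULL
    sel_layers <- list(slope = lay$slope, insolation = lay$insolation,
                       canopy = lay$canopy, dist_water = lay$dist_water)
    if (is.null(sel_layers$insolation)) {
      sel <- NULL  # insolation layer unavailable: skip selection stage
    } else {
      sel <- selection_by_factors(fix_pts, dg_pts, sel_layers)
      utils::write.csv(sel, file.path(out, "selection.csv"),
                       row.names = FALSE)
      sel_sum <- summarize_selection(sel)
      utils::write.csv(sel_sum, file.path(out, "selection_summary.csv"),
                       row.names = FALSE)
    }
  }

  # --- model --------------------------------------------------------------
  pres_rest <- pres[pres$behavior == "resting", ]
  tab <- build_model_table(census, pres, plots, weather_weekly,
                           presence_resting = pres, ndvi_weekly = ndvi_weekly)
  utils::write.csv(tab, file.path(out, "model_table.csv"),
                   row.names = FALSE)
  report <- model_grid(tab, plots, gps_variables = config$gps_variables,
                       spatial_units = config$spatial_units,
                       temporal_units = config$temporal_units,
                       seed = config$seed)
  utils::write.csv(report, file.path(out, "model_report.csv"),
                   row.names = FALSE)

  # hotspot calls from the best-supported configuration (4 plots / 6 weeks,
  # segments as GPS variable) vs the covariates-only model
  hot <- tryCatch({
    agg <- aggregate_units(tab, plots, 4, 6)
    fit_gps <- stepwise_fit(agg$table,
                            gps = c("segment", "segment_resting"))
    fit_ctx <- stepwise_fit(agg$table, gps = NULL)
    per_unit <- function(fit) {
      pred <- stats::predict(fit$model, newdata = agg$table)
      tapply(pred, agg$table$unit_id, sum)
    }
    hg <- per_unit(fit_gps); hc <- per_unit(fit_ctx)
    rbind(
      cbind(detect_hotspots(data.frame(unit_id = as.integer(names(hg)),
                                       predicted = as.numeric(hg)),
                            config$hotspot_threshold), model = "with_gps"),
      cbind(detect_hotspots(data.frame(unit_id = as.integer(names(hc)),
                                       predicted = as.numeric(hc)),
                            config$hotspot_threshold), model = "contextual"))
  }, error = function(e) NULL)
  if (!is.null(hot))
    utils::write.csv(hot, file.path(out, "hotspots.csv"), row.names = FALSE)

  # --- manifest -----------------------------------------------------------
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  digests <- as.list(tools::md5sum(sort(files)))
  names(digests) <- sub(paste0("^", out, "/?"), "", names(digests))
  manifest <- list(seed = config$seed,
                   simulate = config$simulate,
                   n_weeks = n_weeks,
                   counts = counts,
                   digests = digests)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out, "manifest.json"))
  invisible(list(preprocess = pp, thresholds = thr, presence = pres,
                 selection = sel, model_table = tab, report = report,
                 hotspots = hot, manifest = manifest))
}

#' Scan model configurations
#'
#' Fits the stepwise model for every combination of spatial unit, temporal
#' unit and GPS variable (offering the resting-only version alongside each
#' total), validating on the temporal 70/30 split, and returns one row per
#' configuration with the selected coefficients, R2 and the MAEs per plot
#' and week.
#'
#' @param tab Model table from [build_model_table()].
#' @param plots Plot data frame.
#' @param gps_variables Subset of `c("none", "fix", "segment", "time")`.
#' @param spatial_units,temporal_units Aggregation levels.
#' @param scheme Validation scheme passed to [split_validate()].
#' @param seed Seed for the spatial split.
#' @return Data frame report (one row per configuration).
#' @export
model_grid <- function(tab, plots,
                       gps_variables = c("none", "fix", "segment", "time"),
                       spatial_units = c(1, 4), temporal_units = c(1, 6),
                       scheme = "temporal", seed = 1L) {
  covs <- intersect(c("CC", "DW", "IN", "NDVI", "SL", "TA", "TM"),
                    names(tab))
  rows <- list()
  for (sp in spatial_units) for (tu in temporal_units) {
    agg <- tryCatch(aggregate_units(tab, plots, sp, tu),
                    error = function(e) NULL)
    if (is.null(agg) || nrow(agg$table) == 0) next
    for (gv in gps_variables) {
      gps <- if (gv == "none") NULL else {
        rest <- paste0(gv, "_resting")
        c(gv, intersect(rest, names(tab)))
      }
      sv <- tryCatch(
        split_validate(agg, scheme = scheme, seed = seed, gps = gps,
                       covariates = covs),
        error = function(e) NULL)
      if (is.null(sv)) next
      fit <- sv$fit
      coefs <- fit$coefficients
      row <- data.frame(spatial = sp, temporal = tu, gps_variable = gv,
                        gps_used = fit$gps_used,
                        constant = unname(coefs["(Intercept)"]),
                        r2 = fit$r2, mae_cal = sv$mae_cal,
                        mae_val = sv$mae_val)
      for (cc in c("GPS", covs)) row[[cc]] <- NA_real_
      for (tm in fit$terms) {
        col <- if (tm %in% covs) tm else "GPS"
        row[[col]] <- unname(coefs[tm])
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
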