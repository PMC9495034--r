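# Preprocessing of raw collar fixes: fence filtering, gap-day exclusion,
# and resampling of daily trajectories to standardized 30-min timestamps,
# after which every retained day has exactly 48 fixes and 47 segments per
# animal.

#' Remove fixes outside the paddock fence
#'
#' Fixes strictly inside or on the fence are retained; the rest are treated
#' as GPS errors and logged.
#'
#' @param fixes Fix data frame (`device_id`, `timestamp`, `x`, `y`).
#' @param pad A [paddock()].
#' @return List with `fixes` (retained) and `rejected` (with a `reason`
#'   column).
#' @export
fence_filter <- function(fixes, pad) {
  inside <- point_in_polygon(fixes$x, fixes$y, pad$fence)
  rejected <- fixes[!inside, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- "outside_fence"
  list(fixes = fixes[inside, , drop = FALSE], rejected = rejected)
}

# minutes since midnight (UTC calendar day)
day_minutes <- function(timestamp) {
  as.numeric(timestamp - as.POSIXct(paste(as.Date(timestamp), "00:00:00"),
                                    tz = "UTC"),
             units = "mins")
}

#' Exclude days with long data gaps
#'
#' A calendar day is dropped for all devices if any device has a gap of
#' `max_gap_min` minutes or more between consecutive fixes, counting the
#' stretches from midnight to the first fix and from the last fix to the next
#' midnight. A device with no fixes at all on a day also excludes that day.
#' Gaps are measured on true timestamps (a gap of exactly the threshold
#' excludes; anything shorter retains).
#'
#' @param fixes Fence-filtered fix data frame.
#' @param devices Character vector of all device ids that should report.
#' @param max_gap_min Gap threshold (min, default 180 = three hours).
#' @return List with `fixes` (fixes on retained days), `ledger` (per day:
#'   `date`, `max_gap_min`, `worst_device`, `included`).
#' @export
gap_day_filter <- function(fixes, devices = unique(fixes$device_id),
                           max_gap_min = 180) {
  date <- as.Date(fixes$timestamp)
  days <- sort(unique(date))
  snap <- day_minutes(fixes$timestamp)
  groups <- split(snap, list(factor(as.character(date),
                                    levels = as.character(days)),
                             factor(fixes$device_id, levels = devices)),
                  drop = FALSE)
  gaps <- matrix(vapply(groups, function(m) {
    if (!length(m)) 1440 else max(diff(c(0, sort(m), 1440)))
  }, 0), nrow = length(days), ncol = length(devices))
  worst_ix <- max.col(gaps, ties.method = "first")
  ledger <- data.frame(
    date = days,
    max_gap_min = gaps[cbind(seq_along(days), worst_ix)],
    worst_device = devices[worst_ix])
  ledger$included <- ledger$max_gap_min < max_gap_min
  keep_days <- ledger$date[ledger$included]
  list(fixes = fixes[date %in% keep_days, , drop = FALSE], ledger = ledger)
}

#' Resample one device-day to standardized timestamps
#'
#' Positions are linearly interpolated in (true) time onto the 30-min grid
#' starting at midnight; before the first and after the last raw fix the
#' nearest raw position is held, so a retained day always yields exactly
#' `1440/interval` fixes.
#'
#' @param fixes Fixes of one device on one day (any order).
#' @param interval Grid interval (min, default 30).
#' @return Data frame of resampled fixes with `source` = "raw" where a raw
#'   fix sat exactly on the grid, "interpolated" otherwise.
#' @export
resample_trajectory <- function(fixes, interval = 30) {
  if (nrow(fixes) < 2)
    stop("need at least 2 raw fixes on a retained day to interpolate")
  if (length(unique(fixes$device_id)) != 1 ||
      length(unique(as.Date(fixes$timestamp))) != 1)
    stop("resample_trajectory expects one device and one day")
  o <- order(fixes$timestamp)
  fixes <- fixes[o, ]
  day <- as.Date(fixes$timestamp[1])
  midnight <- as.POSIXct(paste(day, "00:00:00"), tz = "UTC")
  tmin <- as.numeric(fixes$timestamp - midnight, units = "mins")
  grid <- seq(0, 1440 - interval, by = interval)
  x <- stats::approx(tmin, fixes$x, xout = grid, rule = 2, ties = "ordered")$y
  y <- stats::approx(tmin, fixes$y, xout = grid, rule = 2, ties = "ordered")$y
  data.frame(device_id = fixes$device_id[1],
             timestamp = midnight + grid * 60,
             x = x, y = y,
             source = ifelse(grid %in% round(tmin, 6), "raw", "interpolated"))
}

#' Resample all device-days of a fix table
#'
#' Applies [resample_trajectory()] per device and calendar day; device-days
#' with fewer than 2 raw fixes are skipped with a warning (they should have
#' been excluded by [gap_day_filter()] already).
#'
#' @param fixes Fence- and gap-filtered fix data frame.
#' @param interval Grid interval (min).
#' @return Resampled fix data frame.
#' @export
resample_fixes <- function(fixes, interval = 30) {
  day <- as.Date(fixes$timestamp)
  key <- paste(fixes$device_id, day)
  parts <- split(seq_len(nrow(fixes)), key)
  grid <- seq(0, 1440 - interval, by = interval)
  ng <- length(grid)
  np <- length(parts)
  xs <- ys <- matrix(NA_real_, ng, np)
  raw <- matrix(FALSE, ng, np)
  dev <- character(np)
  midnight <- rep(as.POSIXct(NA), np)
  keep <- logical(np)
  for (k in seq_len(np)) {
    ii <- parts[[k]]
    if (length(ii) < 2) {
      warning("skipping device-day with <2 fixes: ", key[ii[1]])
      next
    }
    ii <- ii[order(fixes$timestamp[ii])]
    mid <- as.POSIXct(paste(day[ii[1]], "00:00:00"), tz = "UTC")
    tmin <- as.numeric(fixes$timestamp[ii] - mid, units = "mins")
    xs[, k] <- stats::approx(tmin, fixes$x[ii], xout = grid, rule = 2,
                             ties = "ordered")$y
    ys[, k] <- stats::approx(tmin, fixes$y[ii], xout = grid, rule = 2,
                             ties = "ordered")$y
    raw[, k] <- grid %in% round(tmin, 6)
    dev[k] <- fixes$device_id[ii[1]]
    midnight[k] <- mid
    keep[k] <- TRUE
  }
  res <- data.frame(
    device_id = rep(dev[keep], each = ng),
    timestamp = rep(midnight[keep], each = ng) + rep(grid * 60,
                                                     sum(keep)),
    x = as.vector(xs[, keep, drop = FALSE]),
    y = as.vector(ys[, keep, drop = FALSE]),
    source = ifelse(as.vector(raw[, keep, drop = FALSE]), "raw",
                    "interpolated"))
  res[order(res$device_id, res$timestamp), ]
}

#' Build trajectory segments from resampled fixes
#'
#' One segment joins each pair of consecutive on-grid fixes of a device
#' within a day (47 per complete day); each carries its length, its duration
#' (the fix interval) and the implied average speed.
#'
#' @param resampled Resampled fix data frame.
#' @param interval Fix interval (min).
#' @return Segment data frame: `device_id`, `date`, `slot` (1-based index of
#'   the start timestamp within the day), `t_start`, `x0`, `y0`, `x1`, `y1`,
#'   `length_m`, `duration_min`, `speed_m_min`.
#' @export
build_segments <- function(resampled, interval = 30) {
  o <- order(resampled$device_id, resampled$timestamp)
  f <- resampled[o, ]
  n <- nrow(f)
  if (n < 2) return(NULL)
  date <- as.Date(f$timestamp)
  # a segment joins row i to i+1 within one device and one calendar day
  ok <- f$device_id[-n] == f$device_id[-1] & date[-n] == date[-1]
  i0 <- which(ok)
  len <- sqrt((f$x[i0 + 1] - f$x[i0])^2 + (f$y[i0 + 1] - f$y[i0])^2)
  midnight <- as.POSIXct(paste(date[i0], "00:00:00"), tz = "UTC")
  mins <- as.numeric(f$timestamp[i0] - midnight, units = "mins")
  res <- data.frame(device_id = f$device_id[i0], date = date[i0],
                    slot = as.integer(mins / interval) + 1L,
                    t_start = f$timestamp[i0],
                    x0 = f$x[i0], y0 = f$y[i0],
                    x1 = f$x[i0 + 1], y1 = f$y[i0 + 1],
                    length_m = len, duration_min = interval,
                    speed_m_min = len / interval)
  rownames(res) <- NULL
  res
}

#' Run the full preprocessing chain
#'
#' Fence filtering, gap-day exclusion, resampling to the standardized grid
#' and segment construction, in that order.
#'
#' @param fixes Raw fix data frame.
#' @param pad A [paddock()].
#' @param devices All device ids that should report (defaults to those seen).
#' @param interval Fix interval (min).
#' @param max_gap_min Gap-day threshold (min).
#' @return List: `fixes` (resampled), `segments`, `rejected`, `ledger`.
#' @export
preprocess_fixes <- function(fixes, pad, devices = unique(fixes$device_id),
                             interval = 30, max_gap_min = 180) {
  ff <- fence_filter(fixes, pad)
  gf <- gap_day_filter(ff$fixes, devices, max_gap_min)
  rs <- resample_fixes(gf$fixes, interval)
  segs <- build_segments(rs, interval)
  list(fixes = rs, segments = segs, rejected = ff$rejected,
       ledger = gf$ledger)
}
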