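# The three plot-level animal-presence indicators: fix counts, counts of
# trajectory segments intersecting each plot disc, and time allocated to a
# plot from the segment-circle intersection length (30 * y / x minutes for a
# 30-min segment of length x intersecting the disc over length y).

#' Length of the intersection of a segment with a circle
#'
#' Exact analytic chord computation: the line-circle quadratic is solved, the
#' solution interval is clipped to the segment, and the in-circle sub-segment
#' length returned. Tangency and no intersection give 0; a zero-length
#' segment gives 0 (its time allocation is handled by the containment rule in
#' [time_in_plot()]).
#'
#' All arguments are vectorized over segments.
#'
#' @param x0,y0,x1,y1 Segment endpoints (m).
#' @param cx,cy Circle center (m).
#' @param r Circle radius (m).
#' @return Intersection length(s) in meters.
#' @export
segment_circle_intersection <- function(x0, y0, x1, y1, cx, cy, r) {
  dx <- x1 - x0; dy <- y1 - y0
  fx <- x0 - cx; fy <- y0 - cy
  a <- dx^2 + dy^2
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx^2 + fy^2 - r^2
  disc <- b^2 - 4 * a * cc
  a <- rep_len(a, length(disc))
  b <- rep_len(b, length(disc))
  len <- numeric(length(disc))
  ok <- a > 0 & disc > 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- pmax((-b[ok] - sq) / (2 * a[ok]), 0)
    t2 <- pmin((-b[ok] + sq) / (2 * a[ok]), 1)
    len[ok] <- pmax(t2 - t1, 0) * sqrt(a[ok])
  }
  len
}

#' Time an animal spent inside a plot during one segment
#'
#' The paper's allocation rule: a segment of length `x` represents 30 min at
#' constant speed, so an intersection of length `y` contributes `30 * y / x`
#' minutes. A stationary segment (`x = 0`) contributes the full interval if
#' the point lies inside the plot (a resting animal inside the plot spends
#' the whole interval there) and 0 otherwise.
#'
#' @param x0,y0,x1,y1 Segment endpoints (m), vectorized.
#' @param cx,cy,r Plot center and radius (m).
#' @param duration Segment duration (min, default 30).
#' @return Minutes allocated to the plot per segment.
#' @export
time_in_plot <- function(x0, y0, x1, y1, cx, cy, r, duration = 30) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  y <- segment_circle_intersection(x0, y0, x1, y1, cx, cy, r)
  out <- ifelse(len > 0, duration * y / len, 0)
  stationary <- len == 0
  if (any(stationary)) {
    inside <- (x0 - cx)^2 + (y0 - cy)^2 <= r^2
    out[stationary] <- ifelse(inside[stationary], duration, 0)
  }
  out
}

#' Study week of a timestamp
#'
#' Weeks are 7-day windows; week 1 starts at the census start date.
#'
#' @param timestamp POSIXct or Date vector.
#' @param start_date First day of week 1.
#' @return Integer week indices.
#' @export
week_index <- function(timestamp, start_date) {
  floor(as.numeric(as.Date(timestamp) - as.Date(start_date)) / 7) + 1L
}

#' Count fixes per plot and week
#'
#' A fix counts for a plot iff its distance to the plot center is at most the
#' radius (boundary inclusive).
#'
#' @param fixes Resampled fix data frame.
#' @param plots Plot data frame (`plot_id`, `x`, `y`, `radius`).
#' @param start_date First day of week 1.
#' @param behavior Optional per-fix behavior labels (same length as `fixes`
#'   rows) to add a per-behavior breakdown.
#' @return Data frame `plot_id`, `week`, `behavior` ("all" plus labels when
#'   given), `fix_count`; complete over plots x observed weeks.
#' @export
count_fixes <- function(fixes, plots, start_date, behavior = NULL) {
  week <- week_index(fixes$timestamp, start_date)
  weeks <- sort(unique(week))
  lab <- if (is.null(behavior)) rep("all", nrow(fixes)) else behavior
  labs <- unique(c("all", lab))
  out <- expand.grid(plot_id = plots$plot_id, week = weeks,
                     behavior = labs, stringsAsFactors = FALSE)
  out$fix_count <- 0L
  for (i in seq_len(nrow(plots))) {
    d2 <- (fixes$x - plots$x[i])^2 + (fixes$y - plots$y[i])^2
    hit <- d2 <= plots$radius[i]^2
    if (!any(hit)) next
    for (lb in labs) {
      sel <- hit & (lb == "all" | lab == lb)
      if (!any(sel)) next
      tab <- table(factor(week[sel], levels = weeks))
      idx <- out$plot_id == plots$plot_id[i] & out$behavior == lb
      out$fix_count[idx] <- out$fix_count[idx] + as.integer(tab)
    }
  }
  out
}

#' Count intersecting segments and allocated time per plot and week
#'
#' A segment counts for a plot iff its intersection chord has positive
#' length, or it is a stationary point inside the plot; allocated minutes
#' follow [time_in_plot()]. A segment belongs to the week of its start
#' timestamp.
#'
#' @param segments Segment data frame from [build_segments()].
#' @param plots Plot data frame.
#' @param start_date First day of week 1.
#' @param behavior Optional per-segment behavior labels.
#' @return Data frame `plot_id`, `week`, `behavior`, `segment_count`,
#'   `time_min`.
#' @export
count_segments <- function(segments, plots, start_date, behavior = NULL) {
  week <- week_index(segments$t_start, start_date)
  weeks <- sort(unique(week))
  lab <- if (is.null(behavior)) rep("all", nrow(segments)) else behavior
  labs <- unique(c("all", lab))
  out <- expand.grid(plot_id = plots$plot_id, week = weeks,
                     behavior = labs, stringsAsFactors = FALSE)
  out$segment_count <- 0L
  out$time_min <- 0
  for (i in seq_len(nrow(plots))) {
    chord <- segment_circle_intersection(segments$x0, segments$y0,
                                         segments$x1, segments$y1,
                                         plots$x[i], plots$y[i],
                                         plots$radius[i])
    tm <- time_in_plot(segments$x0, segments$y0, segments$x1, segments$y1,
                       plots$x[i], plots$y[i], plots$radius[i],
                       segments$duration_min)
    hit <- chord > 0 | tm > 0   # positive chord, or stationary point inside
    if (!any(hit)) next
    for (lb in labs) {
      sel <- hit & (lb == "all" | lab == lb)
      if (!any(sel)) next
      cnt <- table(factor(week[sel], levels = weeks))
      tmw <- tapply(tm[sel], factor(week[sel], levels = weeks), sum)
      tmw[is.na(tmw)] <- 0
      idx <- out$plot_id == plots$plot_id[i] & out$behavior == lb
      out$segment_count[idx] <- out$segment_count[idx] + as.integer(cnt)
      out$time_min[idx] <- out$time_min[idx] + as.numeric(tmw)
    }
  }
  out
}

#' Full presence table per plot and week
#'
#' Merges fix counts, segment counts and allocated time into one record per
#' plot x week (x behavior class when labels are given).
#'
#' @param fixes Resampled fix data frame.
#' @param segments Segment data frame.
#' @param plots Plot data frame.
#' @param start_date First day of week 1.
#' @param fix_behavior,segment_behavior Optional behavior labels.
#' @return Data frame `plot_id`, `week`, `behavior`, `fix_count`,
#'   `segment_count`, `time_min`.
#' @export
presence_table <- function(fixes, segments, plots, start_date,
                           fix_behavior = NULL, segment_behavior = NULL) {
  fc <- count_fixes(fixes, plots, start_date, fix_behavior)
  sc <- count_segments(segments, plots, start_date, segment_behavior)
  out <- merge(fc, sc, by = c("plot_id", "week", "behavior"), all = TRUE)
  for (cc in c("fix_count", "segment_count", "time_min"))
    out[[cc]][is.na(out[[cc]])] <- 0
  out[order(out$behavior, out$week, out$plot_id), ]
}

#' Accumulate presence records over weeks or units
#'
#' Exact sums of the three indicators by the requested grouping; summing
#' weekly records reproduces a single-pass total.
#'
#' @param records Presence data frame (from [presence_table()]).
#' @param by Grouping columns (default `"plot_id"`, i.e. totals over weeks).
#' @return Aggregated data frame.
#' @export
accumulate_presence <- function(records, by = "plot_id") {
  num <- intersect(c("fix_count", "segment_count", "time_min"),
                   names(records))
  agg <- stats::aggregate(records[num], records[by], sum)
  agg[do.call(order, agg[by]), , drop = FALSE]
}
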