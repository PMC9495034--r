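# Speed-based behavior classification and herd-level metrics. Cattle spend
# on average 57.5% of their time resting (incl. rumination), 40% grazing and
# 2.5% walking, so the 57.5th and 97.5th percentiles of the pooled
# segment-speed distribution separate the three classes.

#' Fit behavior speed thresholds
#'
#' Thresholds are the 57.5th and 97.5th percentiles of the pooled average
#' speeds between consecutive fixes (linear-interpolation percentile
#' definition, [stats::quantile()] type 7).
#'
#' @param speeds Numeric vector of segment speeds (m/min), pooled across all
#'   animals and the whole period; at least 100 values.
#' @param probs Percentile pair (defaults `c(0.575, 0.975)`).
#' @return A `behavior_thresholds` object with `t1` (resting/grazing) and
#'   `t2` (grazing/walking) in m/min.
#' @export
fit_thresholds <- function(speeds, probs = c(0.575, 0.975)) {
  if (length(speeds) < 100)
    stop("need at least 100 pooled speeds to fit behavior thresholds")
  if (any(speeds < 0)) stop("speeds must be nonnegative")
  q <- stats::quantile(speeds, probs, type = 7, names = FALSE)
  structure(list(t1 = q[1], t2 = q[2], probs = probs, n = length(speeds)),
            class = "behavior_thresholds")
}

#' @export
print.behavior_thresholds <- function(x, ...) {
  cat(sprintf(paste0("behavior thresholds (percentiles %.1f/%.1f of %d",
                     " speeds): resting < %.3f <= grazing < %.3f <= walking",
                     " m/min\n"),
              100 * x$probs[1], 100 * x$probs[2], x$n, x$t1, x$t2))
  invisible(x)
}

#' Classify segment speeds into behaviors
#'
#' `speed < t1` is resting, `t1 <= speed < t2` grazing, `speed >= t2`
#' walking (at an exact threshold the upper class wins).
#'
#' @param speed Numeric vector of speeds (m/min), nonnegative.
#' @param thresholds A [fit_thresholds()] object.
#' @return Character vector of labels.
#' @export
classify_behavior <- function(speed, thresholds) {
  if (any(speed < 0, na.rm = TRUE)) stop("negative speed")
  ifelse(speed < thresholds$t1, "resting",
         ifelse(speed < thresholds$t2, "grazing", "walking"))
}

#' Daily activity profile
#'
#' Mean trajectory-segment length per time-of-day slot (48 slots for 30-min
#' segments), optionally per group (animal or season). With exactly two
#' groups, a per-slot Welch two-sample comparison is added.
#'
#' @param segments Segment data frame (needs `slot`, `length_m`).
#' @param group Optional grouping vector (length `nrow(segments)`).
#' @param n_slots Number of slots per day (default 48).
#' @return Data frame `slot`, `group`, `mean_length_m`, `sd_length_m`, `n`;
#'   with two groups also a per-slot `p_value` (Welch) replicated across the
#'   slot's rows.
#' @export
activity_profile <- function(segments, group = NULL, n_slots = 48) {
  g <- if (is.null(group)) rep("all", nrow(segments)) else as.character(group)
  slot <- factor(segments$slot, levels = seq_len(n_slots))
  key <- interaction(slot, g, drop = FALSE)
  mean_l <- tapply(segments$length_m, key, mean)
  sd_l <- tapply(segments$length_m, key, stats::sd)
  n <- tapply(segments$length_m, key, length)
  parts <- do.call(rbind, strsplit(names(mean_l), ".", fixed = TRUE))
  out <- data.frame(slot = as.integer(parts[, 1]), group = parts[, 2],
                    mean_length_m = as.numeric(mean_l),
                    sd_length_m = as.numeric(sd_l),
                    n = ifelse(is.na(n), 0L, as.integer(n)))
  groups <- unique(g)
  if (length(groups) == 2) {
    out$p_value <- NA_real_
    for (s in seq_len(n_slots)) {
      a <- segments$length_m[segments$slot == s & g == groups[1]]
      b <- segments$length_m[segments$slot == s & g == groups[2]]
      if (length(a) >= 2 && length(b) >= 2)
        out$p_value[out$slot == s] <- stats::t.test(a, b)$p.value
    }
  }
  out[order(out$group, out$slot), ]
}

#' Herd dispersal at synchronized timestamps
#'
#' At each timestamp where every device reports (guaranteed on retained days
#' after resampling), the herd centroid is the arithmetic mean of positions
#' and dispersal is each animal's Euclidean distance to it. Timestamps with
#' missing animals are skipped and logged in the result.
#'
#' @param fixes Resampled fix data frame.
#' @param devices All device ids (defaults to those seen).
#' @return List with `records` (`timestamp`, `device_id`, `distance_m`,
#'   `herd_mean_m`) and `skipped` (timestamps missing some device).
#' @export
herd_dispersal <- function(fixes, devices = unique(fixes$device_id)) {
  parts <- split(seq_len(nrow(fixes)), fixes$timestamp)
  recs <- vector("list", length(parts))
  skipped <- as.POSIXct(character(), tz = "UTC")
  for (k in seq_along(parts)) {
    ii <- parts[[k]]
    if (!setequal(fixes$device_id[ii], devices) ||
        length(ii) != length(devices)) {
      skipped <- c(skipped, fixes$timestamp[ii[1]])
      next
    }
    cx <- mean(fixes$x[ii]); cy <- mean(fixes$y[ii])
    d <- sqrt((fixes$x[ii] - cx)^2 + (fixes$y[ii] - cy)^2)
    recs[[k]] <- data.frame(timestamp = fixes$timestamp[ii],
                            device_id = fixes$device_id[ii],
                            distance_m = d, herd_mean_m = mean(d))
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  list(records = records, skipped = skipped)
}

#' Meteorological season of a date
#'
#' Calendar meteorological seasons of the northern hemisphere (winter =
#' Dec-Feb, spring = Mar-May, summer = Jun-Aug, autumn = Sep-Nov), used to
#' group weeks for seasonal contrasts.
#'
#' @param date Date vector (or coercible).
#' @return Character vector of season names.
#' @export
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "autumn", "autumn", "autumn", "winter")[m]
}
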