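# Readers and writers for the interchange formats used by the pipeline:
# comma-delimited fix/census/weather tables, ESRI ASCII grids, and GeoJSON
# vector layers in the local planar frame.

#' Read a GPS fix table
#'
#' Comma-delimited with header `device_id,timestamp,x,y[,source][,valid]`;
#' timestamps ISO-8601, parsed as UTC.
#'
#' @param path File path.
#' @return Data frame with `device_id`, `timestamp` (POSIXct UTC), `x`, `y`,
#'   and `source`/`valid` when present.
#' @export
read_fixes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("device_id", "timestamp", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fix table missing columns: ",
                         paste(miss, collapse = ", "))
  ts <- as.POSIXct(strptime(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  bad <- is.na(ts)
  if (any(bad))
    ts[bad] <- as.POSIXct(strptime(df$timestamp[bad], "%Y-%m-%d %H:%M:%S",
                                   tz = "UTC"))
  if (anyNA(ts)) stop("unparseable timestamp at row ",
                      which(is.na(ts))[1], " of ", path)
  for (cc in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v) && !anyNA(df[[cc]]))
      stop("non-numeric coordinate '", cc, "' at row ",
           which(is.na(v))[1], " of ", path)
    df[[cc]] <- v
  }
  df$timestamp <- ts
  df
}

#' Write a GPS fix table
#'
#' @param fixes Data frame as returned by [read_fixes()].
#' @param path File path.
#' @export
write_fixes <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(fixes$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' Standard 6-line header (ncols, nrows, xllcorner, yllcorner, cellsize,
#' NODATA_value) followed by rows north to south.
#'
#' @param path File path.
#' @return A [raster_layer()]; nodata cells carry the nodata value.
#' @export
read_raster <- function(path) {
  lines <- readLines(path, n = 6)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ASCII grid header missing: ",
                         paste(miss, collapse = ", "))
  if (!is.finite(hdr$cellsize) || hdr$cellsize <= 0)
    stop("invalid cellsize in ASCII grid header")
  vals <- scan(path, skip = 6, quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop("ASCII grid body does not match header dimensions")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  raster_layer(grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                         hdr$nrows, hdr$ncols),
               m, nodata = hdr$nodata_value)
}

#' Write an ESRI ASCII grid
#'
#' @param layer A numeric [raster_layer()].
#' @param path File path.
#' @export
write_raster <- function(layer, path) {
  g <- layer$grid
  hdr <- c(paste("ncols", g$n_cols), paste("nrows", g$n_rows),
           paste("xllcorner", format(g$origin_x, digits = 15)),
           paste("yllcorner", format(g$origin_y, digits = 15)),
           paste("cellsize", format(g$cell_size, digits = 15)),
           paste("NODATA_value", format(layer$nodata, digits = 15)))
  body <- apply(layer$values, 1, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write paddock and sampling-plot layout as GeoJSON
#'
#' Coordinates are meters of the local planar frame; plot radius is stored as
#' a feature property.
#'
#' @param pad A [paddock()].
#' @param plots Data frame with `plot_id`, `x`, `y`, `radius`.
#' @param path File path.
#' @export
write_layout <- function(pad, plots, path) {
  ring <- rbind(pad$fence, pad$fence[1, , drop = FALSE])
  feats <- list(
    list(type = "Feature",
         properties = list(kind = "fence", area_m2 = pad$area),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) c(ring[i, 1], ring[i, 2]))))),
    list(type = "Feature",
         properties = list(kind = "water"),
         geometry = list(type = "Point",
                         coordinates = c(pad$water_point[1],
                                         pad$water_point[2]))))
  for (i in seq_len(nrow(plots))) {
    feats[[length(feats) + 1]] <- list(
      type = "Feature",
      properties = list(kind = "plot", plot_id = plots$plot_id[i],
                        radius = plots$radius[i]),
      geometry = list(type = "Point",
                      coordinates = c(plots$x[i], plots$y[i])))
  }
  obj <- list(type = "FeatureCollection", crs_note = "local planar meters",
              features = feats)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read paddock and sampling-plot layout from GeoJSON
#'
#' @param path File written by [write_layout()] (or equivalent).
#' @return List with `paddock` and `plots` (data frame).
#' @export
read_layout <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  fence <- NULL; water <- NULL
  plots <- list()
  for (f in obj$features) {
    kind <- f$properties$kind
    if (identical(kind, "fence")) {
      ring <- f$geometry$coordinates[[1]]
      fence <- do.call(rbind, lapply(ring, function(p)
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    } else if (identical(kind, "water")) {
      water <- as.numeric(unlist(f$geometry$coordinates))
    } else if (identical(kind, "plot")) {
      plots[[length(plots) + 1]] <- data.frame(
        plot_id = f$properties$plot_id,
        x = as.numeric(f$geometry$coordinates[[1]]),
        y = as.numeric(f$geometry$coordinates[[2]]),
        radius = f$properties$radius)
    }
  }
  if (is.null(fence) || is.null(water))
    stop("layout file lacks a fence or water feature")
  list(paddock = paddock(fence, water), plots = do.call(rbind, plots))
}

#' Read or write simple study tables
#'
#' Thin CSV wrappers for the weekly dung census (`plot_id, week, count`) and
#' daily weather table; they validate required columns.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_census <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("plot_id", "week", "count"), names(df))
  if (length(miss)) stop("census table missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_census
#' @param census Data frame with `plot_id`, `week`, `count`.
#' @export
write_census <- function(census, path) {
  utils::write.csv(census, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_census
#' @export
read_weather <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("date", "tavg", "tmax", "tmin", "rain", "rh",
                    "radiation", "wind"), names(df))
  if (length(miss)) stop("weather table missing columns: ",
                         paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  df
}

#' @rdname read_census
#' @param weather Daily weather data frame.
#' @export
write_weather <- function(weather, path) {
  out <- weather
  out$date <- format(as.Date(weather$date))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
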