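# Planar geometry primitives and environment-layer computation.
# All coordinates are planar meters in a local projected frame; raster value
# matrices are stored in ESRI ASCII order (row 1 = northernmost row).

#' Define a raster grid
#'
#' A grid is anchored at its lower-left corner and uses square cells.
#'
#' @param origin_x,origin_y Lower-left corner of the grid (m).
#' @param cell_size Cell edge length (m), positive.
#' @param n_rows,n_cols Grid dimensions, at least 1.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size, n_rows, n_cols) {
  stopifnot(is.finite(origin_x), is.finite(origin_y),
            cell_size > 0, n_rows >= 1, n_cols >= 1)
  structure(list(origin_x = origin_x, origin_y = origin_y,
                 cell_size = cell_size,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "grid_spec")
}

#' Create a raster layer on a grid
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix of dimension `n_rows x n_cols`, row 1 being the
#'   northernmost row. Categorical layers store integer category codes.
#' @param nodata Missing-value marker used on disk (default -9999).
#' @param categories Optional character vector of category labels; when given
#'   the layer is treated as categorical and values index into this set.
#' @return A `raster_layer` object.
#' @export
raster_layer <- function(grid, values, nodata = -9999, categories = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("values shape does not match grid (", grid$n_rows, "x", grid$n_cols, ")")
  if (!is.null(categories)) {
    codes <- values[is.finite(values)]
    if (length(codes) && (any(codes < 1) || any(codes > length(categories))))
      stop("categorical values outside declared label set")
  }
  structure(list(grid = grid, values = values, nodata = nodata,
                 categories = categories),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  g <- x$grid
  cat(sprintf("raster_layer: %d x %d cells of %g m, origin (%g, %g)%s\n",
              g$n_rows, g$n_cols, g$cell_size, g$origin_x, g$origin_y,
              if (is.null(x$categories)) "" else
                paste0(", categories: ", paste(x$categories, collapse = "/"))))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return List with `x` (length `n_cols`, west to east) and `y` (length
#'   `n_rows`, north to south, matching matrix row order).
#' @export
cell_centers <- function(grid) {
  cs <- grid$cell_size
  list(x = grid$origin_x + (seq_len(grid$n_cols) - 0.5) * cs,
       y = grid$origin_y + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * cs)
}

#' Locate points on a grid
#'
#' Cell membership is half-open: a point on a cell's west/south edge belongs to
#' that cell; the grid's east/north outer edges are outside.
#'
#' @param grid A [grid_spec()].
#' @param x,y Point coordinates (m), recycled to common length.
#' @return Data frame with columns `row`, `col` (NA outside the grid).
#' @export
cell_index <- function(grid, x, y) {
  cs <- grid$cell_size
  col <- floor((x - grid$origin_x) / cs) + 1
  row_from_bottom <- floor((y - grid$origin_y) / cs) + 1
  row <- grid$n_rows - row_from_bottom + 1
  bad <- !is.finite(x) | !is.finite(y) |
    col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations
#'
#' @param layer A [raster_layer()].
#' @param x,y Point coordinates (m).
#' @param label For categorical layers, return labels instead of codes.
#' @return Vector of cell values; NA for points outside the grid or on nodata.
#' @export
values_at <- function(layer, x, y, label = FALSE) {
  idx <- cell_index(layer$grid, x, y)
  v <- rep(NA_real_, nrow(idx))
  ok <- !is.na(idx$row)
  v[ok] <- layer$values[cbind(idx$row[ok], idx$col[ok])]
  v[!is.na(v) & v == layer$nodata] <- NA
  if (label && !is.null(layer$categories)) {
    out <- rep(NA_character_, length(v))
    out[!is.na(v)] <- layer$categories[v[!is.na(v)]]
    return(out)
  }
  v
}

# finite-difference gradient of a DEM: central differences in the interior,
# one-sided at borders; returns list(gx = east, gy = north derivative)
dem_gradient <- function(dem) {
  V <- dem$values
  cs <- dem$grid$cell_size
  nr <- nrow(V); nc <- ncol(V)
  if (nr < 3 || nc < 3) stop("DEM must have at least 3x3 cells")
  gx <- matrix(NA_real_, nr, nc)
  gx[, 2:(nc - 1)] <- (V[, 3:nc] - V[, 1:(nc - 2)]) / (2 * cs)
  gx[, 1] <- (V[, 2] - V[, 1]) / cs
  gx[, nc] <- (V[, nc] - V[, nc - 1]) / cs
  # row 1 is north: northward derivative is (row above - row below)
  gy <- matrix(NA_real_, nr, nc)
  gy[2:(nr - 1), ] <- (V[1:(nr - 2), ] - V[3:nr, ]) / (2 * cs)
  gy[1, ] <- (V[1, ] - V[2, ]) / cs
  gy[nr, ] <- (V[nr - 1, ] - V[nr, ]) / cs
  list(gx = gx, gy = gy)
}

#' Terrain slope in percent
#'
#' Slope is `100 * ||grad z||` from finite differences (central differences in
#' the interior, one-sided at borders).
#'
#' @param dem Elevation raster (m), at least 3x3 cells.
#' @return Raster of slope (%), nonnegative.
#' @export
slope_percent <- function(dem) {
  g <- dem_gradient(dem)
  raster_layer(dem$grid, 100 * sqrt(g$gx^2 + g$gy^2), nodata = dem$nodata)
}

#' Downhill aspect azimuth
#'
#' Azimuth of the steepest descent direction, degrees clockwise from north in
#' `[0, 360)`. Cells with zero gradient get 0 (they are below any sensible
#' flat-terrain threshold anyway).
#'
#' @param dem Elevation raster (m).
#' @return Raster of azimuth (degrees).
#' @export
aspect_azimuth <- function(dem) {
  g <- dem_gradient(dem)
  az <- (atan2(-g$gx, -g$gy) * 180 / pi) %% 360
  az[g$gx == 0 & g$gy == 0] <- 0
  raster_layer(dem$grid, az, nodata = dem$nodata)
}

#' Insolation class from terrain
#'
#' Cells with slope below `flat_threshold_pct` are labelled `Flat` (no effect
#' of insolation); steeper cells are binned by downhill azimuth into four 90
#' degree sectors centered on the cardinal directions: North `[315, 45)`,
#' East `[45, 135)`, South `[135, 225)`, West `[225, 315)`. A slope exactly at
#' the threshold is assigned an aspect class.
#'
#' @param dem Elevation raster (m).
#' @param slope Slope raster (%), same grid as `dem`.
#' @param flat_threshold_pct Flat-terrain slope threshold (%, default 10).
#' @return Categorical raster with labels Flat/North/East/South/West.
#' @export
insolation_class <- function(dem, slope, flat_threshold_pct = 10) {
  if (!identical(unclass(dem$grid), unclass(slope$grid)))
    stop("dem and slope must share a grid")
  az <- aspect_azimuth(dem)$values
  cls <- matrix(NA_real_, nrow(az), ncol(az))
  sector <- ifelse(az >= 315 | az < 45, 2,          # North
            ifelse(az < 135, 3,                      # East
            ifelse(az < 225, 4, 5)))                 # South else West
  cls[] <- ifelse(slope$values < flat_threshold_pct, 1, sector)
  raster_layer(dem$grid, cls, nodata = dem$nodata,
               categories = c("Flat", "North", "East", "South", "West"))
}

#' Euclidean distance-to-water raster
#'
#' Distance from each cell centroid to the water point, meters.
#'
#' @param grid A [grid_spec()].
#' @param water_point Numeric length-2 vector `c(x, y)` (m).
#' @return Raster of distances (m).
#' @export
distance_to_water <- function(grid, water_point) {
  stopifnot(length(water_point) == 2, all(is.finite(water_point)))
  ctr <- cell_centers(grid)
  dx <- outer(rep(1, grid$n_rows), ctr$x - water_point[1])
  dy <- outer(ctr$y - water_point[2], rep(1, grid$n_cols))
  raster_layer(grid, sqrt(dx^2 + dy^2))
}

#' Block-aggregate a raster to a coarser grid
#'
#' Mean of `fact x fact` child cells; grid dimensions must be divisible by
#' `fact` so alignment is exact.
#'
#' @param layer A numeric [raster_layer()].
#' @param fact Aggregation factor (default 2, e.g. 5 m to 10 m cells).
#' @return Raster on the coarser grid.
#' @export
block_aggregate <- function(layer, fact = 2) {
  g <- layer$grid
  if (g$n_rows %% fact != 0 || g$n_cols %% fact != 0)
    stop("grid dimensions not divisible by aggregation factor")
  nr <- g$n_rows %/% fact; nc <- g$n_cols %/% fact
  v <- layer$values
  out <- matrix(0, nr, nc)
  for (i in seq_len(fact)) for (j in seq_len(fact))
    out <- out + v[seq(i, g$n_rows, by = fact), seq(j, g$n_cols, by = fact)]
  gg <- grid_spec(g$origin_x, g$origin_y, g$cell_size * fact, nr, nc)
  raster_layer(gg, out / fact^2, nodata = layer$nodata)
}

#' Summarize a raster layer over a circular sampling plot
#'
#' Area-weighted mean over the plot disc, estimated by a deterministic subcell
#' lattice (default 0.5 m spacing): lattice points inside the disc are mapped
#' to cells and averaged. Categorical layers return the majority label (ties
#' broken by category order).
#'
#' @param layer A [raster_layer()].
#' @param plot_x,plot_y Plot center (m).
#' @param radius Plot radius (m, default 5).
#' @param subcell Lattice spacing (m, default 0.5).
#' @return A single numeric value (or character label for categorical layers).
#' @export
plot_summary <- function(layer, plot_x, plot_y, radius = 5, subcell = 0.5) {
  stopifnot(radius > 0, subcell > 0)
  s <- seq(-radius + subcell / 2, radius - subcell / 2, by = subcell)
  pts <- expand.grid(dx = s, dy = s)
  pts <- pts[pts$dx^2 + pts$dy^2 <= radius^2, ]
  v <- values_at(layer, plot_x + pts$dx, plot_y + pts$dy)
  v <- v[!is.na(v)]
  if (!length(v)) stop("plot does not intersect raster extent")
  if (is.null(layer$categories)) return(mean(v))
  layer$categories[which.max(tabulate(v, nbins = length(layer$categories)))]
}

#' Factor category definitions
#'
#' Returns the ordered category set used to stratify the paddock by an
#' environmental factor, with a half-open binning convention (lower edge
#' inclusive, upper exclusive). Canopy cover has an exact-zero "0%" category.
#'
#' @param factor One of `"slope"`, `"insolation"`, `"canopy"`,
#'   `"distance_to_water"`.
#' @return A `factor_bins` object with elements `factor`, `labels`, and for
#'   numeric factors `breaks`.
#' @export
factor_bins <- function(factor = c("slope", "insolation", "canopy",
                                   "distance_to_water")) {
  factor <- match.arg(factor)
  out <- switch(factor,
    slope = list(breaks = c(-Inf, 5, 10, 20, Inf),
                 labels = c("<5%", "5-10%", "10-20%", ">20%")),
    insolation = list(breaks = NULL,
                      labels = c("Flat", "North", "East", "South", "West")),
    canopy = list(breaks = c(0, 25, 50, Inf),   # 0 is its own category
                  labels = c("0%", "0-25%", "25-50%", ">50%")),
    distance_to_water = list(breaks = c(-Inf, 50, 100, 200, Inf),
                             labels = c("<50 m", "50-100 m", "100-200 m",
                                        ">200 m")))
  structure(c(list(factor = factor), out), class = "factor_bins")
}

#' Assign values to factor categories
#'
#' @param value Numeric vector (or category labels for insolation).
#' @param bins A [factor_bins()] object.
#' @return Character vector of category labels.
#' @export
bin_factor <- function(value, bins) {
  stopifnot(inherits(bins, "factor_bins"))
  if (bins$factor == "insolation") {
    if (!all(value %in% bins$labels)) stop("unknown insolation label")
    return(as.character(value))
  }
  if (any(!is.finite(value))) stop("cannot bin non-finite values")
  if (bins$factor == "canopy") {
    if (any(value < 0)) stop("canopy cover cannot be negative")
    return(ifelse(value == 0, "0%",
           ifelse(value < 25, "0-25%",
           ifelse(value < 50, "25-50%", ">50%"))))
  }
  # half-open [lower, upper)
  idx <- findInterval(value, bins$breaks, left.open = FALSE,
                      rightmost.closed = FALSE)
  idx <- pmin(pmax(idx, 1L), length(bins$labels))
  bins$labels[idx]
}

#' Bin a numeric raster into a categorical raster
#'
#' @param layer Numeric [raster_layer()].
#' @param bins A [factor_bins()] object.
#' @return Categorical raster whose categories are `bins$labels`.
#' @export
bin_raster <- function(layer, bins) {
  lab <- bin_factor(as.vector(layer$values), bins)
  codes <- matrix(match(lab, bins$labels), nrow(layer$values), ncol(layer$values))
  raster_layer(layer$grid, codes, nodata = layer$nodata,
               categories = bins$labels)
}

#' Area fraction of each category of a categorical raster
#'
#' @param layer Categorical [raster_layer()].
#' @return Named numeric vector of fractions summing to 1 (nodata excluded).
#' @export
category_fractions <- function(layer) {
  stopifnot(!is.null(layer$categories))
  v <- layer$values[layer$values != layer$nodata & is.finite(layer$values)]
  n <- tabulate(v, nbins = length(layer$categories))
  stats::setNames(n / sum(n), layer$categories)
}

#' Aggregate daily weather records to study weeks
#'
#' Means of temperature, humidity, radiation and wind; rainfall is summed.
#' Weeks are 7-day windows aligned to the census start date; weeks with fewer
#' than 7 observed days are aggregated over the available days and flagged.
#'
#' @param daily Data frame with columns `date` (Date or ISO-8601 character),
#'   `tavg`, `tmax`, `tmin`, `rain`, `rh`, `radiation`, `wind`.
#' @param start_date First day of week 1 (Date or character).
#' @param n_weeks Optional number of weeks to keep.
#' @return Data frame per week: `week`, aggregated variables, `n_days`,
#'   `complete`.
#' @export
weekly_weather <- function(daily, start_date, n_weeks = NULL) {
  need <- c("date", "tavg", "tmax", "tmin", "rain", "rh", "radiation", "wind")
  miss <- setdiff(need, names(daily))
  if (length(miss)) stop("daily table missing columns: ",
                         paste(miss, collapse = ", "))
  d <- as.Date(daily$date)
  week <- floor(as.numeric(d - as.Date(start_date)) / 7) + 1
  keep <- week >= 1 & (if (is.null(n_weeks)) TRUE else week <= n_weeks)
  daily <- daily[keep, ]; week <- week[keep]
  if (!nrow(daily)) stop("no daily records fall in the study weeks")
  agg <- function(v, f) tapply(v, week, f)
  out <- data.frame(
    week = as.integer(names(agg(daily$tavg, mean))),
    tavg = as.numeric(agg(daily$tavg, mean)),
    tmax = as.numeric(agg(daily$tmax, mean)),
    tmin = as.numeric(agg(daily$tmin, mean)),
    rain = as.numeric(agg(daily$rain, sum)),
    rh = as.numeric(agg(daily$rh, mean)),
    radiation = as.numeric(agg(daily$radiation, mean)),
    wind = as.numeric(agg(daily$wind, mean)),
    n_days = as.integer(agg(daily$tavg, length)))
  out$complete <- out$n_days == 7L
  out[order(out$week), , drop = FALSE]
}

#' Weekly per-pixel NDVI means
#'
#' Pixelwise mean over the satellite scenes falling in each study week. Weeks
#' without any scene carry the last available weekly mean forward and are
#' flagged as filled.
#'
#' @param scene_dates Vector of scene dates (Date or character).
#' @param ndvi Matrix of per-pixel NDVI, one row per scene.
#' @param start_date First day of week 1.
#' @param n_weeks Number of study weeks.
#' @return List with `values` (matrix `n_weeks x n_pixels`) and `filled`
#'   (logical per week, TRUE where carried forward).
#' @export
weekly_ndvi <- function(scene_dates, ndvi, start_date, n_weeks) {
  if (!length(scene_dates)) stop("no NDVI scenes supplied")
  stopifnot(is.matrix(ndvi), nrow(ndvi) == length(scene_dates))
  week <- floor(as.numeric(as.Date(scene_dates) - as.Date(start_date)) / 7) + 1
  if (any(week < 1 | week > n_weeks))
    stop("scene date outside the study weeks")
  vals <- matrix(NA_real_, n_weeks, ncol(ndvi))
  for (w in unique(week))
    vals[w, ] <- colMeans(ndvi[week == w, , drop = FALSE])
  filled <- rep(FALSE, n_weeks)
  if (all(is.na(vals[1, ]))) {
    first <- which(!is.na(vals[, 1]))[1]
    for (w in seq_len(first - 1)) { vals[w, ] <- vals[first, ]; filled[w] <- TRUE }
  }
  for (w in seq_len(n_weeks)[-1]) if (all(is.na(vals[w, ]))) {
    vals[w, ] <- vals[w - 1, ]; filled[w] <- TRUE
  }
  list(values = vals, filled = filled)
}

#' Construct a paddock
#'
#' @param fence Two-column matrix of fence vertices (m), a simple closed
#'   polygon (first vertex need not be repeated).
#' @param water_point Numeric `c(x, y)` of the water trough, inside or on the
#'   fence.
#' @return A `paddock` object with `fence`, `area` (m2) and `water_point`.
#' @export
paddock <- function(fence, water_point) {
  stopifnot(is.matrix(fence), ncol(fence) == 2, nrow(fence) >= 3)
  if (all(fence[1, ] == fence[nrow(fence), ])) fence <- fence[-nrow(fence), ]
  area <- polygon_area(fence)
  if (area <= 0) stop("fence polygon has non-positive area")
  if (!point_in_polygon(water_point[1], water_point[2], fence))
    stop("water point must lie inside or on the fence")
  structure(list(fence = fence, area = area, water_point = water_point),
            class = "paddock")
}

# shoelace formula, vertices in either orientation
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Test points against a polygon (boundary inclusive)
#'
#' Ray-casting point-in-polygon for planar coordinates; points on an edge or
#' vertex count as inside.
#'
#' @param px,py Point coordinates (vectors).
#' @param poly Two-column vertex matrix (closed implicitly).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  finite <- is.finite(px) & is.finite(py)
  for (e in seq_len(n)) {
    x1 <- poly[e, 1]; y1 <- poly[e, 2]
    j <- if (e == n) 1L else e + 1L
    x2 <- poly[j, 1]; y2 <- poly[j, 2]
    on_edge <- on_edge |
      (pmin(x1, x2) - 1e-9 <= px & px <= pmax(x1, x2) + 1e-9 &
       pmin(y1, y2) - 1e-9 <= py & py <= pmax(y1, y2) + 1e-9 &
       abs((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)) <=
         1e-9 * (abs(x2 - x1) + abs(y2 - y1) + 1))
    cross <- (y1 > py) != (y2 > py)
    if (any(cross)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      flip <- cross & px < xint
      inside[flip] <- !inside[flip]
    }
  }
  (inside | on_edge) & finite
}
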