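# shared fixtures: all data is generated in code, nothing is read from disk

# small but complete synthetic study, built once per test run
small_config <- function(seed = 11L, ...) {
  sim_config(seed = seed, n_weeks = 2L, n_animals = 3L, ...)
}

.study_cache <- new.env(parent = emptyenv())
small_study <- function() {
  if (is.null(.study_cache$s)) .study_cache$s <- simulate_study(small_config())
  .study_cache$s
}

# raster whose values form the plane z = a*x + b*y + c over cell centers
plane_raster <- function(a, b, c = 0, n_rows = 8, n_cols = 10,
                         cell_size = 5) {
  g <- grid_spec(0, 0, cell_size, n_rows, n_cols)
  ctr <- cell_centers(g)
  X <- outer(rep(1, n_rows), ctr$x)
  Y <- outer(ctr$y, rep(1, n_cols))
  raster_layer(g, a * X + b * Y + c)
}

# minimal fix table on the 30-min grid for one device-day
grid_fixes <- function(device = "A01", day = "2021-02-15",
                       x = NULL, y = NULL, minutes = seq(0, 1430, 30)) {
  n <- length(minutes)
  if (is.null(x)) x <- seq(0, by = 10, length.out = n)
  if (is.null(y)) y <- rep(0, n)
  data.frame(device_id = device,
             timestamp = as.POSIXct(paste(day, "00:00:00"),
                                    tz = "UTC") + minutes * 60,
             x = x, y = y)
}

rect_paddock <- function(w = 660, h = 350, water = c(w - 15, 15)) {
  paddock(cbind(c(0, w, w, 0), c(0, 0, h, h)), water)
}
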