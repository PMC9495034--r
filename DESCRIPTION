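Package: dungscape
Title: Linking GPS Collar Tracking of Cattle to Dung Distribution on Pasture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate the distribution of grazing cattle, monitored with
    low-frequency commercial GPS collars, to the spatial and temporal pattern of
    dung deposition on a fenced paddock. Implements trajectory preprocessing
    (fence filtering, gap-day exclusion, resampling to standardized 30-min
    timestamps), three plot-level animal-presence indicators (fix counts,
    intersecting trajectory-segment counts, and time allocated from
    segment-circle intersections), speed-percentile behavior classification,
    herd dispersal and daily activity profiles, Jacobs selection indices per
    environmental factor, and stepwise regression of weekly per-plot dung counts
    on presence indicators and environmental covariates with spatial and temporal
    aggregation, 70/30 validation and hotspot detection. A seeded synthetic-data
    generator emulates the full study design (paddock, terrain layers, correlated
    random-walk trajectories with diurnal behavior schedules, GPS dropout, and
    presence-driven dung deposition) with known ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
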