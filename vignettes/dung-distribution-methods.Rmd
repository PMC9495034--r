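---
title: "Modelling cattle dung distribution from commercial GPS collars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cattle dung distribution from commercial GPS collars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dungscape)
```

## The problem

On continuously grazed paddocks, cattle concentrate their activity — and
their dung — in a few preferred areas: flat ground, the surroundings of the
water trough, habitual resting places. The resulting nutrient hotspots
degrade soil and water and waste the fertilizing value of manure elsewhere.
Commercial GPS collars transmit a position every 30 minutes; the question
this package addresses is whether that coarse, gappy signal, combined with
freely available environmental layers (terrain, canopy cover, weather,
NDVI), suffices to model the weekly spatial pattern of dung deposition and
to flag hotspots as they form.

The package implements the full chain: trajectory preprocessing, three
plot-level animal-presence indicators, speed-based behavior classification,
use-vs-availability selection indices, and stepwise regression of weekly
per-plot dung counts with spatial/temporal aggregation, validation and
hotspot detection. A seeded synthetic-data generator reproduces the study
design end to end with known ground truth, so every stage is testable
against the parameters that generated the data.

## Study design emulated by the generator

The design the defaults encode: a herd of 7 collared animals on a fenced
23.1 ha paddock (660 m x 350 m in the synthetic frame) with a single water
trough at the southeastern end; 90 circular sampling plots of 5 m radius
(78.5 m^2^) roughly 50 m apart, censused weekly for 19 weeks from
mid-February to early July; GPS fixes scheduled every 30 min with dropout;
environment described by slope (%), insolation class, canopy cover (%) and
distance to water on a 10-m grid.

### Plot placement

Ninety plot centers with a 50-m minimum separation inside 23.1 ha amount to
a packing density of about 0.77 exclusion discs per unit area — beyond what
independent random placement with rejection can reach (random sequential
adsorption of discs jams near 0.55). Real field layouts of this density are
laid out on a survey grid, so the generator places plots on a hexagonal
lattice with 52 m spacing, jitters each center by up to 0.5 m per
coordinate (guaranteeing the 50 m bound), and keeps a random subset of the
requested size. Layout is deterministic given the seed.

### Terrain, canopy and distance layers

The DEM is a sum of smooth Gaussian hills (broad relief of 6-15 m amplitude
over 120-250 m, plus a few sharper knolls) over a gentle base gradient,
chosen so the binned slope mix spans a sizeable flat fraction (<10%), a
dominant 10-20% class and some cells above 20%, as on the real farm. Slope
is computed by central finite differences (one-sided at borders) — the
slope operator is deliberately simple and documented so oracle tests can
reproduce it analytically; aspect is the downhill azimuth binned into four
90-degree sectors centered on the cardinal directions, with cells under 10%
slope classed as flat (a slope of exactly 10% receives an aspect class).
Canopy cover is a clumped random field rescaled by a one-dimensional root
search so its paddock mean matches the target 24.7% while keeping a
treeless fraction. The 5-m DEM products are block-averaged 2x2 onto the
10-m analysis grid, and grids are constructed so that alignment is exact.

### Movement model

Cattle movement is a discrete-time (1-min) correlated random walk with
three behavioral states — resting, grazing, walking — drawn per 30-min
interval from a diurnal schedule with two grazing bouts (06:00-10:00 and
17:00-21:00 by default). Each state has a mean speed (0.4 / 3 / 12 m/min)
and a turning-angle concentration; step lengths get a lognormal multiplier
(sdlog 0.3). Two heading biases act on top of the turn: attraction toward
the water trough, with a weight that follows a logistic ramp of weekly mean
temperature between roughly 15 and 22 degrees C (cattle seek water on warm
days), and attraction toward the herd centroid that is strongest while
resting (cattle bunch up to rest and spread out to graze — this is what
makes herd dispersal higher during grazing bouts, a pattern the behavior
module's tests check). Positions reflect at the fence. The walker is
implemented in C++ for speed; it draws from R's RNG so a seed fixes the
trajectory exactly.

These defaults are calibrated qualitatively — plausible speeds and bout
timing for grazing cattle — and are not claimed to match any particular
herd. The speed means are chosen so the pooled 30-min-average speed
distribution yields sensible percentile thresholds.

### GPS observation and dung deposition

Fixes sample the true path every 30 min with Bernoulli dropout (default
12%), uniform timestamp jitter of +/-2 min (devices are not synchronized),
and a 1% chance of a gross error that reports a position outside the fence;
injected errors are flagged in the ground truth so the fence filter's
recall is measurable exactly.

Dung events per 30-min step are Poisson with rate `base(state) *
exp(-0.002 * dist_water) * exp(-0.8 * canopy_fraction)`, with base rates
0.55 / 0.28 / 0.08 events per step for resting / grazing / walking —
deposition concentrates where animals rest, near water, and away from tree
cover. The totals come to roughly 10-15 events per animal-day; published
defecation-rate magnitudes for cattle are of order 10 per day, and the
default is an order-of-magnitude choice, not a measured value. Planted
hotspots are available for detectability experiments: `hotspot_plots`
multiplies the rate inside chosen plot discs, and `select_hotspot_plots()`
implements the planting rule — the best-visited plot in the 50-150 m
distance band plus its nearest same-unit band neighbor, so the pair sits in
one high-traffic 4-plot unit the way real hotspot pairs form beside the
water approach. The default multiplier (40 at the 19-week study scale,
lower values for longer runs) was set once so planted-plot totals land on
the few-hundred-droppings scale that field hotspots reach.

## Preprocessing

Four steps, in order:

1. **Fence filter** — fixes outside the paddock polygon are GPS errors and
   are removed (point-in-polygon is boundary-inclusive).
2. **Gap-day exclusion** — a calendar day is dropped for *all* devices if
   any device has three consecutive hours without data. Gaps are measured
   on true timestamps between consecutive fixes and against both midnight
   boundaries; a gap of exactly 180 min excludes, 179 min retains. A
   device with no fixes at all on a day excludes the day.
3. **Resampling** — positions are linearly interpolated in time onto the
   30-min grid anchored at midnight. Before the first and after the last
   raw fix of a day the nearest raw position is held rather than
   extrapolated, so every retained day yields exactly 48 fixes; whether the
   original study interpolated or dropped such day-edge stubs is not
   stated, and the hold rule is this package's choice.
4. **Segments** — consecutive on-grid fixes are joined into straight
   segments of 30 min each (47 per day), carrying length and average speed.

Days are calendar days in UTC in the synthetic frame; with real data the
time zone is whatever the fix timestamps are expressed in.

## Presence indicators

Three per-plot, per-week measures of herd presence:

* **Fix count** — a fix belongs to a plot iff its distance to the center is
  at most the radius (boundary inclusive).
* **Segment count** — a segment counts iff its chord through the plot disc
  has positive length (a tangent does not count), or it is a stationary
  point inside the disc.
* **Time** — a segment of length `x` represents 30 min at constant speed,
  so an intersection chord of length `y` contributes `30 * y / x` minutes.
  The chord is computed analytically from the line-circle quadratic with
  the parameter interval clipped to the segment. At `x = 0` the formula is
  undefined; the package allocates the full 30 min if the stationary point
  is inside the plot (a resting animal inside the plot spends the interval
  there) and 0 otherwise.

The boundary conventions (fix inclusive, segment strictly positive chord)
are chosen so the point- and segment-based measures agree in the limit of a
shrinking segment. Tests check the time allocation against a dense
Monte-Carlo oracle (10^4^ points per segment) to half a minute.

## Behavior classification

Cattle spend on average 57.5% of their time resting (including rumination),
40% grazing and 2.5% walking, so the 57.5th and 97.5th percentiles of the
pooled segment-speed distribution serve as class boundaries: below the
first percentile is resting, between them grazing, at or above the second
walking. Percentiles use the linear-interpolation definition
(`quantile(type = 7)`), pooled over all animals and the full period; a
switch to per-animal pooling is a one-line change in user code since the
fitting function takes a plain speed vector. At an exact threshold the
upper class wins, which keeps the walking class non-empty under heavy ties
(in the fully degenerate all-equal pool both thresholds coincide and
everything classifies as walking).

Herd-level metrics require synchronized positions, which is precisely what
resampling provides: herd dispersal is each animal's distance to the
positional centroid at a shared timestamp, and daily activity profiles are
mean segment lengths per 30-min slot. Seasonal contrasts use per-slot Welch
two-sample tests; the original analysis does not name its test, so the
reproduction is in kind, not in letter.

## Selection indices

For each environmental factor the paddock is partitioned into the field's
standard categories (slope <5 / 5-10 / 10-20 / >20%; insolation
Flat/N/E/S/W; canopy 0 / 0-25 / 25-50 / >50%; distance to water <50 /
50-100 / 100-200 / >200 m; half-open bins, lower edge inclusive, canopy
zero its own category). Weekly use fractions `r` come from fix or dung
positions assigned to 10-m cells; availability `p` is the category's cell
fraction. The Jacobs selection index

$$JSI = \frac{r - p}{r + p - 2rp} \in [-1, 1]$$

is antisymmetric in `r` and `p`, strictly increasing in `r`, and defined as
0 when `r = p` (continuity through the 0/0 corner). Summaries report the
weekly mean and SD per category, across-category letters from
Kruskal-Wallis followed by pairwise Wilcoxon rank-sum tests
(Holm-adjusted), and fixes-vs-droppings stars from a paired Wilcoxon
signed-rank test on matching weeks. The letter display is computed from
maximal cliques of the non-significance graph; with at most five categories
per factor, brute-force enumeration is exact and dependency-free.

## The dung model

The response is the number of droppings per plot and week; candidates are
one GPS presence indicator (fixes, segments or minutes — each offered both
as its total and its resting-only version, with whichever enters better
blocking the other) plus the environmental covariates CC (canopy cover
fraction), DW (distance to water, m), IN (insolation azimuth, degrees —
per-plot IN is the mean downhill azimuth over non-flat subcells, 0 for
fully flat plots), NDVI, SL (slope, %), TA and TM (weekly mean and maximum
temperature).

Selection is bidirectional stepwise ordinary least squares with partial-F
tests: enter below p = 0.05, remove above p = 0.10 — the classic
statistical-package dialect; the original analysis states only "stepwise"
with 0.05 significance, so the removal threshold and the bidirectional
order are this package's choice, and a dropped variable may not re-enter
(which guarantees termination). Counts are fitted by OLS rather than a
Poisson GLM deliberately: interpretability of the linear coefficients is
the point of the exercise, and the study being reproduced made the same
trade-off.

Aggregation: spatially, plots are grouped into units of four mutual
neighbors by a greedy deterministic rule (lowest remaining id seeds a group
with its three nearest unassigned plots); temporally, weeks form
consecutive 6-week blocks aligned to week 1, with the incomplete trailing
block dropped (19 = 3 x 6 + 1). Counts and presence are summed, covariates
averaged, and MAEs are always re-expressed per plot and week by dividing
the unit-level MAE by plots-per-unit x weeks-per-unit (24 for the 4-plot /
6-week configuration) — the "per plot and week" normalization is stated
but not defined in the source material, and division by the unit size is
this package's reading.

Validation: the temporal scheme calibrates on the first 70% of temporal
units, floored — 13 of 19 weeks, matching the published week 1-13 / 14-19
split — and validates on the rest; the spatial scheme draws a seeded
uniform 70/30 plot partition. Hotspot calls flag units whose predicted
count exceeds 100 droppings (the published rule at the 4-plot / 6-week
scale); a relative rule (above five times the median) is available.

## What the synthetic tests do and do not show

The generator reproduces the *structure* of the study — sampling design,
observation process, diurnal behavior, presence-driven deposition with
known covariate effects — so recovery tests can verify that the pipeline
measures what it claims to measure: sign recovery of the presence and
distance-to-water effects, exact resampling contracts (48 fixes/day, 336
per full week), conservation between events and censuses, and the
detectability gap between models with and without GPS data on planted
hotspots.

It does not reproduce real cattle: there is no memory of good patches, no
social hierarchy, no shade-seeking distinct from canopy, no pasture
depletion feedback, and weather is a smooth seasonal ramp with noise.
Passing tests therefore validate the computational pipeline and the
qualitative mechanisms, not any field-level effect size. Numerical results
on real collar data will differ, and the honest check there is the one the
pipeline itself provides: calibration/validation MAE on held-out weeks and
plots.

## Numerical choices and degenerate inputs

* Plot-level averages of raster layers use a deterministic 0.5-m subcell
  lattice (no Monte-Carlo noise in per-plot covariates).
* The slope operator needs at least a 3x3 raster; categorical layers
  declare their label set and summarize by majority.
* A raster value equal to the nodata marker (-9999) is treated as missing
  everywhere.
* `segment_circle_intersection` returns 0 for tangency (discriminant 0)
  and for zero-length segments; time allocation handles the stationary
  case by containment.
* Weeks with zero use points are skipped (with a message) in selection;
  zero-variance candidates are silently dropped from stepwise; correlation
  against a constant series is NA, flagged, never an error.
* All randomness flows from one root seed with fixed per-stage offsets, so
  any stage can be regenerated independently and identically.

## Known limitations

* The movement and deposition models are the package authors' stand-ins;
  their parameters are study conditions, not estimates.
* OLS on counts can predict negative values near zero presence; the
  hotspot threshold operates far from that regime, but per-plot-week
  predictions at low counts should be read with care (a Poisson option is
  a natural extension and deliberately not the default).
* Spatial autocorrelation between neighboring plots is ignored, as in the
  analysis being reproduced.
* The spatial 70/30 validation is unstable at 90 plots — selected
  variables vary between partitions; that instability is a finding, not a
  defect, and is visible in the model report.

## Problem sizes used in the test suite

The bundled tests run the full study design at reduced scale (2-week,
3-animal herds for module tests; 50 simulated weeks at the full herd size,
20 replicates, for the parameter-recovery study; 1,000 random segment-disc
pairs against the 10^4^-point oracle), sizes chosen so the complete suite
exercises every code path at full fidelity while remaining quick to run on
a laptop.
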