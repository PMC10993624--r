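---
title: "Vegetation-water sensitivity and cumulative effect duration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vegetation-water sensitivity and cumulative effect duration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In water-limited ecosystems such as the Sahel, interannual variation in
vegetation productivity is driven largely by variation in water
availability. Two quantities summarise this coupling per grid cell:

* **Vegetation-water sensitivity** — the Pearson correlation `r` between
  growing-season NDVI anomalies and the Standardized Precipitation
  Evapotranspiration Index (SPEI), estimated inside a moving window of
  five consecutive years. Larger `r` means productivity tracks water
  availability more tightly.
* **Cumulative effect duration (CED)** — the SPEI accumulation scale (in
  months, 1-12) at which the NDVI-SPEI correlation first peaks or
  plateaus. SPEI-k standardises the k-month trailing sum of the monthly
  water balance (precipitation minus potential evapotranspiration), so the
  CED measures how many months of accumulated water conditions vegetation
  integrates — a legacy, or memory, of water constraint.

`vegwater` implements the full per-pixel pipeline: anomaly preprocessing,
moving-window correlation over the twelve scales, the first-peak-or-plateau
reduction, Mann-Kendall/Sen trend analysis of both responses, stratified
area summaries, and a random-forest attribution of the response trends to
climate-driver trends. A seeded synthetic generator produces coupled
NDVI/SPEI/climate fields with known ground truth so that every stage can be
validated by parameter recovery rather than by eye.

## Preprocessing

Monthly NDVI anomalies remove the mean seasonal cycle:

`anomaly(m, y) = NDVI(m, y) - mean_y NDVI(m, y)`

per pixel and calendar month `m`, using the full record as the
climatological baseline. A single ordinary-least-squares line against the
continuous month index is then fitted per pixel over the whole monthly
anomaly series and subtracted, so that a long-term greening or browning
trend does not inflate the apparent water response. Detrending is per pixel
and on the full monthly series (not per calendar month), which is the only
reading under which a "detrended time series" comes out of one best-fitting
line; re-fitting after detrending gives a slope below 1e-10, and the
operation is idempotent.

The growing season is defined from a static phenology map: it starts one
month before green-up, runs forward through the seasonal peak and ends one
month after it, on the circular calendar (a season may wrap December).
Seasons that wrap are attributed to the "season year" in which they start;
that convention keeps each season's months pooled together when windows are
formed. In the degenerate case where green-up and peak are so far apart
that the nominal window would exceed twelve months, the season saturates to
the full year; real phenologies never approach this, but the rule keeps the
operation total.

## Sensitivity and CED

For each pixel, window centre year and scale `k` in 1..12, all
growing-season months of the window's five season-years are pooled and the
Pearson correlation between the detrended NDVI anomaly and SPEI-k is
computed. Windows slide by one year, so a record of 1982-2016 yields centre
years 1984-2014. A window correlation is valid only with at least
`min_samples = 10` complete pairs (a three-month season times five years
gives fifteen), and zero-variance samples on either side yield a missing
value rather than a NaN.

The twelve-scale profile is reduced by a scan from short to long scales
that stops at the first scale whose successor does not exceed it by more
than `plateau_tol`: either a local maximum (next value lower or equal) or
the first entry of a plateau (next value higher by at most the tolerance).
A strictly increasing profile reports the longest scale, and ties between
equal peaks resolve to the shortest scale. The stopping scale is the CED
and the correlation there is the sensitivity, which makes the two outputs
internally consistent by construction. "Plateau" has no quantitative
definition in common usage, so the tolerance is an explicit parameter;
the default of 0.01 absolute correlation units is small relative to the
sampling noise of a window correlation (roughly 0.1 at these sample sizes)
and is exposed in the API.

A pixel is **water constrained** when its record-average sensitivity over
valid windows is strictly positive. Negative-sensitivity windows are kept
in the per-window surface; exclusion happens only through this mask, which
is applied before any trend analysis.

## Trend analysis

Per-pixel series of sensitivity or CED over window centre years are tested
with the Mann-Kendall statistic `S` (concordant minus discordant pairs)
using the tie-corrected variance; CED series are small integers, so ties
are the norm and no jittering is applied. For n <= 10 without ties the
two-sided p-value comes from the exact permutation null, computed from the
inversion-number generating function; otherwise the normal approximation
with continuity correction is used. The magnitude estimate is the Sen
slope, the median of all pairwise slopes — it accompanies every test
because the attribution stage uses it as the response variable.

Significance is assessed per pixel at `alpha = 0.05` with no
multiple-testing correction: the pixel-wise significance maps are meant as
descriptive area fractions, as is conventional in this literature, not as
a family-wise inference. Stratified summaries report fractions of
significantly increasing and decreasing pixels per land-cover class
(shrubs, herbaceous, cropland, forest, other) or per rainfall zone, with
zones cut at the 150/300/600/1000/1200 mm isohyets of mean annual
precipitation. The domain mean series is an unweighted average over
constrained pixels; at dryland latitudes the cos-latitude area factor
varies little across a scene, and the approximation is documented rather
than hidden behind a weighting option.

## Attribution

For every retained pixel the growing-season mean and standard deviation of
monthly precipitation, temperature, incoming solar radiation and CO2 are
computed per season-year, averaged inside the same five-year moving window
as the response, and each per-centre-year feature series is reduced to its
Sen slope. That yields eight "driver trend" features per pixel; the
response is the per-pixel Sen slope of sensitivity (or CED). Rows are
restricted to water-constrained pixels with a significant response trend.
CO2 enters as one global monthly series broadcast to all pixels, so its
features vary spatially only through the phenology (which months are
pooled), mirroring the non-spatial nature of global CO2 products.

A random-forest regressor is trained on all rows — attribution, not
prediction, so no held-out set — with 500 trees and `mtry = p/3` by
default. Permutation importance is the mean reduction in R-squared over
repeated shuffles of one feature at a time (10 repeats by default).
Importance is scored on out-of-bag predictions: a regression forest
trained and evaluated on the same rows interpolates them, and in-sample
permutation importance then credits every feature, including pure noise,
with a large apparent contribution. Out-of-bag scoring restores the
expected null behaviour (importances scattered around zero when the
response is decoupled from all features) while leaving the ranking of a
genuine driver untouched; in-sample scoring remains available via
`importance_mode = "insample"`. Partial-dependence curves are computed on
an equally spaced grid spanning the central 95% of each feature. Spatial
autocorrelation between pixels is not corrected; importances should be
read as descriptive rankings, not as tests.

## The synthetic generator

The generator emulates the statistical structure the pipeline assumes,
not the biophysics:

* **Water balance**: seasonal cycle (wet season centred on August, mean
  45 mm/month with amplitude growing 20 to 60 mm/month from north to
  south) plus a spatially smoothed AR(1) anomaly (innovation SD 15
  mm/month, month-to-month autocorrelation 0.2, Gaussian smoothing length
  1.5 cells). One spin-up year precedes the analysis span so all twelve
  accumulation scales are defined from the first analysis month.
* **SPEI surrogate**: the k-month trailing sum standardised to zero mean
  and unit SD per pixel and calendar month over the record. Operational
  SPEI products fit a log-logistic distribution before transforming to
  standard normal; the pipeline consumes only the standardised-anomaly
  property, so the empirical standardisation is sufficient and documented
  as a deliberate divergence.
* **NDVI**: seasonal climatology plus a linear drift (a re-greening
  surrogate, 1e-4 NDVI/month by default, removed by the pipeline's
  detrending) plus growing-season anomalies `beta(year) * SPEI-k*` with
  iid Gaussian noise; off-season months carry noise only. The true scale
  `k*` runs 2 to 6 months from north to south, echoing the observed
  lengthening of water memory along the rainfall gradient, and the
  phenology map lengthens seasons southwards the same way. The noise SD
  defaults to the value that makes the theoretical pixel correlation
  `beta0 / sqrt(beta0^2 + sigma^2)` equal 0.7 at `beta0 = 0.7` — a typical
  strong dryland coupling.
* **Scenarios**: `recovery` (stationary coupling) validates CED and
  sensitivity recovery; `trend` plants a coupling decline of 0.025 per
  year, chosen a priori by a power calculation so that the per-pixel
  Mann-Kendall test on 31 overlapping-window centre years has high
  (> 0.9 nominal) power — a clear-signal scenario for validating sign and
  rate recovery, intentionally stronger than the subtle domain rates seen
  in observations; `null` removes the coupling entirely; `attribution`
  plants a spatially varying negative coupling trend and constructs the
  trend field of exactly one designated climate driver (temperature mean
  by default) to covary with it across pixels, leaving all other driver
  trends independent.

Everything is driven by one mandatory seed; each stage derives a fixed
sub-seed so that independently called stages are individually reproducible
and a regenerated scenario is bit-identical.

What the generator does **not** emulate: cloud and sensor artefacts,
spatially correlated NDVI noise, non-Gaussian water-balance tails,
phenology that shifts over time, and land-cover change. Passing recovery
tests therefore demonstrates the correctness of the estimators under the
model's assumptions, not the fidelity of any particular satellite product.

## Numerical choices and edge cases

* Grids are exchanged in the ESRI ASCII (.asc) text format, one file per
  month with the date encoded in the file name; gap detection names the
  first missing month. Resampling onto the analysis geometry block-averages
  continuous fields and takes the majority class for land cover, breaking
  ties towards the lowest class code; target cells with under half their
  contributing area valid become missing. Time alignment crops to the
  intersection of spans — padding would fabricate data.
* Anomaly climatologies need at least two years per calendar month;
  detrending needs at least 24 non-missing months, otherwise the pixel is
  flagged and passed through.
* In the noise-free limit the pipeline recovers the true accumulation
  scale exactly, while the recovered correlation saturates slightly below
  1 (about 0.97 on a 10-year record) because the monthly climatology is
  re-estimated from the finite record; this attenuation shrinks with
  record length and is a property of the method, not an implementation
  artefact.
* Problem sizes in the validation harness: the recovery, trend and
  attribution scenarios use a 40 x 40 grid over 35 years (the scale at
  which the statistics of interest stabilise); the oracle comparison uses
  1e5 random profiles; the attribution harness repeats the
  driver-simulation/fit cycle with 300 trees and 5 importance repeats,
  which preserves the ranking behaviour of the full-size fit at a fraction
  of the cost.

## Known limitations

* Only monotonic trends are tested; breakpoints (such as a mid-record
  reversal) are outside the Mann-Kendall framework.
* Consecutive moving windows share four of their five years, so per-pixel
  sensitivity/CED series are serially correlated and the pixel-wise
  Mann-Kendall test is anticonservative — mildly so on a 31-centre-year
  record, strongly so on short records (see the README example). Area
  fractions of "significant" trends should be compared between strata or
  against a simulated null rather than read as calibrated error rates.
* The water-constrained mask is a hard threshold on the mean correlation;
  pixels hovering near zero flip membership under resampling.
* The attribution is correlational: permutation importance ranks
  predictive contributions among the offered features and cannot rule out
  confounding by unmodelled drivers (management, land-cover change).
* Same-CRS, integer-factor resampling only; reprojection belongs upstream.

## A worked micro-example

```{r, eval = FALSE}
library(vegwater)

scn <- simulate_scenario("recovery", seed = 1, nrow = 10, ncol = 10,
                         n_years = 15)
res <- run_response_pipeline(scn$ndvi, scn$spei, scn$pheno)

# fraction of pixels whose median CED lands within one month of truth
ced_med <- apply(res$surface$ced, c(1, 2), median, na.rm = TRUE)
mean(abs(ced_med - scn$truth$k_star) <= 1)

tf <- trend_map(res$surface, "sensitivity", res$mask)
stratify(tf, scn$landcover)
```
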