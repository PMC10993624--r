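# vegwater

Pixel-wise analysis of how dryland vegetation responds to water
availability, for ecohydrologists working with monthly gridded time series.
Given co-registered monthly stacks of NDVI and of SPEI at accumulation
scales 1-12 months, plus a phenology map, the package computes per pixel
and per 5-year moving window:

* **vegetation-water sensitivity** — the Pearson correlation *r* between
  detrended growing-season NDVI anomalies and SPEI, evaluated at the scale
  where the correlation profile first peaks or plateaus;
* **cumulative effect duration (CED)** — that accumulation scale itself,
  in months: how much accumulated water history vegetation integrates.

Downstream stages mask the water-constrained region (record-mean *r* > 0),
test per-pixel temporal trends with the Mann-Kendall statistic and Sen
slope, summarise significant trends by land-cover class and rainfall zone,
and attribute response trends to trends in climate drivers (growing-season
mean and variability of precipitation, temperature, radiation, CO2) with a
random-forest model, permutation importance and partial-dependence curves.

Because real multi-decade satellite archives cannot ship with a package,
`vegwater` includes a first-class synthetic generator: fully seeded,
coupled NDVI/water-balance/climate scenarios with known ground truth (true
accumulation scale, true coupling trajectory, designated causal driver).
The test suite validates the pipeline by parameter recovery on those
scenarios.

## Worked example

```r
library(vegwater)

scn <- simulate_scenario("recovery", seed = 1, nrow = 10, ncol = 10, n_years = 15)
res <- run_response_pipeline(scn$ndvi, scn$spei, scn$pheno)

ced_med <- apply(res$surface$ced, c(1, 2), median, na.rm = TRUE)
mean(abs(ced_med - scn$truth$k_star) <= 1)
#> [1] 0.94
mean(res$mask$constrained)
#> [1] 1
round(mean(res$mask$mean_r, na.rm = TRUE), 3)
#> [1] 0.673
```

94% of pixels recover the generator's true accumulation scale to within one
month, every pixel is (correctly) classified as water constrained, and the
grid-mean sensitivity of 0.673 sits close to the generator's theoretical
coupling of 0.7 (window correlations are slightly attenuated on short
records). Trend maps and stratified summaries follow:

```r
tf <- trend_map(res$surface, "sensitivity", res$mask)
stratify(tf, scn$landcover)
#>      stratum  n n_increasing n_decreasing fraction_increasing fraction_decreasing
#> 1     shrubs 30            6            3           0.2000000          0.10000000
#> 2 herbaceous 29           10            4           0.3448276          0.13793103
#> 3   cropland 22            3            2           0.1363636          0.09090909
#> 4     forest 16            4            2           0.2500000          0.12500000
#> 5      other  3            2            0           0.6666667          0.00000000
```

The coupling here is stationary, yet 10-30% of pixels per class show
"significant" trends: with only eleven window centres and windows sharing
four of five years, the per-pixel Mann-Kendall test is markedly
anticonservative. On the 31 centre years of a full-length record the
inflation is far milder — one reason the validation scenarios use 35-year
records, and a caveat to keep in mind when reading pixel-wise significance
maps. See the vignette
(`vignettes/vegetation-water-response.Rmd`) for the model, the estimator
definitions, parameter defaults and the generator's design.

Gridded inputs and outputs are exchanged as ESRI ASCII (`.asc`) text grids,
one file per month with a `VariableName_YYYYMM.asc` naming scheme
(`read_monthly_stack()` / `write_monthly_stack()`), so everything is
inspectable with a text editor or standard GIS tools.

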