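---
title: "Dasymetric downscaling of livestock censuses: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dasymetric downscaling of livestock censuses: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Livestock censuses report headcounts per administrative district, but most
ecological and epidemiological questions need densities per pixel. The gap
is filled by dasymetric downscaling: learn how district-level density
(head/km²) relates to environmental and socioeconomic covariates, predict
that relation at every pixel, and then rescale each district's pixels so
they sum back to the census — the pycnophylactic (mass-conserving)
property. `livestockgrid` implements this pipeline end to end for annual
multi-species census series, together with per-pixel Mann-Kendall/Sen
trend analysis of the resulting density stacks and a synthetic-landscape
generator that makes the whole pipeline testable without any external
data.

## Pipeline

1. **Census repair** — densities are headcount/area; interior gaps in a
   district's series are filled by linear interpolation between the
   nearest flanking observed years (never extrapolated); restructured
   districts are merged by summing headcounts and areas
   (`interpolate_missing_years()`, `merge_districts()`).
2. **Settlement-proxy sampling** — each district contributes its `k = 10`
   most populous settlements as pseudo-training points; all points of a
   district carry the district's density as response, since no
   sub-district response exists. Covariates are read either at the point's
   pixel or as the mean over a circular buffer (2/5/10 km) representing
   the daily livestock movement range. Buffers are physical discs and are
   not clipped at district borders.
3. **Random-forest regression** — `density_rf()` fits a forest of the
   density on the 13 covariates; `mtry` and `ntree` are tuned by 10-fold
   cross-validation with 5 repetitions (lowest mean CV RMSE, ties toward
   smaller forests). The buffer radius and train:test split are chosen
   once from a 12-model experiment (4 buffers x 3 splits) on a selection
   year, each cell independently tuned and scored
   (`run_experiment_grid()`).
4. **Mass-conserving adjustment** — predicted pixels in district *j* are
   multiplied by the ratio of the observed census total to the predicted
   district total, so every district's pixels sum back to the census
   exactly (`adjust_surface()`, verified independently by
   `verify_conservation()`).
5. **Trends** — per-pixel Mann-Kendall tau-b, two-sided normal p-value
   and Sen's slope over the annual adjusted stacks, masked at p < 0.05
   (`trend_surface()`).

## Model-selection metric

Across the 12 experiment cells the test partitions differ in size and
composition, so raw test RMSE is not comparable between splits: a lucky
low-variance 10% holdout can undercut an honest 30% one. Selection
therefore ranks cells by independent-test R² — which normalises each
partition by its own variance — breaking ties by lower test RMSE, lower
test MAE, then larger buffer. On the packaged reference 12-model
selection table this rule reproduces the (10 km, 90:10) choice.

## The synthetic landscape

The generator supplies every input the pipeline consumes, with the
statistical structure the method assumes. Its reference configuration
(used throughout the tests) is 24 districts on a 200 x 200 grid of 1 km
cells, 12 settlements per district, 20 annual covariate stacks and two
species, seed 42.

* **Districts** are the Voronoi cells of uniformly random seed pixels:
  contiguous, variably sized zones resembling administrative districts.
* **Settlements** scatter around each district centroid (Gaussian, sd =
  1/4 of the district's equivalent radius, rejection-sampled into the
  district) with log-normal populations (median 500, sigma 1.2), spanning
  hamlets to cities.
* **Covariates.** The eight climate/vegetation layers are standardized
  Gaussian random fields with a 60 km correlation length — smooth at the
  district scale, as interpolated climatologies are — superimposed on a
  planar gradient that carries 70% of the spatial standard deviation.
  All dynamic layers share one gradient orientation per landscape:
  climate and vegetation drivers are physically coupled and co-vary along
  the same continental gradient, and it is precisely this between-district
  contrast that makes censuses transferable to pixels. Annual anomalies
  are redrawn per year from sub-seeds; the gradient orientation is not.
  Elevation is static (smoothed field plus gradient). Population density
  and nighttime light are sums of per-settlement Gaussian kernels scaled
  by population. Distance-to-settlement and distance-to-water are exact
  Euclidean distance transforms (pixel-center metric, km).
* **Latent truth.** Base density is
  `D0 = s * exp(beta' z) * [b + (1 - b) * exp(-d/lambda)]` with `z` the
  standardized covariates (settlement-kernel layers log-transformed
  first — they are heavy-tailed, and raw z-scores of city spikes explode
  through the exponential link), `s` = 15 head/km² for small ruminants
  and 1.5 for horses, decay length `lambda` = 10 km (the daily grazing
  radius) and background `b = 0.3`: density concentrates around
  settlements but remote pastures retain a share of the local level,
  because larger herds graze well beyond the daily radius. Year `t` adds
  a relative trend of 2%/yr of `D0` (the order of the multi-decade herd
  recovery in Central Asian drylands) plus white noise (sd 2 and 0.2
  head/km² for the two species), clipped at zero with the clipped
  fraction recorded. The resulting fields have realistic magnitudes:
  pixel densities of 0-900 head/km² and district means spanning roughly
  1.5-850.
* **Census** tables are exact aggregations of the truth (density x pixel
  area summed per district), so conservation checks have a sharp target.

What the generator does **not** emulate: physical units and
cross-correlations of real covariate suites beyond the shared gradient,
seasonal (sub-annual) structure, terrain-routed water access, or
settlement growth over time. Passing the recovery tests therefore shows
the pipeline recovers a latent field that satisfies the method's own
assumptions — it does not certify accuracy on real data, where the
response is not a clean function of the covariates.

## Numerical choices

* Distances are center-to-center in km; point sources snap to their
  containing pixel, so a source pixel is exactly 0.
* Settlement population ties break by ascending settlement id; tuning
  ties break toward smaller `ntree`, then smaller `mtry`.
* `P_j = 0` with `O_j > 0` (forest predicts nothing in a district that
  has stock): the observed total is spread uniformly over the district
  and the district is flagged. `O_j = 0` zeroes the district outright.
  Negative census totals are errors.
* Conservation is checked as `|sum - O_j| / max(O_j, 1) < 1e-9`, i.e.
  relative with an absolute floor for empty districts.
* Mann-Kendall uses the tie-corrected variance and tau-b (annual density
  rasters contain tied zeros), a continuity-corrected normal deviate, and
  no multiple-testing correction by default — the mask reproduces the
  conventional raw p < 0.05 display; `fdr = TRUE` switches to
  Benjamini-Hochberg. With 20-year series the normal approximation is
  adequate.
* Trends run on adjusted surfaces by default (`trend_stage` switches to
  raw predictions).
* Missing pixels are `NA` in memory and -9999 on disk; rasters are ESRI
  ASCII grids (plain text, GIS-standard) named `sr_<year>` / `hr_<year>`
  for the two species, with a JSON manifest carrying the grid geometry
  and seeds.
* `run_pipeline()` tunes hyperparameters once per species on the
  selection year and reuses them across years by default
  (`retune_per_year = TRUE` restores fully independent per-year tuning at
  roughly tenfold tuning cost); the selected buffer/split is always
  shared across years.

## Problem sizes used by the test suite

Module tests run on 60 x 60 landscapes with 5-6 districts; the
end-to-end checks use the full reference configuration (24 districts,
200 x 200, 20 years, 2 species), 1000-series Mann-Kendall oracle sweeps,
10,000-pixel null calibration stacks, and three landscape replicates for
the recovery statistic. These sizes exercise every code path at the
reference scale while keeping a complete run in minutes on one core.

## Known limitations

* All points of a district share one response, so point-grouped
  train/test splits leak information between partitions; the
  `grouping = "district"` option quantifies the cost of honest splitting
  but the default mirrors the conventional design.
* Forest predictions cannot leave the range of training responses, and
  covariate values far outside the sampled support (e.g. pixels much
  farther from settlements than any training buffer) receive flat
  extrapolations; the within-district pattern there is carried mostly by
  the adjustment's district scaling.
* The experiment's CV scores are computed on the training partition only;
  with 10 points per district they are optimistic in the same way the
  original design is.
* No spatial cross-validation, no alternative learners, and no
  autocorrelation-corrected Mann-Kendall variants are provided.
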