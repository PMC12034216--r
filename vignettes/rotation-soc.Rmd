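---
title: "Rotation effects on soil organic carbon: models, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotation effects on soil organic carbon: models, generator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotsoc)
```

`rotsoc` studies the association between corn–soybean rotation sequences and
soil organic carbon (SOC) stocks. This vignette is the package's account of
the science it implements: the statistical model and its assumptions, what
the synthetic-data generator does and does not emulate, the numerical and
design choices that were genuinely open, and the limits of what the tests
can show.

## The estimation problem

A cross-sectional SOC survey gives, for each site, stocks (Mg C/ha) in
three depth layers (0–5, 5–30, 30–100 cm), coordinates, a measurement date,
a soil-texture class and a region label. Annual categorical crop rasters
give the crop grown on each ~30 m cell each year; extracting the raster
value at a site's coordinates for the measurement year and the two prior
years yields its 3-year cropping sequence. Sequences made up entirely of
corn and soybeans are grouped by the number of corn years — 0c, 1c, 2c, 3c —
and any other crop in the window excludes the site from the regressions
(it still counts in transition tables and area shares, as "other").

The model for the total 0–100 cm stock (or a single layer) is log-linear:

$$\log(SOC_i) = \beta_0 + \beta_{r(i)} + \beta_{lat} Lat_i +
\sum_{k=1}^{8}\gamma_k W_{ik} + \tau_{t(i)} + \alpha_{a(i)} + \mu_{m(i)} +
\varepsilon_i$$

where $\beta_{r(i)}$ is the rotation term in one of three encodings
(per-year corn dummies; group dummies against a configurable base group;
or a linear term in corn years), $W$ are the eight windowed climate
covariates, $\tau$, $\alpha$, $\mu$ are texture, region ("area") and
measurement-month fixed effects. Estimation is ordinary least squares on
the log outcome with listwise deletion; coefficient covariance defaults to
heteroskedasticity-robust (HC1), with classical available — field SOC
dispersion plausibly varies across groups and regions, and the robust
choice is the safer default when the error structure is unknown. Effects
are reported as percent effects $100(e^{\beta}-1)$, with
endpoint-transformed intervals $100(e^{\beta \pm z\,se}-1)$: the transform
is exact, strictly increasing and maps 0 to 0, so interval endpoints remain
ordered.

Group contrasts of log stocks are also tested directly with one-tailed
Welch two-sample *t*-tests (alternative: the more corn-intensive group has
the larger mean). The Welch form is used because group variances are not
assumed equal; the one-sided 95% interval is reported as (lower, ∞).

## Climate windows

The eight weather covariates are means of monthly temperature and
precipitation over the warm (April–September) and cold (October–March)
calendar months of two windows counted back from the measurement month:
recent = months 1–12 and lag = months 7–18. Months are counted back from
the measurement month *exclusive* (month 1 is the calendar month
immediately preceding measurement) so a partially observed measurement
month never enters a mean. Every 12-consecutive-month window contains
exactly six warm and six cold months, and the code treats any window
configuration producing a different count as an error rather than silently
averaging fewer months.

Two windowing conventions are defensible for the "historical" block — a lag
of months 7–18 or of months 13–36 — and sources describing this class of
analysis are not consistent between them. The package defaults to 7–18,
which keeps every feature a 6-month mean, and exposes the bounds in
`climate_windows()` so the 13–24 variant can be run; no claim is made that
either is uniquely "the" specification. Note that with the default windows
the recent and lag blocks overlap in months 7–12; their warm-month subsets
coincide only for measurement months that place months 7–12 entirely in the
cold season (e.g. October measurements), which is also the only alignment
in which the four month-sets tile months 1–18 exactly.

## The synthetic-data generator

The generator produces the three data sources the analysis consumes, under
recorded ground truth:

* **Crop rasters** (`generate_crop_rasters()`): each region of a planar
  layout is tiled into square field patches (default 4×4 cells of 30 m, a
  realistic field scale against the raster resolution); each patch draws a
  3-year rotation pattern from the region's configured mix, realizes it as
  a coherent per-year code sequence (corn = 1, soybeans = 5, "other"
  patches a winter-wheat/alfalfa code so the exclusion path is exercised),
  and repeats the template cyclically for longer spans. A configurable
  fraction of patches is masked as non-cropland. The emitted truth table
  records both configured and realized pattern shares.
* **Sites** (`generate_sites()`): placed on valid raster cells, with
  measurement year/month, a latitude covariate mapped linearly from the
  planar y coordinate onto 38–46°N (the Corn Belt span), and a texture
  class drawn from the 16 USDA labels. The default site count, 2,105,
  mirrors the cropland site count of the national survey the table
  emulates.
* **Weather** (`generate_weather()`): a July-peaked sinusoid plus a
  latitude gradient and Gaussian noise for temperature, a summer-peaked
  sinusoid floored at zero for precipitation. Defaults (annual mean 10 °C,
  amplitude 12 °C, noise 2 °C; 80 mm/month, amplitude 30 mm, noise 15 mm)
  are ordinary mid-latitude magnitudes. For the noiseless sinusoid the
  warm-minus-cold gap of 6-month means is exactly
  $A(2+\sqrt3)/3$ (`seasonal_warm_cold_gap()`), which the tests use as a
  closed form.
* **Stocks** (`generate_soc()`): the log total stock is the linear
  predictor implied by `generative_params()` plus $N(0,\sigma^2)$ noise;
  the total is split into the three depth layers by per-site
  Dirichlet-perturbed shares.

Key generator defaults, and why:

* Group log effects default to $\ln 1.300$, $\ln 1.424$, $\ln 1.713$
  (+30.0%, +42.4%, +71.3% for 1c/2c/3c) and the per-corn-year slope to
  $\ln 1.2508$ (+25.08%/year) — the effect sizes this class of analysis
  reports, so parameter-recovery tests check the pipeline at realistic
  signal strength.
* $\sigma = 0.5$ on the log scale. Field SOC stocks are highly dispersed
  (coefficients of variation around 50% are unremarkable); the value is a
  stand-in, recorded in the truth file, and configurable. $\sigma = 0$ is
  allowed and gives exact identification, which the tests exploit.
* Under log-normal noise the arithmetic group mean is
  $e^{\mu + \sigma^2/2}$, so matching a target arithmetic mean (e.g. the
  0c mean of 109.73 Mg C/ha) requires $\mu = \log(\text{target}) -
  \sigma^2/2$; `calibrate_intercept()` does this. Without the correction a
  $\sigma=0.5$ simulation overshoots its intended mean by ~13%.
* Layer fractions default to 0.08/0.28/0.64 for 0–5/5–30/30–100 cm. The
  deep-layer-largest ordering is the robust qualitative feature of depth
  profiles integrated over such intervals; the exact split is a stand-in
  since per-layer shares are not published, with Dirichlet concentration 50
  giving mild per-site variation.

What the generator does **not** emulate: the multi-level stratified
sampling design of the real survey, real state geometries or climate
interpolation, spatial autocorrelation in stocks or in weather, and
management covariates (tillage, fertilization, cover crops) — in the
simulation, rotation assignment is exogenous by construction. Passing
recovery tests therefore show the estimator is consistent and correctly
implemented *under the model's own assumptions*; they cannot show that the
assumptions hold for real fields, where rotation choice is confounded with
soils and management.

## Rasters and file formats

No geospatial raster stack is required: rasters are a minimal in-package
class (`crop_raster`) — an integer matrix with an affine extent — with
half-open cells ([left, right) horizontally, top-inclusive vertically, so
every in-extent point belongs to exactly one cell and points on the
right/bottom outer edge are outside. All rasters entering an operation must
share one grid and coordinate-reference label; there is deliberately no
reprojection engine, because a silent reprojection is a reproducibility
hazard in a pipeline meant to be exactly checkable. Serialization is ESRI
ASCII grid, a standard plain-text single-band format readable by common GIS
tools, with the CRS label in a sidecar. Tables are CSV with typed, schema-
checked readers; configuration and truth records are YAML.

## Area shares and scenarios

`sample_points()` samples uniformly (with replacement by default — the
draw is over valid cells and replacement keeps it well-defined for any n;
without-replacement is available) from the cells valid in every year,
optionally masked to a region. `rotation_proportions()` classifies each
point's 3-year sequence and reports shares under two denominators: all
sampled land, and corn–soy land only. Both are emitted because "share of
cropland" and "share of the corn–soy system" are different quantities and
published figures are not always explicit about which one they show.

`run_scenarios()` prices conversions: moving `area` hectares from group
*g* to a strictly more corn-intensive group gains
`area × mean_SOC(g) × pct_effect(g→g')` Mg C. Policies are sets of
conversions that must touch disjoint (state, from-group) cells —
overlapping conversions are an error, not a double count. Valuation is the
exact product with the social cost of carbon, default $678/t C (2020 USD),
with 1 Mg = 1 t.

`cornbelt_reference()` ships the published four-state accounting inputs
(per-state areas by current rotation group, the 0c group mean of 109.73
Mg C/ha, the 0c-base effects +30.0/+42.4/+71.3% and the 3c-vs-1c effect
+31.8%, and per-state reference gains for the six conversions). The 1c and
2c group means and the remaining cross effects are **derived
calibrations**: they are not independently published, so they are
back-solved from the reference gains (e.g. the 1c mean from the 1c→3c
block total and the +31.8% effect, giving ≈143.8 Mg C/ha; the 2c→3c effect
is fixed at the ratio 1.713/1.424 − 1 ≈ +20.3%, giving a 2c mean of
≈174.8 Mg C/ha). They are flagged `derived = TRUE` and should be read as
"the inputs that reproduce the published accounting", not as measurements.
One bookkeeping detail: the four published state 0c areas sum to 737,956
ha while the published total row prints 737,955; the package always sums
the state cells.

## Numerical choices and degenerate inputs

* Zero total stock is an error (the log is undefined), as is any negative
  layer; the generator cannot produce either.
* A Welch test with zero variance in both samples is an error; one
  zero-variance sample is fine (the statistic is still defined).
* Rank-deficient regression designs are an error naming the collinear
  columns; single-level factors (e.g. one region) are dropped from the
  formula instead, since a constant block is a degenerate fixed effect,
  not a user mistake.
* Group summaries require two sites per reported group (a one-site CI is
  undefined); smaller groups are dropped with a warning.
* All generators take explicit integer seeds and are byte-reproducible;
  the pipeline derives fixed per-stage offsets from the master seed so
  stages are independently reproducible.

## Problem sizes

The test suite and acceptance script run at sizes chosen to make
Monte-Carlo noise small relative to the quantities checked while staying
desk-scale: parameter-recovery fits at n = 5,000 sites; interval-coverage
studies at 200 replicates of n = 2,000; the calibrated-mean check at
n = 2,000; area-share recovery on a 600×600-cell synthetic state
(22,500 field patches) sampled at 40,000 points — at that patch count the
realization noise of a ~10% configured share is ±0.2 percentage points,
well inside the sampling tolerance. Rasters in unit tests are ≤ 80×80
cells, where brute-force oracles are exact and fast.

## Known limitations

* Cross-sectional identification: the regression measures association;
  rotation choices on real fields are endogenous to soil quality and
  management, and nothing in the pipeline corrects for that.
* No spatial autocorrelation in errors or covariates, and no
  spatially-clustered standard errors.
* The scenario accounting assumes stocks jump to the target group's mean
  immediately and completely — it prices an equilibrium difference, not a
  sequestration path over time.
* Non-CO₂ consequences of more corn (nitrogen fertilizer, N₂O) and market
  feedbacks are out of scope.
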