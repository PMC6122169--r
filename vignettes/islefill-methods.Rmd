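---
title: "Elevation-aware gap-filling of island LST records: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elevation-aware gap-filling of island LST records: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islefill)
```

## The problem

Radiometric land-surface-temperature (LST) records over small, mountainous
islands are riddled with cloud gaps, and those gaps are not random: cloud
sits preferentially over high ground, daytime heating drives convection,
and spring storm tracks add a seasonal bias. Deleting gappy months or
averaging around the gaps therefore biases climatologies warm. `islefill`
implements a gap-filler that predicts each missing monthly value from its
spatio-temporal neighbourhood with the island's elevation field as a
covariate, together with the validation machinery needed to decide whether
such an imputer can be trusted: knockout experiments, error statistics,
support--error regressions, spatial-autocorrelation and missingness
diagnostics, and a protocol for comparison against in-situ soil loggers.

## The gap-filling model

For a missing value at cell $c$ and month-layer $t$, a subset is extracted:
all cells within `spatial_radius` (default 5, an $11\times11$ window)
crossed with the slices at month-of-year offsets $\{-1,0,+1\}$ and year
offsets $\{-2,\dots,+2\}$ — up to $121 \times 15$ entries, hence a maximum
*support* (observed entries excluding the target) of 1814. Month offsets
cross calendar-year boundaries (December $\leftrightarrow$ January); year
offsets truncate at the ends of the record; the spatial window truncates at
the island's bounding box.

On the observed entries of the subset the linear model

$$ y_{c',t'} \;=\; \beta_0 + \beta_1\,a_{t'} + \beta_2\,e_{c'} $$

is fitted by pinball-loss (check-loss) minimization at quantile level
$\tau$, where $e_{c'}$ is the DEM elevation of the cell and $a_{t'}$ is the
*slice anomaly*: the mean of the slice's observed values minus the grand
mean of the subset's observations (zero for slices with no observations,
including possibly the target's own slice). The anomaly term absorbs
seasonality and synoptic month-to-month shifts; the elevation term carries
the lapse structure that makes predictions at unsampled altitudes sensible.

Three quantile fits are evaluated at the target's covariates
$(1, a_t, e_c)$:

* the point prediction at $\tau^\*$, the target cell's own typical
  quantile level: in every slice where the target cell is observed, its
  normalized mid-rank (Hazen position, $(r-0.5)/n$) among the slice's
  observed cells is computed; $\tau^\*$ is the mean of these, truncated to
  $[0.05, 0.95]$, falling back to $0.5$ when the target cell is observed
  nowhere in the subset. This preserves persistent within-window biases
  (a cell that always runs warm is predicted warm). Prediction at a fixed
  $\tau=0.5$ is available via `subset_spec(predict_at = "median")`.
* the lower and upper 95% confidence limits at $\tau = 0.025$ and
  $0.975$.

Point predictions are clipped to the island's observed minimum/maximum
(the *clip range*, computed per island and photoperiod); confidence limits
are deliberately left unclipped and may exceed it. A prediction *fails* —
is recorded missing with a flag, never invented — when support falls below
`n_min` (default 10, comfortably above the 3 coefficients); a month that is
missing across all cells together with its temporal neighbours therefore
fails everywhere, reproducing the known failure mode of very small islands.

### The quantile-regression solver

No quantile-regression library is assumed; the fitter
(`rq_fit()`) is an exchange (simplex) algorithm on basic solutions: an
optimal $\tau$-quantile plane interpolates $p$ observations, so the solver
walks from basis to basis along the direction of steepest one-sided descent
of the pinball loss, with a ratio test over residual sign changes. Two
numerical choices matter:

* **Degenerate vertices.** With tied data more than $p$ points can lie on
  the optimal plane, and a single basis then does not expose every edge of
  the loss polytope. At an apparently optimal basis the solver enumerates
  the other bases of the same vertex (bounded by a visited set) before
  declaring convergence. A zero-loss shortcut accepts any exactly
  interpolating plane immediately (the check loss is non-negative), which
  keeps noise-free fields — where *every* observation lies on the optimal
  plane and the vertex is maximally degenerate — from degenerating into an
  exhaustive vertex walk. The test suite checks exactness against
  brute-force enumeration of all basic solutions on problems up to
  $n = 30$, tied and continuous, at central and extreme $\tau$.
* **Warm starts.** The three fits per subset share a design matrix; each
  fit seeds the next with its optimal basis.

Collinear designs (constant elevation in the window, a single informative
slice) drop the offending column before fitting. Because separately fitted
quantile planes can cross in finite samples, the three predictions are
sorted (monotone rearrangement), guaranteeing
`lower_ci <= mean <= upper_ci` before the mean is clipped.

## The synthetic world

Every stage is testable offline against generated island scenes
(`simulate_scene()`), whose structure states the conditions the method
assumes rather than tuning toward any test:

* **DEM** (`make_dem()`): a Gaussian dome with its coast (elevation zero)
  at a fixed radius, plus smooth roughness of 2% of the peak height;
  defaults give a ~1200 m peak — a Marion-like island — with at least 25%
  land.
* **Temperature** (`simulate_lst()`): $T = T_0 + A\cos(2\pi(m -
  \phi)/12) + \Gamma\,\mathrm{elev} + W\,\mathrm{windward} + \eta_t +
  \varepsilon$, with day-time sea-level mean $T_0 = 7$°C, seasonal
  half-amplitude $A = 4$°C peaking in January (austral summer), the
  standard environmental lapse rate $\Gamma = -0.0065$ °C/m, a westward
  (windward) coast $1$°C cooler via a linear west–east ramp, nights $7$°C
  colder than days, slice anomalies $\eta_t \sim N(0, 1)$ and pixel noise
  $\varepsilon \sim N(0, 0.8^2)$.
* **Cloud gaps** (`simulate_cloud_mask()`): Bernoulli draws from
  $\mathrm{logit}\,P = b_0 + b_e\,\mathrm{elev} + b_d\,[\mathrm{Day}] +
  b_s\,[\mathrm{Sep–Nov}] + S_t$ with a smooth spatial logit field $S_t$
  (white noise convolved with a Gaussian kernel) redrawn per layer.
  Defaults ($b_0=-3.9$, $b_e=0.002$/m, $b_d=0.5$, $b_s=0.5$, field SD 1,
  range 3 cells) produce roughly 10% missingness — matching the ~9.85%
  average gap fraction of the real archipelago records — with more gaps at
  altitude, by day, and in austral spring (September–November; all target
  islands are austral).
* **Soil loggers** (`simulate_soil_monthly()`): shallow soil damps the
  diurnal cycle, so synthetic soil is an AR(1) smoothing of the day/night
  mean surface truth plus 30% of the diurnal half-range (daytime soil
  cooler than the day surface, night-time soil warmer than the night
  surface) plus logger noise. This reproduces the qualitative situation in
  which night-time fills can resemble soil *better* than raw observations.

What the generator does **not** emulate: cloud-contamination outliers with
realistic magnitudes (the preprocessing quantile filter is tested on
injected extremes instead), topographically locked cloud (the logit field
is stationary), inter-annual trends, and sensor-specific artefacts. A green
validation suite therefore establishes the machinery's correctness and the
method's behaviour under the stated statistical structure — not performance
on any real satellite archive.

Scenes used in tests are scaled to ~16–24 cells a side and 2–5 years so
the full suite runs on one CPU in minutes; the published records they
stand in for are 15-year, 180-layer cubes.

## Validation machinery

* **Knockouts**: `knockout_random()` deletes exactly
  $\mathrm{round}(f\,n_{\mathrm{obs}})$ observed land cell-layers;
  `knockout_clustered()` deletes 3×3 spatial blocks around random centres
  until the target fraction is reached (overshoot at most one block,
  matching the "approximately $f$" design). Both are deterministic under a
  seed.
* **Error statistics** use the convention $\mathrm{error} = \mathrm{observed}
  - \mathrm{predicted}$, so a negative mean error means the imputer runs
  warm. RMSE, mean error, error range (max − min), sample SD and the
  failure count are reported per scenario.
* **Support–error regression**: median ($\tau=0.5$) pinball fit of
  $|\mathrm{error}|$ on support, with the Koenker–Machado $R^1$
  ($1 - V_{\mathrm{full}}/V_{\mathrm{null}}$ on $\tau$-weighted absolute
  residuals) as goodness of fit. Slope uncertainty comes from a seeded
  case-resampling bootstrap ($B = 200$) — reference implementations vary in
  their default rank-based inference, and a bootstrap is reproducible
  across ecosystems; $t$ and the two-sided $p$ use $n-2$ degrees of
  freedom.
* **Moran's I** on per-cell statistics uses queen contiguity with
  row-standardized weights (the common default, configurable to binary),
  expectation $-1/(n-1)$, and the normality-assumption variance for a
  two-sided $p$.
* **GLM diagnostics**: binomial logit for missingness on photoperiod,
  season and elevation (`stats::glm`, convergence tolerance $10^{-8}$,
  complete separation flagged); negative binomial with ML dispersion for
  counts of gap-fill errors above a configurable 1 °C threshold
  (`MASS::glm.nb`). No island term is included: pooling follows the
  original analysis design.
* **Ground truthing**: hourly logger series are despiked (records jumping
  ≥ 10 °C per hour from the last retained record are dropped), split into
  day/night by the solar hour-angle equations with the refraction-adjusted
  zenith 90.833° and no elevation correction (differences are sub-minute at
  these latitudes), and averaged per site-month-photoperiod. Months whose
  soil mean is below 0 °C are excluded — snow decouples soil from the
  surface — regardless of the LST value (the quoted rule is one-sided on
  soil). Products are compared by Pearson correlation, RMSE, and a
  tie-corrected normal-approximation Mann–Whitney U (no continuity
  correction) on the two absolute-error samples, with effect size
  $r = z/\sqrt{n}$. Half of the observations are knocked out before
  filling so both products have comparable sample sizes. Loggers map to
  the nearest cell centre.

## Numerical and design choices that were genuinely open

* *Quantile filter sidedness*: "outside the 99.99% quantiles" is read as a
  two-sided central interval of mass 0.9999 (tails of $5\times10^{-5}$
  each), computed per island-photoperiod cube with type-7 (linear
  interpolation) empirical quantiles; the mass is configurable.
* *8-day to monthly assignment*: a composite contributes to the calendar
  month containing its start date, with no proration.
* *Eligibility boundary*: "more than 50% missing" is strict — exactly 50%
  missing is still filled.
* *Year-offset reading*: "the previous and next two-year period" is
  implemented as offsets $\{-2,\dots,+2\}$ (15 slices), the only reading
  consistent with reported mean supports of ~1300 against a 1814 maximum.
* *Point prediction at $\tau^\*$ vs the median*: the main text does not
  pin this down; $\tau^\*$ is the default, `predict_at = "median"` the
  alternative. No retry with enlarged subsets is attempted after failure.
* *On-disk formats*: NetCDF classic and GeoTIFF are written by small
  self-contained codecs (no geospatial I/O stack is assumed at run time);
  files are valid for standard readers — the tests verify round-trips
  through `scipy` and `tifffile` — but compression and the original fill
  value conventions of the published archive are not reproduced. The
  R-native `.grd` dialect is intentionally not implemented.
* *Coordinates*: cell centres, row 1 northernmost, WGS84 (EPSG:4326)
  only; GeoTIFFs declare the PixelIsPoint raster convention.

## Known limitations

The solver is exact but pure R; cubes of hundreds of thousands of gaps
will be slow (the published archive's islands run minutes to hours, not
seconds). Confidence limits are quantile-plane evaluations, not calibrated
prediction intervals; at extreme $\tau$ with support near `n_min` they are
noisy. The clip range is a hard constraint borrowed from the data's
observed extremes and can mask genuine out-of-range conditions at poorly
observed altitudes — which is precisely why the unclipped confidence
limits are published alongside the means.
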