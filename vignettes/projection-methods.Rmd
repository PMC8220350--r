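---
title: "Models and methods behind the rpclim projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the rpclim projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpclim)
```

`rpclim` projects the population burden of Raynaud's phenomenon (RP) — an
episodic, cold-triggered vasospasm of the digital microcirculation — onto
gridded climate under greenhouse-gas emission scenarios. This vignette is
the package's own account of the science: the two statistical models, the
climate plumbing around them, every tunable that matters, and what the test
suite does and does not demonstrate.

## The prevalence model

Surveys of RP prevalence in the general population span roughly 0.3 % to
15.5 % across mid-latitude cities, and colder sites report more RP. The
package models survey prevalence $p_i$ (percent) as linear in the mean
temperature $T_i$ (°C) of the cold season preceding each survey's
publication:

$$p_i = \beta_0 + \beta_1 T_i + \varepsilon_i .$$

`fit_prevalence()` estimates $(\beta_0, \beta_1)$ by least squares —
unweighted by default, sample-size-weighted on request, since the sources
do not establish a weighting. The model is kept on the raw percent scale
(no logit) because the scientific claim of interest — a change of so many
percentage points of prevalence per °C — is additive in percent.
Predictions are clamped to $[0, 100]$; the zero crossing
$T_0 = -\beta_0/\beta_1$ (defined for cooling slopes $\beta_1 < 0$) is the
temperature above which the model declares a population RP-free.

Assumptions worth stating plainly:

* **Ecological regression.** Each point is a whole survey, not a person;
  between-survey differences in methods, age structure and sex ratio all
  land in $\varepsilon_i$. Mean ages are parsed from the table but unused.
* **Winter defines exposure.** A survey published in year $Y$ is assigned
  the mean of 1 Nov $Y{-}1$ to 31 Mar $Y$ at its city's grid cell — the only
  reading of "the winter preceding publication" in which the winter actually
  precedes it. The window is 151 days (152 when the end-year February has
  29 days).
* **Southern hemisphere.** The single austral site in the bundled table is
  handled, by default, with the same November–March window, mirroring the
  calibration's single stated window; `assign_winter_temps(south_window =
  austral_winter_window())` switches southern sites to May–September for
  sensitivity analysis.
* **Extrapolation is temperature-mediated.** Worldwide prediction uses each
  grid cell's own temperature; latitude enters only through temperature. A
  latitude-only regression (`predictor = "abs_latitude"`) is available as a
  deliberately crude fallback for settings with no linked climate.

## The severity model

Pooled n-of-1 daily diaries give, per patient-day, an attack count $y_{it}$
and the local daily temperature. `fit_poisson()` fits the log-link Poisson
model

$$y_{it} \sim \mathrm{Poisson}\!\left(\exp(\beta_0 + \beta_T T_{it} + \dots)\right)$$

with exposure fixed at one day per row. Covariates beyond temperature are a
configurable list (default: temperature only) and optional patient
fixed-effect indicators absorb between-patient baseline differences.
Because a deposited model's exact covariate set is generally not printed in
accompanying articles, `severity_fit_from_coefficients()` /
`read_severity_fit()` accept externally estimated coefficients instead of
refitting.

Weekly attack frequency is $7\exp(x^\top\beta)$. Separately from the
smooth model, an empirical ceiling is imposed at prediction time: at and
above `attack_threshold_temp` (default 13 °C, matching the temperature at
which observed attack rates vanish and consistent with the prevalence
zero crossing) the predicted frequency is exactly zero. It is a hard
post-prediction rule, not a model term, and can be disabled
(`threshold = FALSE`).

`weekly_temperature_effect()` summarises the fit as the mean slope of the
weekly frequency between two temperatures (default 0 °C to the ceiling) and
its reciprocal — the °C of warming per one fewer weekly attack. The
endpoints are evaluated on the *unthresholded* rate: a flat model must
report a zero slope rather than an artefactual drop created by the ceiling
zeroing its upper endpoint.

### Fitting: IRLS, in the package

The Poisson likelihood is maximised by iteratively reweighted least squares
written in the package (the covariance comes from the inverse Fisher
information at the optimum):

* initialisation: $\beta_0 = \log(\bar{y} + 10^{-6})$, all other
  coefficients 0 — deterministic, no randomness in fitting;
* Newton/Fisher step $\delta = (X^\top W X)^{-1} X^\top (y - \mu)$ with
  $W = \mathrm{diag}(\mu)$, followed by step halving until the
  log-likelihood does not decrease, which makes the likelihood trace
  monotone on every dataset (`$ll_trace` records it);
* convergence when the relative log-likelihood change falls below
  $10^{-8}$, capped at 100 iterations (`converged = FALSE` flags the cap);
* the linear predictor is clipped at 30 inside the likelihood to avoid
  overflow in pathological intermediate steps;
* degenerate inputs fail loudly: rank-deficient designs and all-zero counts
  (whose MLE sits at $-\infty$) are errors, not warnings.

The tests hold this implementation against two independent routes: R's own
`glm(family = poisson())` and a zoom-refined exhaustive grid search over the
coefficient plane.

## Climate handling

`read_temperature_grid()` loads CF-convention NetCDF with a
`(time, lat, lon)` variable (default `tasAdjust`, the bias-adjusted
near-surface air temperature of ISIMIP forcing files). Kelvin is detected
from the units attribute and converted at load — every quantity in the
package is °C, since the scientific parameters (the 13 °C ceiling, the
slope per °C) are Celsius. The daily time axis is truncated to calendar
dates (ISIMIP stamps noon, hence offsets of 0.5 days); non-daily axes are
errors. The land mask is "at least one non-missing time step", so
land-only files mask the ocean automatically.

`window_mean()` averages exactly the days of a calendar window; a grid
that misses days fails with the list of missing dates rather than silently
averaging fewer days. `extract_at()` realises the "nearest weather
station" analogue on a grid: the nearest *unmasked* cell center by
great-circle (haversine) distance, searched ring by ring up to
`max_radius` rings (default 3) so that coastal cities on land-only grids
reach their nearest land cell; distances are compared at metre resolution
and genuine ties break toward smaller $|$latitude$|$, then smaller
longitude. No interpolation is performed — one value, one cell — and an
area-average alternative is left as a documented possible extension.

The bundled survey table carries no longitudes (the usual extraction
schema does not include them), so a small city gazetteer ships with the
package; an explicit longitude column always overrides it.

## Projection and comparison

`project_scenario()` averages a scenario's grid over a Christmas window —
defined here as 22–28 December of the target year, a choice the sources
leave open beyond naming "Christmas", and configurable — and applies both
models cell-wise. `compare_to_baseline()` differences scenario fields
against the historical baseline (Christmas 1999 by default) cell-wise and
reports cosine-latitude area-weighted summary means, which exist for
regression testing and trend reading rather than as published quantities.
Masked cells never acquire values; linearity means a uniform $+\Delta$ °C
scenario shifts unclamped prevalence by exactly $\beta_1 \Delta$.

`run_pipeline()` chains the stages from one YAML config, validates every
input path before any computation, attaches the failing stage and record to
any error, and writes deterministic outputs (byte-identical CSVs on rerun).

## The synthetic world

The generators exist so that every stage can be exercised against known
ground truth without external downloads. Their defaults are fixed study
conditions, not tuning knobs:

| parameter | default | why |
|---|---|---|
| grid | 36 × 72 (5°) | coarse enough for seconds-scale tests, fine enough for nearest-cell logic |
| equator temperature | 27 °C | realistic annual-mean tropical value |
| latitudinal gradient | 0.6 °C/° | ≈ 50 °C equator-pole contrast |
| seasonal amplitude | 10 °C | mid-latitude seasonal swing; phase puts the northern minimum in mid-January so November–March is the cold season |
| daily noise SD | 2 °C | weather variability around the smooth cycle |
| land fraction | 0.3 | Earth-like land share, random mask |
| scenario offsets | +1.5/+2.5/+3.0/+4.5 °C | end-of-century warming vs ~2000 under a high-sensitivity model, ordered RCP2.6 → RCP8.5 |
| survey law | slope −0.5 %/°C, intercept 6.5 % | slope is the quantity of scientific interest; the intercept places the zero crossing at 13 °C, consistent with the no-attack ceiling |
| survey noise SD | 1 % | between-survey scatter |
| sites | 20 in 30–60 °N | the real table's size and (predominantly boreal) latitude band |
| sample sizes | log-uniform 67–4182 | the real table's extremes |
| diary law | $\beta = (0.3, -0.12)$, $T \sim U(-5, 15)$ | cool-season exposure with a strong cold effect |
| diaries | 4 patients × 550 days | over 2000 patient-days, the scale of deposited n-of-1 series |

Scenario grids share the historical weather realisation (the noise stream
is keyed to the date range), so a scenario minus its baseline is exactly
the uniform offset — the property the projection-linearity checks rely on.
Each generator draws from its own seed-derived stream and restores the
caller's RNG state, so adding a generator call never perturbs another.

What the generators do *not* emulate: spatial covariance and weather
autocorrelation (days and cells are independent given the smooth
structure), realistic coastlines, survey heterogeneity beyond Gaussian
noise, or overdispersed counts. Passing tests therefore demonstrate the
*statistical machinery* — unbiased recovery, correct intervals, exact
calendar and projection algebra — not that real RP data satisfy the linear
or Poisson laws.

## Test problem sizes

The suite's heavier checks use sizes chosen to finish in seconds while
leaving the statistics meaningful: 50 random tables for the least-squares
oracle; 2-coefficient Poisson problems with $n \le 200$ against the grid
search; 100 seeded replicates for each parameter-recovery check (full
climate→survey chain at the defaults; 500-day diaries), asserting 95 % CI
coverage of the truth in at least 90 of 100 — the conventional lower bound
for a binomial(100, 0.95) outcome.

## Known limitations

* One climate grid per run; no regridding, no multi-model ensembles, no
  uncertainty bands around the projections.
* No bias correction: inputs are assumed already bias-adjusted.
* The prevalence model is ecological and linear; it will not capture
  saturation near 0 % except by clamping.
* The Poisson model extrapolates $\exp(\beta_T T)$ far below the diary
  temperature range when applied to polar winter cells, inflating predicted
  attack frequencies there; area-weighted severity summaries should be read
  with this in mind (the published analogue only mapped the fields).
* No overdispersion or random-effects extension; diaries are treated as
  independent given covariates.
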