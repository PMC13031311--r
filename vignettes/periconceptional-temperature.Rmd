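---
title: "Periconceptional temperature anomalies and adult metabolic outcomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Periconceptional temperature anomalies and adult metabolic outcomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(periclim)
```

# The question and the identification idea

Ambient temperature around the time of conception has been proposed to
"prime" offspring metabolism (via brown adipose tissue programming), with
consequences visible decades later in outcomes such as BMI, waist
circumference, HbA1c, triglycerides and total cholesterol.  Raw temperature
cannot identify such an effect: it is confounded by geography (north–south
climate gradients correlate with deprivation and health) and by season of
conception (families who conceive in winter differ from those who conceive
in summer).  The identification strategy implemented here uses *day-specific
temperature anomalies*: the deviation of the daily mean temperature from the
long-run expectation for that exact place and day of year.  Whether a
particular January was unusually cold is quasi-random, uncorrelated with who
chooses to conceive in January and where they live.

The pipeline has three stages:

1. **Climatology** — for each weather station, fit the long-run expected
   daily mean temperature as a function of day of year, and compute daily
   deviations from it.
2. **Linkage and exposure** — interpolate the daily deviation field to each
   birthplace by inverse-distance weighting of stations within 200 km, and
   average it over windows around the estimated date of conception (DOC),
   taken as the birth date minus 266 days.
3. **Inference** — regress adult outcomes on the window-mean anomaly with
   area-by-birth-month fixed effects, covariates and area-clustered errors:
   \(y_{irt} = \alpha\,\mathrm{TempDev}_{irt} + \gamma_{rm} + X'_{irt}\beta +
   \varepsilon_{irt}\), with a logistic analogue for binarized outcomes and
   Holm correction across the five outcomes in each window.

Because the real data (a UK biobank cohort and the national daily
temperature archive) are access-restricted, the package ships a synthetic
world generator with stored ground truth, and the validation is by
simulation: parameter recovery, confounding removal, and measurement-error
attenuation.

# Stage 1: climatology and anomalies

The daily mean is `(tmin + tmax) / 2`.  Day of year is indexed 1–365; in
leap years February 29 shares index 59 with February 28 and later dates
shift down by one, so no day is discarded and December 31 is always 365.
A station enters the climatology if at least 30 calendar years in 1933–1971
have at least 180 valid daily records; the 180-day floor is this package's
reading of "a year with data", and both knobs are configurable.

The long-run profile is ordinary least squares of the daily mean on a
degree-4 polynomial of the day index.  Internally the index is affinely
rescaled to \([-1, 1]\) before powering — raw `day^4` reaches \(1.8\times
10^{10}\) and makes the normal equations ill-conditioned — and predictions
are invariant to this rescaling (`test-climatology.R` checks this against a
naive unscaled fit).  All pooled observations enter one fit, so each day of
year is weighted by how often it was observed; for balanced data this
coincides with smoothing per-day means.  Two properties follow from
OLS-with-intercept and are enforced by tests: deviations average to ~0 over
the fit data, and adding a constant to every record leaves deviations
unchanged after refitting.

A degree-4 polynomial cannot represent a cosine exactly: for a seasonal
harmonic of amplitude \(A\) the best \(L_2\) degree-4 approximation has a
maximum error of about \(0.104A\) (~0.73 °C at \(A = 7\) °C), an oscillating
day-of-year pattern we call *seasonal leakage*.  The tests pin the fit to a
dense-grid least-squares oracle rather than to a fixed error bound.  The
polynomial is also not periodic across the December 31 → January 1 boundary;
the discontinuity is accepted, as any single polynomial in day-of-year
implies.  Leakage matters twice below: it is the mechanism that makes a
no-fixed-effects model genuinely confounded in the simulation, and a small
attenuating measurement error in the estimated exposure.

# Stage 2: linkage and exposure windows

Distances are inverse Vincenty on the WGS84 ellipsoid (iterated to
\(|\Delta\lambda| < 10^{-12}\), 200 iterations, great-circle fallback for
near-antipodal pairs, which cannot occur at UK scale); the implementation is
cross-checked against an independent geodesic library and the exact
equatorial closed form.  Stations within an inclusive 200-km radius
contribute with weights \(\propto 1/\max(d, 10^{-6}\,\mathrm{km})^p\),
renormalized each day over the stations actually reporting; \(p = 1\) by
default (the exponent is not pinned down by the method description, so it is
exposed as a configuration option, with nearest-neighbour as the robustness
alternative).  Interpolation is per-day first, then time-averaged: the two
orders coincide with complete data, and with gaps the per-day renormalization
uses all available information.  `build_exposure_table()` exploits exactly
this: when every in-radius station reports every window day, the per-day
scheme collapses to a weighted sum of station window means computed from
cumulative sums, which is the fast path; gappy rows fall back to the literal
per-day loop, and tests assert the two paths agree to \(10^{-10}\).

The five windows are anchored at the estimated DOC (birth − 266 days):
the DOC day itself, and −2w;DOC, −3w;+1w, −4w;+2w, −5w;+3w with lengths
14/28/42/56 days.  "Till DOC" is read as *up to but not including* the
conception day: that is the only convention under which +1 °C confined to
the two pre-conception weeks averages to exactly +0.25 °C over the 8-week
window, the worked dilution identity the tests enforce.  The 15-day
inclusive reading remains available by editing the offset table in one
place.  An exposure is reported only when at least 80% of window days have
an interpolated value (configurable); participants with no in-radius station
keep all-missing rows and are counted.

# Stage 3: inference

The linear model absorbs area-by-birth-month cells (e.g. 24 areas × 12
months) by the within transformation; the estimate is numerically identical
to explicit dummy-variable OLS (tested to \(10^{-8}\), coefficients and
residuals).  Sex, year of birth and year of assessment enter as categorical
dummies — "controlling for" a year is read as a flexible categorical trend,
matching the fixed-effects style.  Standard errors are CR1 cluster-robust at
the area level: \((X'X)^{-1}\left[\sum_g X_g'e_g e_g' X_g\right](X'X)^{-1}\)
scaled by \(\frac{G}{G-1}\frac{N-1}{N-K}\), with \(K\) counting *all*
estimated parameters including the absorbed cells — within-transform
residuals are deflated by the absorbed parameters and the \((N-1)/(N-K)\)
factor restores their scale on average (our null simulations confirm the
uncorrected version over-rejects when cells are small).  Inference uses
\(t_{G-1}\).  With a single cluster the function refuses and points to a
heteroskedasticity-robust alternative.  Singleton cells are retained in
linear fits (they self-absorb); in logistic fits, cells whose outcome does
not vary are dropped with a count, since they carry no likelihood
information.  The logistic model is plain MLE with the cells as dummy
columns, as the model is written; a warning fires when the average cell size
drops below 20, where incidental-parameter bias becomes a concern.
Cluster-robust covariance for the logistic fits comes from the sandwich
estimator.  Holm correction is applied across the five outcomes within each
window (delegating to `stats::p.adjust`).

Binary outcomes use the conventional risk cutoffs, all inclusive:
BMI ≥ 25 kg/m², waist ≥ 94 cm (men) / ≥ 80 cm (women), HbA1c ≥ 39 mmol/mol,
triglycerides ≥ 1.7 mmol/l, total cholesterol ≥ 5.2 mmol/l.

# The synthetic world

`sim_config()` defines the study conditions; the defaults are UK-like and
are the conditions under which the package's claims are tested:

* **Stations**: 25 stations uniform over a 50–58.5° N, −6–1.8° E box,
  1933–1971, daily mean = 9 °C + (−0.6 °C/°lat) latitude gradient + a
  seasonal harmonic of amplitude 7 °C peaking at day 197 (UK seasonal range)
  + a *shared* regional AR(1) anomaly (SD 2 °C, lag-1 autocorrelation 0.7,
  matching the few-day persistence of weather) + independent per-station
  noise (SD 0.5 °C, instrument/microclimate); records are emitted as
  mean ∓ half of a 7 °C diurnal range.  One shared anomaly process rather
  than a spatial covariance field is deliberate: it is what the IDW and
  fixed-effects machinery needs, at a fraction of the cost.
* **Cohort**: 20,000 participants over 24 grid areas, birthplace uniform in
  the area, true conception dates drawn from an area-specific von-Mises-style
  day-of-year weighting peaking near December; gestation ~ round(Normal(266,
  9)) days truncated at ±6 SD (9 days reflects observed gestation-length
  variation), birth = conception + gestation.  Outcomes have realistic
  intercepts and residual SDs (so the binarization cutoffs land at sensible
  prevalences), plus area effects, a sex shift, a small birth-year trend, a
  seasonal conception-timing effect (amplitude `fertility_season_strength`
  outcome-SDs, phase-aligned with the temperature harmonic), and
  `true_alpha` times the **regional anomaly on the true conception day**.
* **Ground truth** (true conception dates and conception-day anomalies) is
  written to a sidecar file marked test-only and is never consumed by the
  inference stage.

Two design choices deserve their reasoning spelled out.

**The true exposure is the conception-day anomaly, not a multi-day window.**
With a multi-day true window, moderate conception-date error can move the
*estimated* day into the true window and increase, not decrease, its
covariance with the truth, destroying the monotone attenuation that the
measurement-error experiment checks.  A single true day with an AR(1)
anomaly gives covariance \(\propto \mathbb{E}[\rho^{|\delta|}]\), strictly
decreasing in the gestation-noise scale — the cleanest possible attenuation
benchmark.

**Default effect sizes are larger than a biobank-scale study would report.**
`true_alpha` defaults to roughly 3% of an outcome SD per °C.  Real effects
of ~0.3% SD need ~40× the sample to measure; at the simulation's n = 20,000,
recovery bias could not be resolved from Monte-Carlo noise at realistic
sizes.  The simulated effect is a *detectability* choice, not a claim about
plausible magnitudes, and every recovery statement is relative to it.

What the generator does **not** emulate: real UK geography and station
placement, spatially decaying weather correlation, quality-control flags and
station moves, realistic disease prevalences, migration between conception
and birth.  Passing tests therefore show the *method* is correct under its
assumptions, not that the headline epidemiological estimates are
reproducible from this package (they require the restricted data).

# Simulation experiments and their sizing

All experiment sizes were fixed at design time, before the corresponding
tests were frozen, by pilot power calculations under the null or by analytic
approximation; none was chosen by iterating on a failing test.

* **Parameter recovery** (`experiment_recovery`): 100 replicates of the full
  pipeline at n = 20,000 with `gestation_sd = 0`.  Checks that the 95%
  cluster-robust CI covers the true effect ≥ 93/100 times and the mean bias
  is below 5% of the truth.  Residual attenuation of ~1–3% is expected from
  seasonal leakage and IDW-weighted station noise, and is well inside the
  bias budget.
* **Confounding removal** (`experiment_confounding`): 200 replicates,
  n = 6,000, 48 areas, true effect zero, `fertility_season_strength = 3`.
  The seasonal outcome effect is correlated with the exposure only through
  the seasonal leakage of the polynomial climatology, which is exactly how
  season confounds anomaly exposures in the real design.  The naive
  no-fixed-effects regression should reject far above its nominal 5% level
  and the area-by-birth-month FE model near it.  The n and area count were
  chosen by a *null* calibration pilot (`fss = 0`): with many absorbed cells
  and few observations per cell the \((N-1)/(N-K)\) correction dominates and
  the nominal test turns conservative, while n = 6,000 with 48 areas is
  close to nominal.  The confounding strength 3 (a 3-outcome-SD seasonal
  amplitude) is a stress level chosen so the naive model's bias is
  unambiguous at n = 6,000.
* **Attenuation** (`experiment_attenuation`): 100 replicates × gestation SD
  ∈ {0, 5, 10, 15} days at n = 4,000, common seed per replicate across
  levels, true effect 0.5 outcome-SD per °C so that the attenuated signal at
  SD 15 still dominates sampling noise.  Mean |estimate| must be
  non-increasing in gestation SD (plus paired rank tests between consecutive
  levels).  Longer windows attenuate *less* in relative terms, since a
  window overlaps the true day even when the point estimate of the DOC is
  off.

# Numerical choices and degenerate inputs

* Polynomial fitting: rescaled basis, `lm.fit`; rank deficiency errors with
  the station named; fewer than 5 distinct day-of-year values errors.
* Vincenty: tolerance \(10^{-12}\) rad, 200 iterations, logged great-circle
  fallback; coordinates validated.
* IDW: zero-distance clamp at \(10^{-6}\) km, so a participant on top of a
  station receives that station's value; weights renormalized over the
  reporting subset each day.
* Exposure: coverage floor 0.8; out-of-span window days count as missing.
* Within-transform: exposure constant within every cell is an identification
  error; covariate columns with no within-cell variance are dropped before
  the solve.
* Holm: `p.adjust`, family = five outcomes per window, per family and
  stratum.
* Rounding for display is half-away-from-zero (`round_half_up`), matching
  printed-table conventions; machine outputs keep full precision.
* Seeds: one run seed fans out to named per-stage substreams
  (`stage_seed`), so stations, cohort and placebo generation can be re-run
  in isolation; all derived seeds stay below \(2^{31}\).

# Known limitations

* The logistic FE model is unconditional MLE; with small cells the
  incidental-parameter problem biases it (hence the warning).  Conditional
  logit was deliberately not substituted, since the model is specified with
  dummy intercepts.
* CR1 + \(t_{G-1}\) is approximate with few clusters; the package refuses
  only the degenerate G = 1 case.
* The climatology is fitted on the same years used for exposure, so a small
  share of realized anomalies is absorbed into the profile (order 1/39 here);
  with the real 39-year record this is the standard and unavoidable choice.
* Anomalies are interpolated from point stations; no elevation or coastal
  adjustment (kriging is out of scope).
* Scenario translations scale linearly, including CI endpoints; no
  extrapolation uncertainty is added.

# Problem sizes used in the shipped runs

The analysis scripts under `analysis/` run the narrative pipeline at
n = 20,000 with 25 stations and reduced replicate counts (25–50) for the
experiments; the test suite and `scripts/acceptance.R` run the full
experiment sizes stated above.  These sizes are the package's validation
design: large enough that every tested property is resolved with margin,
small enough that a full validation runs on a single CPU in minutes.
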