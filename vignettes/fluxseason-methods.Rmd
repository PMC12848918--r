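---
title: "Models, synthetic world and numerical choices in fluxseason"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, synthetic world and numerical choices in fluxseason}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxseason)
```

## The scientific problem

Chamber-collar campaigns measure soil respiration (Rs) a few mornings per
month at a handful of forest stands, together with soil temperature at
10 cm (T) and volumetric soil moisture in the 0–10 cm layer (W). Three
questions follow: how does Rs respond to T and W; how temperature-sensitive
is it (Q10); and what annual carbon flux does each stand release once the
point measurements are scaled through a daily soil-temperature series. In
monsoon climates, all of this is organised around the dry (November–April)
and wet (May–October) seasons; `assign_season()` uses the calendar month
only, because campaigns never split months across seasons.

## Response models and their assumptions

Three fixed functional forms are fitted per stand:

* `Rs = m + n W` — ordinary least squares;
* `Rs = a e^{bT}` — the exponential temperature response, from which
  `Q10 = e^{10 b}`;
* `Rs = a e^{bT} W^c` — the bivariate form, with the univariate models as
  special cases.

Assumptions worth making explicit:

* **Fitting scale.** The default method is nonlinear least squares on the
  original rate scale, initialised from the log-linear closed form
  (`ln Rs = ln a + b T (+ c ln W)`). Field reports tabulate "R² of Rs", so
  R² is always reported as `1 − SSE/SST` *on the rate scale* — for a
  nonlinear fit this can be smaller than the squared correlation, and for
  the log-linear method it can even be negative on pathological data. Both
  methods are exposed (`method = "nls"` / `"loglinear"`) because published
  tables rarely say which was used; on noise-free data they agree to
  machine precision (tested).
* **Error structure.** NLS assumes additive homoscedastic errors, but
  chamber noise is multiplicative and right-skewed. Because the noise is
  mean-one, the NLS estimating equations remain consistent; the residual
  heteroscedasticity mainly inflates parameter standard errors. The
  log-linear method is the matching estimator for lognormal noise.
* **Significance.** Model p-values come from the F-test against the
  constant-mean model; stars follow the field convention (** p<0.01,
  * p<0.05).
* **Q10 uncertainty.** Published Q10 ± values rarely state a derivation;
  this package reports a delta-method se (`10 · Q10 · se(b)`) from the nls
  fit and labels it as its own choice; `bootstrap_flux()` provides the
  resampling analogue for the annual flux.

Records with `rs ≤ 0` are excluded from log-linear paths with a logged
count; they are retained by the rate-scale NLS.

## Air→soil calibration and annual upscaling

Monthly calibrations between soil and air temperature are conventionally
*printed* as air-on-soil regressions (`air = slope · soil + intercept`)
yet *used* to predict soil from air. `fit_calibration()` mirrors this:
the default fits the printed direction and `predict_daily_soil_temp()`
applies the algebraic inverse `(air − intercept)/slope`. Because the
inverse of a regression line is not the least-squares line of the swapped
variables, a direct `soil_on_air` fit is offered as an escape hatch.

The annual flux integrates the exponential model day by day,

    R = Σ_d a e^{b T_d} · 3600·24·12·10⁻⁶   [gC m⁻² a⁻¹],

which holds the daily mean rate constant over 24 h (that is what the
3600·24 factor implies) and fixes the molar mass of carbon at exactly
12 g mol⁻¹. `annual_flux()` refuses series that do not cover 365 or 366
consecutive days: silent gap-filling would make fluxes incomparable
between stands. Uncertainty comes from resampling whole collars with
replacement (collars are the replication unit; observations within a
collar are not independent), refitting, and re-integrating; the CI is the
2.5/97.5 percentile.

## The synthetic world

The generator exists so that every downstream stage can be tested against
known truth. Its defaults describe a four-stand tropical coastal
shelter-forest campaign (CA *Casuarina*, CO coconut, MF mixed plantation,
SF secondary forest): one year sampled monthly from September, 18 collars
per stand in 3 plots, with

* **Generative law**: the bivariate model, per-stand `(a, b, c)` from the
  published bivariate regressions — so the univariate fits are, by
  construction, mildly misspecified, exactly as in the real model
  hierarchy. (The SF bivariate temperature coefficient is taken equal to
  its univariate value 0.102; the printed 0.01 is a truncation artefact.)
* **Climate**: daily air temperature is a sinusoid (minimum mid-January,
  maximum mid-July) solved so the dry/wet seasonal means equal the
  stand's published envelopes *exactly* in the noise-free limit, plus
  Gaussian day-to-day noise (sd 1.2 °C — maritime tropical sites have
  small synoptic variability). Rainfall is Bernoulli–gamma with expected
  monthly totals equal to the seasonal envelopes; the implied wet-season
  share of annual precipitation is 86–91% for these stands (the region is
  often described as "about 80%", but the per-stand monthly envelopes are
  what the driver statistics consume, so they win).
* **Soil temperature**: the truth calibration line inverted on daily air
  temperature plus noise (sd 0.3 °C, a thermometer-precision scale — this
  also keeps errors-in-variables attenuation of b̂ below 1%). The printed
  calibration tables for these forests have slopes ≥ 1, which contradicts
  the same study's observed seasonal soil-temperature amplitudes
  (5.63/7.10/6.28/5.12 °C wet-minus-dry against air amplitudes of only
  4.38–4.80 °C). The default truth lines are therefore derived from the
  amplitudes — `slope = Δair/Δsoil` through the seasonal midpoint, with
  the SF dry-season soil mean anchored at 21.2 °C and the other stands
  offset by their reported dry-season differences. Two consequences favour
  this choice: the wet/dry respiration ratios land at ≈1.65–1.85
  (bracketing the observed 1.69–2.04), and integrating the published
  univariate `(a, b)` over the resulting soil year reproduces the
  published annual fluxes to within ~5%. With the printed lines instead,
  ratios fall to ≈1.25 for the coconut stand and the flux ordering
  degrades — the printed lines and the observed seasonal course cannot
  both be true.
* **Soil moisture**: a seasonal baseline (dry/wet means; differences
  between stands read as percentage *points*, which is the only reading
  that makes the published dry-season and wet-season differences mutually
  consistent; the SF dry-season mean is anchored at 22 vol%, a reasonable
  value for moist secondary-forest sandy loam) plus two phenomenological
  mid-season dips producing the W-shaped annual course, precipitation
  anomaly pulses, and noise, clipped to (0, 100). Dips and pulses are
  centred within each season, so noise-free seasonal means are exact. No
  water-balance model is attempted — the W shape is imposed, not derived.
* **Campaign noise**: persistent mean-one lognormal collar offsets
  (sd 0.10) times mean-one lognormal observation noise with CV 0.25. The
  CV was chosen once so the synthetic exponential-fit R² falls in the
  0.57–0.85 band typical of such campaigns; collar offsets cancel in
  wet/dry ratios because the same collars are measured in both seasons.
  Observed T and W carry additive Gaussian measurement noise; observed
  moisture is floored at 0.1 vol% (probes do not read zero, and the
  power-law moisture term requires W > 0).
* **Chemistry**: one dry and one wet record per stand, each variable
  Normal around its published mean ± sd, truncated to the schema
  invariants (pH in (0,14), concentrations > 0, SOC < SOM).

What a green test does and does not establish: the generator reproduces
the *seasonal structure* (envelopes, ratios, flux ordering and magnitude)
and known parameter recovery; it deliberately omits spatial
autocorrelation between collars, typhoon/salinity disturbance pulses,
sub-daily chamber dynamics and rain-event respiration pulses. Tests green
against this world validate the estimators and plumbing, not those field
phenomena.

## Environmental-driver statistics

* **Aggregation level.** Correlation screens and importance rankings run
  on stand × month rows within a season (monthly mean Rs joined with
  monthly climate aggregates and the stand's seasonal chemistry) — the
  published per-season analyses imply aggregate rows, but their exact n
  is unstated, so the row construction is documented here rather than
  asserted as "the" original. Collar-level tables can be passed directly
  to `pearson_screen()` if preferred.
* **LSD letters.** One-way ANOVA followed by unadjusted pairwise t-tests
  on the pooled MSE — Fisher's LSD exactly as named, with no multiplicity
  correction, which is anti-conservative with many groups. The compact
  letter display uses insert-and-absorb, which guarantees the
  biconditional: two groups share a letter *iff* their pair is
  non-significant (verified against all-pairs brute force on random
  fixtures).
* **Variable importance.** No random-forest package is assumed: a bagged
  CART regression-tree ensemble (bootstrap samples, per-node random
  feature subsets, default 500 trees, mtry = ⌊p/3⌋, minimum node size 5)
  is implemented in `src/`, with importance = mean increase in out-of-bag
  MSE when a feature is permuted. Significance is this package's choice:
  the response is permuted (default 500 times), the ensemble refitted,
  and a variable is significant when its observed importance exceeds the
  1−α quantile of the *maximum* importance across variables under the
  null. The max-statistic controls the family-wise error rate — with ten
  correlated per-variable tests at α = 0.05, a per-variable null would
  flag a spurious driver in roughly 40% of pure-noise analyses, which is
  useless for screening. Feature columns are canonicalised alphabetically
  before fitting so results are invariant to column order; ties in
  importance are broken alphabetically.

## Numerical choices and degenerate inputs

* NLS uses `scaleOffset = 1` so artificial zero-residual (noise-free)
  data converges rather than erroring; start values of exactly zero are
  nudged to 1e-8 because the numeric-derivative step is relative and a
  zero start yields a zero gradient column.
* Constant predictors raise degenerate-design errors; constant columns in
  correlation screens are flagged, not fatal.
* Dates are strict ISO-8601; unparseable dates are errors, never NAs.
* Writers round rates to 4 decimals and temperatures/moisture to 2; the
  read/write round trip is lossless at that declared precision. YAML
  configs serialise doubles at 17 significant digits so a written config
  regenerates bit-identical studies.
* All randomness flows from a single seed through named sub-streams
  (climate/microclimate/campaign/chemistry/bootstrap/importance per
  stand), so pipeline stages are individually reproducible and full runs
  are byte-identical.

## Known limitations

* The univariate exponential fit carries a small (+2–3% on b) upward
  misspecification gap under the bivariate generative law, because
  moisture co-varies with temperature seasonally; this is a property of
  the model hierarchy, not an estimator defect, and disappears in the
  bivariate fit.
* LSD letters are anti-conservative; treat single shared/unshared letters
  near the α boundary with caution.
* The bootstrap resamples collars within a stand (n = 18), so CI
  endpoints are themselves noisy at the few-percent level.
* Published percent differences between stands do not all reconcile with
  the published fluxes at 2-decimal precision (the secondary-forest vs
  coconut figure is one such case); the package computes, it does not
  adjudicate.
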