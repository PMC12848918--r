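# fluxseason

Seasonal soil-respiration modelling and annual carbon-flux upscaling for
collar-based chamber campaigns in monsoon-climate forests.

Soil respiration (Rs, μmol CO₂ m⁻² s⁻¹) is the dominant pathway returning
soil carbon to the atmosphere. In strongly seasonal coastal forests it is
measured with chamber collars a few days per month, then scaled to an
annual carbon budget through its temperature response. `fluxseason`
packages that workflow for ecosystem ecologists:

* **Response models.** The three standard forms, fitted per stand:

  * moisture: `Rs = m + n·W`
  * temperature: `Rs = a·e^(bT)`, with temperature sensitivity
    `Q10 = e^(10b)`
  * bivariate: `Rs = a·e^(bT)·W^c`

  where `T` is soil temperature at 10 cm (°C) and `W` volumetric soil
  moisture in the 0–10 cm layer (%). Nonlinear fits run on the rate scale
  (R² = 1 − SSE/SST there), initialised from the log-linear closed form;
  the log-linear fit is exposed as an alternative method.

* **Annual upscaling.** A monthly air↔soil temperature calibration line
  (fitted in the conventionally printed air-on-soil direction and inverted
  for prediction) maps daily weather-station air temperature to daily soil
  temperature; the annual flux is
  `R = Σ_d a·e^(bT_d) · 3600·24·12·10⁻⁶` (gC m⁻² a⁻¹), with a
  collar-resampling bootstrap CI.

* **Seasonal driver statistics.** Dry (Nov–Apr) / wet (May–Oct) seasonal
  summaries, wet/dry ratios and percent differences, Pearson screens of
  respiration against ten environmental factors, one-way ANOVA with
  Fisher-LSD compact letter displays, and permutation variable importance
  from a bagged regression-tree ensemble (built in, with a family-wise
  response-permutation significance test).

* **Synthetic studies.** A fully parameterised generator (4 stands ×
  12 monthly visits × 18 collars by default, with daily climate, soil
  microclimate, campaign noise and per-season soil chemistry) whose
  generative truth is recorded alongside the data, so every stage of the
  pipeline is testable without field data.

## Worked example

```r
library(fluxseason)

bundle <- generate_study(study_config(), seed = 7)
#> <study_bundle> 4 stands, 864 measurements, 1464 climate days, seed 7

sf  <- subset(bundle$measurements, stand_id == "SF")
fit <- fit_temperature_exponential(sf)
fit
#> <exponential_fit> Rs = 0.3706 exp(0.0996 T)   Q10 = 2.71
#>   R2 = 0.648**  (n = 216)
```

The secondary forest's respiration rises by a factor `Q10 = 2.71 ± 0.15`
(delta-method se) per 10 °C of soil warming, and soil temperature explains
65% of the rate variance across the 216 collar observations. Wet-season
respiration exceeds dry-season respiration in every stand:

```r
round(wet_dry_ratio(bundle$measurements, "rs"), 2)
#>   CA   CO   MF   SF
#> 1.87 1.68 2.22 1.86

tab <- reproduce_table4(bundle$measurements, bundle$climate, n_boot = 200, seed = 7)
tab[, c("stand_id", "a_exp", "b_exp", "r2_exp", "q10", "flux",
        "flux_ci_low", "flux_ci_high")]
#>   stand_id a_exp  b_exp r2_exp  q10 flux flux_ci_low flux_ci_high
#> 1       CA 0.198 0.0926  0.636 2.52  875         796          904
#> 2       CO 0.362 0.0710  0.565 2.03 1044         945         1067
#> 3       MF 0.209 0.0889  0.692 2.43 1043         961         1069
#> 4       SF 0.371 0.0996  0.648 2.71 1684        1565         1712
```

The annual fluxes (gC m⁻² a⁻¹, with 95% bootstrap CIs) rank the secondary
forest far above the plantations — the spatial pattern the driver
statistics then attribute mostly to soil organic matter.

The same pipeline runs end to end from the command line:

```sh
exec/fluxseason run --simulate --seed 7 --out outdir   # fits.json, flux.json, ...
```

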