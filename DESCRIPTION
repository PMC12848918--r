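Package: fluxseason
Title: Seasonal Soil Respiration Modelling and Annual Carbon Flux Upscaling
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for collar-based soil respiration campaigns in strongly
    seasonal (dry/wet monsoon) forest ecosystems: validated readers for
    measurement, daily-climate and soil-chemistry tables; a synthetic study
    generator with known generative truth; linear, exponential and bivariate
    temperature/moisture response model fitting with Q10 temperature
    sensitivity; air-to-soil temperature calibration and annual carbon flux
    upscaling with bootstrap uncertainty; and seasonal environmental-driver
    statistics (seasonal summaries, Pearson screens, one-way ANOVA with LSD
    compact letter displays, and permutation variable importance from a
    bagged regression-tree ensemble).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
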