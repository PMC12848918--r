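test_that("calibration fits recover pinned lines and handle errors", {
  soil <- seq(18, 30, length.out = 12)
  # identity pairs
  f0 <- fit_calibration(soil, soil)
  expect_equal(f0$slope, 1, tolerance = 1e-12)
  expect_equal(f0$intercept, 0, tolerance = 1e-10)
  expect_equal(f0$r2, 1, tolerance = 1e-12)

  # noise-free pairs from a printed air-on-soil line
  air <- 1.067 * soil - 1.078
  f1 <- fit_calibration(soil, air, direction = "air_on_soil")
  expect_equal(f1$slope, 1.067, tolerance = 1e-9)
  expect_equal(f1$intercept, -1.078, tolerance = 1e-9)

  # noisy months give r2 strictly inside (0, 1) and a p-value
  set.seed(3)
  f2 <- fit_calibration(soil, air + rnorm(12, 0, 0.6))
  expect_true(f2$r2 > 0 && f2$r2 < 1)
  expect_true(f2$p_value > 0 && f2$p_value <= 1)
  expect_equal(f2$n_months, 12L)

  expect_error(fit_calibration(soil, air[-1]), class = "fs_alignment_error")
  expect_error(fit_calibration(rep(20, 5), 1:5), class = "fs_degenerate_error")
  expect_error(fit_calibration(soil[1:2], air[1:2]), class = "fs_argument_error")
})

test_that("daily soil temperature prediction inverts or applies the line", {
  ca <- list(slope = 1.067, intercept = -1.078, direction = "air_on_soil")
  expect_equal(round(predict_daily_soil_temp(ca, 25), 2), 24.44)

  ident <- list(slope = 1, intercept = 0, direction = "air_on_soil")
  x <- runif(30, 15, 32)
  expect_equal(predict_daily_soil_temp(ident, x), x)

  fwd <- list(slope = 0.85, intercept = 3.1, direction = "soil_on_air")
  expect_equal(predict_daily_soil_temp(fwd, 25), 0.85 * 25 + 3.1)

  # forward/inverse round trip
  soil <- runif(50, 15, 32)
  air <- 1.067 * soil - 1.078
  expect_equal(predict_daily_soil_temp(ca, air), soil, tolerance = 1e-12)

  expect_error(predict_daily_soil_temp(list(slope = 0, intercept = 1,
                                            direction = "air_on_soil"), 20),
               class = "fs_degenerate_error")
})

test_that("daily flux applies the exact unit conversion", {
  expect_equal(daily_flux(1, 0, 25), 86400 * 12 * 1e-6)  # 1.0368 exactly
  expect_equal(daily_flux(0, 0.1, 25), 0)
  expect_equal(daily_flux(0.174, 0.098, 25),
               0.174 * exp(2.45) * 1.0368, tolerance = 1e-12)
  expect_equal(round(daily_flux(0.174, 0.098, 25), 2), 2.09)
  expect_error(daily_flux(-1, 0, 25), class = "fs_argument_error")
})

test_that("annual flux sums the days and guards coverage", {
  days <- data.frame(date = seq(as.Date("2023-09-01"), by = "1 day",
                                length.out = 365),
                     soil_temp = 20)
  est <- annual_flux(1, 0, days)
  expect_equal(est$flux, 378.432)   # 365 * 1.0368 exactly
  expect_equal(est$n_days, 365L)

  # closed form at constant temperature
  days$soil_temp <- 23.5
  expect_equal(annual_flux(0.3, 0.08, days)$flux,
               365 * 0.3 * exp(0.08 * 23.5) * 1.0368, tolerance = 1e-12)

  # toy 2-day series with the guard disabled
  toy <- annual_flux(1, 0.1, c(0, 10), allow_partial = TRUE)
  expect_equal(toy$flux, 1.0368 * (1 + exp(1)), tolerance = 1e-12)

  # leap-year coverage: 366 days accepted, 366 terms summed
  leap <- data.frame(date = seq(as.Date("2023-09-01"), by = "1 day",
                                length.out = 366),
                     soil_temp = 20)
  expect_equal(annual_flux(1, 0, leap)$flux, 366 * 1.0368)

  gappy <- days[-100, ]
  expect_error(annual_flux(1, 0, gappy), "gaps", class = "fs_coverage_error")
  expect_error(annual_flux(1, 0, days[1:100, ]), class = "fs_coverage_error")
})

test_that("annual flux is strictly increasing in a, and in b for positive temperatures", {
  days <- data.frame(date = seq(as.Date("2023-09-01"), by = "1 day",
                                length.out = 365),
                     soil_temp = runif(365, 10, 32))
  f <- vapply(c(0.1, 0.2, 0.4), function(a) annual_flux(a, 0.08, days)$flux, 0)
  expect_true(all(diff(f) > 0))
  g <- vapply(c(0.05, 0.08, 0.12), function(b) annual_flux(0.2, b, days)$flux, 0)
  expect_true(all(diff(g) > 0))
})

test_that("bootstrap flux CIs behave like percentile intervals", {
  tr <- noise_free_truth(a = 0.25, b = 0.09, c = 0)
  cl <- simulate_daily_climate(tr, "2023-09-01", 365, seed = 1)
  mc <- simulate_soil_microclimate(cl, tr, seed = 2)
  days <- data.frame(date = mc$date, soil_temp = mc$soil_temp)

  # zero-noise records: degenerate bootstrap, CI width ~ 0
  meas0 <- simulate_campaign(tr, mc, monthly_schedule(), n_collars = 6, seed = 3)
  est0 <- bootstrap_flux(meas0, days, n_boot = 200, seed = 4)
  expect_lt(est0$ci_high - est0$ci_low, 1e-6 * est0$flux)

  # noisy records: CI contains the point estimate, stable across seeds
  trn <- default_stand_truths()$CA
  cln <- simulate_daily_climate(trn, "2023-09-01", 365, seed = 5)
  mcn <- simulate_soil_microclimate(cln, trn, seed = 6)
  measn <- simulate_campaign(trn, mcn, monthly_schedule(), n_collars = 18,
                             seed = 7)
  daysn <- data.frame(date = mcn$date, soil_temp = mcn$soil_temp)
  e1 <- bootstrap_flux(measn, daysn, n_boot = 400, seed = 11)
  e2 <- bootstrap_flux(measn, daysn, n_boot = 400, seed = 12)
  expect_true(e1$ci_low <= e1$flux && e1$flux <= e1$ci_high)
  w1 <- e1$ci_high - e1$ci_low; w2 <- e2$ci_high - e2$ci_low
  expect_lt(abs(w1 - w2) / w1, 0.25)
  expect_identical(unclass(bootstrap_flux(measn, daysn, 200, seed = 9)),
                   unclass(bootstrap_flux(measn, daysn, 200, seed = 9)))

  few <- measn[measn$collar_id %in% c("C01", "C02"), ]
  expect_error(bootstrap_flux(few, daysn, 200), class = "fs_resampling_error")
  expect_error(bootstrap_flux(measn, daysn, n_boot = 50),
               class = "fs_argument_error")
})

test_that("flux ordering across default stands follows the truth parameters", {
  # with the stand-level univariate parameters as truth (c = 0) and each
  # stand's own calibrated soil temperature, annual flux orders SF > CO > MF > CA
  uni <- list(CA = c(0.174, 0.098), CO = c(0.357, 0.071),
              MF = c(0.214, 0.088), SF = c(0.331, 0.102))
  defaults <- default_stand_truths()
  flux <- vapply(names(uni), function(id) {
    tr <- defaults[[id]]
    tr$a_true <- uni[[id]][1]; tr$b_true <- uni[[id]][2]; tr$c_true <- 0
    for (f in c("air_noise_sd", "temp_noise_sd")) tr[[f]] <- 0
    cl <- simulate_daily_climate(tr, "2023-09-01", 365, seed = 21)
    mc <- simulate_soil_microclimate(cl, tr, seed = 22)
    annual_flux(tr$a_true, tr$b_true,
                data.frame(date = mc$date, soil_temp = mc$soil_temp))$flux
  }, 0)
  expect_equal(names(sort(flux, decreasing = TRUE)), c("SF", "CO", "MF", "CA"))
})
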