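test_that("noise-free climate hits the seasonal air-temperature envelope exactly", {
  tr <- noise_free_truth()
  cl <- simulate_daily_climate(tr, "2023-09-01", 366L, seed = 1)
  wet <- assign_season(cl$date) == "wet"
  # deterministic sinusoid is solved against the envelope; the envelope gap
  # for this truth is 5 degC by construction
  expect_equal(mean(cl$air_temp[wet]), 27, tolerance = 1e-3)
  expect_equal(mean(cl$air_temp[!wet]), 22, tolerance = 1e-3)
  jan <- as.integer(format(cl$date, "%m")) == 1
  jul <- as.integer(format(cl$date, "%m")) == 7
  expect_lt(mean(cl$air_temp[jan]), mean(cl$air_temp[jul]))
})

test_that("default stands keep the wet-dry air envelope gap in the regional range", {
  for (tr in default_stand_truths()) {
    tr$air_noise_sd <- 0
    cl <- simulate_daily_climate(tr, "2023-09-01", 365L, seed = 1)
    wet <- assign_season(cl$date) == "wet"
    gap <- mean(cl$air_temp[wet]) - mean(cl$air_temp[!wet])
    expect_true(gap >= 4.38 - 0.05 && gap <= 4.80 + 0.05)
  }
})

test_that("wet-season precipitation share matches the envelope-implied share", {
  # the seasonal envelopes imply wet shares of ~0.86-0.91; sampling sd of
  # the realised share is ~0.02, tolerance set at ~3 sd
  for (tr in default_stand_truths()[c("CA", "SF")]) {
    cl <- simulate_daily_climate(tr, "2023-09-01", 365L, seed = 5)
    wet <- assign_season(cl$date) == "wet"
    implied <- (6 * tr$precip_wet) / (6 * tr$precip_wet + 6 * tr$precip_dry)
    share <- sum(cl$precip[wet]) / sum(cl$precip)
    expect_lt(abs(share - implied), 0.06)
  }
})

test_that("climate simulation is deterministic under a seed and errors on bad n_days", {
  tr <- default_stand_truths()$CA
  expect_identical(simulate_daily_climate(tr, seed = 9),
                   simulate_daily_climate(tr, seed = 9))
  expect_error(simulate_daily_climate(tr, n_days = 0), class = "fs_argument_error")
})

test_that("soil temperature inverts the printed-direction calibration line", {
  # air-on-soil line from a coastal Casuarina stand: air = 1.067 soil - 1.078
  tr <- noise_free_truth(slope = 1.067, intercept = -1.078)
  cl <- validate_climate(data.frame(stand_id = "X",
                                    date = as.Date("2024-01-01") + 0:9,
                                    air_temp = 25, precip = 0, rh = 80))
  mc <- simulate_soil_microclimate(cl, tr, seed = 1)
  expect_equal(mc$soil_temp, rep((25 + 1.078) / 1.067, 10))
  expect_equal(round(mc$soil_temp[1], 2), 24.44)

  # identity line, zero noise: soil equals air
  tr2 <- noise_free_truth(slope = 1, intercept = 0)
  cl2 <- simulate_daily_climate(tr2, "2023-09-01", 100L, seed = 2)
  mc2 <- simulate_soil_microclimate(cl2, tr2, seed = 3)
  expect_equal(mc2$soil_temp, cl2$air_temp)
})

test_that("noise-free moisture reproduces the stated seasonal offsets and W shape", {
  tr <- default_stand_truths()$SF
  for (f in c("air_noise_sd", "temp_noise_sd", "moist_noise_sd")) tr[[f]] <- 0
  cl <- simulate_daily_climate(tr, "2023-09-01", 366L, seed = 1)
  cl$precip <- 0  # isolate the deterministic seasonal structure
  mc <- simulate_soil_microclimate(cl, tr, seed = 1)
  wet <- assign_season(mc$date) == "wet"
  expect_equal(mean(mc$soil_moisture[wet]) - mean(mc$soil_moisture[!wet]),
               5.18, tolerance = 1e-6)
  # W shape: mid-season dips below the seasonal means
  jul <- as.integer(format(mc$date, "%m")) == 7
  jan <- as.integer(format(mc$date, "%m")) == 1
  expect_lt(min(mc$soil_moisture[jul]), mean(mc$soil_moisture[wet]))
  expect_lt(min(mc$soil_moisture[jan]), mean(mc$soil_moisture[!wet]))
})

test_that("noise-free campaign reproduces the generative law exactly", {
  # pure exponential law (c = 0)
  tr <- noise_free_truth(a = 0.331, b = 0.102, c = 0)
  cl <- validate_climate(data.frame(stand_id = "X",
                                    date = as.Date("2024-03-01") + 0:30,
                                    air_temp = 25, precip = 0, rh = 80))
  mc <- simulate_soil_microclimate(cl, tr, seed = 1)
  meas <- simulate_campaign(tr, mc, as.Date("2024-03-10"), n_collars = 5,
                            seed = 1)
  expect_equal(meas$rs, rep(0.331 * exp(0.102 * 25), 5))

  # bivariate law at a pinned microclimate
  tr2 <- noise_free_truth(a = 0.307, b = 0.066, c = 0.118)
  mc2 <- data.frame(stand_id = "X", date = as.Date("2024-03-10"),
                    soil_temp = 25, soil_moisture = 20)
  m2 <- simulate_campaign(tr2, mc2, as.Date("2024-03-10"), n_collars = 3,
                          seed = 1)
  expect_equal(m2$rs, rep(0.307 * exp(0.066 * 25) * 20^0.118, 3))

  # cardinality: 12 monthly dates x 18 collars
  cl3 <- simulate_daily_climate(tr, "2023-09-01", 366L, seed = 4)
  mc3 <- simulate_soil_microclimate(cl3, tr, seed = 5)
  m3 <- simulate_campaign(tr, mc3, monthly_schedule(), n_collars = 18, seed = 6)
  expect_equal(nrow(m3), 216L)

  # moisture power undefined at W <= 0
  mc_bad <- data.frame(stand_id = "X", date = as.Date("2024-03-10"),
                       soil_temp = 25, soil_moisture = 0)
  expect_error(simulate_campaign(tr2, mc_bad, as.Date("2024-03-10"), 3),
               class = "fs_domain_error")
})

test_that("chemistry simulation honours means, invariants and determinism", {
  tr <- default_stand_truths()$SF
  tr$chemistry$sd <- 0
  chem <- simulate_chemistry(tr, seed = 1)
  expect_equal(chem$som[chem$season == "dry"], 39.76)
  expect_equal(chem$ph[chem$season == "wet"], 5.43)

  tr2 <- default_stand_truths()$CA
  for (s in 1:20) {
    ch <- simulate_chemistry(tr2, seed = s)
    expect_true(all(ch$soc < ch$som))
    expect_true(all(ch[CHEM_VARS] > 0))
  }
  expect_identical(simulate_chemistry(tr2, seed = 3),
                   simulate_chemistry(tr2, seed = 3))
})

test_that("generate_study produces a consistent, reproducible bundle", {
  b <- small_bundle()
  expect_s3_class(b, "study_bundle")
  expect_equal(nrow(b$measurements), 4 * 12 * 18)
  expect_setequal(unique(b$measurements$stand_id), names(b$truth))
  expect_setequal(unique(b$climate$stand_id), names(b$truth))

  # same seed => identical bundle; different seed => same truth, new noise
  b2 <- generate_study(study_config(), seed = 42L)
  expect_identical(b$measurements, b2$measurements)
  b3 <- generate_study(study_config(), seed = 43L)
  expect_identical(b3$truth, b$truth)
  expect_false(identical(b3$measurements$rs, b$measurements$rs))

  # physical invariants
  expect_true(all(b$measurements$rs >= 0))
  expect_true(all(b$measurements$soil_moisture >= 0 &
                    b$measurements$soil_moisture <= 100))
  expect_true(all(b$microclimate$soil_moisture > 0 &
                    b$microclimate$soil_moisture < 100))
})

test_that("wet-season respiration exceeds dry-season in every stand, ratio bracketed", {
  # the stated world brackets the observed wet/dry ratios (1.69-2.04): the
  # per-stand expected ratio (mean across seeds) must lie in [1.5, 2.3],
  # and wet > dry must hold seed by seed (seed count scaled for runtime)
  seeds <- c(42L, 1:19)
  ratios <- vapply(seeds, function(s) {
    b <- if (s == 42L) small_bundle() else generate_study(seed = s)
    r <- wet_dry_ratio(b$measurements, "rs")
    expect_true(all(r > 1), info = paste("seed", s))
    r
  }, numeric(4L))
  avg <- rowMeans(ratios)
  expect_true(all(avg >= 1.5 & avg <= 2.3),
              info = paste(names(avg), round(avg, 3), collapse = ", "))
})

test_that("study bundles round-trip through the CSV writers", {
  dir <- withr::local_tempdir()
  b <- small_bundle()
  write_study(b, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "measurements.csv", "climate_daily.csv", "chemistry.csv", "truth.json")))))
  back <- read_measurements(file.path(dir, "measurements.csv"))
  expect_equal(nrow(back), nrow(b$measurements))
  expect_equal(back$rs, round(b$measurements$rs, 4))
})
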