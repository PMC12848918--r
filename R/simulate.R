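# Synthetic study generator.
#
# The generator is a stated world, not a tuning knob: its defaults encode
# the campaign design (4 stands x 12 monthly visits x 18 collars), the
# seasonal climate envelopes, and the bivariate respiration law as
# generative truth, so that every downstream stage can be tested against
# known parameters without any field data.

seasonal_phase <- function(dates) {
  doy <- as.integer(format(dates, "%j"))
  cos(2 * pi * (doy - 196) / 365.25)  # maximum mid-July, minimum mid-January
}

# Solve the sinusoid offset/amplitude so that dry- and wet-season means of
# the deterministic part equal the stand's envelope exactly.
air_sinusoid_coef <- function(stand, start_date) {
  ref <- seq(start_date, by = "1 day", length.out = 365L)
  s <- seasonal_phase(ref)
  wet <- assign_season(ref) == "wet"
  kw <- mean(s[wet]); kd <- mean(s[!wet])
  amp <- (stand$air_temp_wet - stand$air_temp_dry) / (kw - kd)
  c(offset = stand$air_temp_wet - amp * kw, amp = amp)
}

#' Simulate a daily climate series for one stand
#'
#' Daily air temperature is an annual sinusoid (minimum in January, maximum
#' in July) whose dry- and wet-season means equal the stand's seasonal
#' envelope exactly in the noise-free limit, plus Gaussian day-to-day noise.
#' Precipitation is an occurrence/amount (Bernoulli-gamma) process whose
#' expected monthly totals equal the stand's seasonal monthly means, and
#' relative humidity fluctuates around the seasonal envelope.
#'
#' @param stand a [stand_truth()] object.
#' @param start_date first day (ISO-8601 or `Date`).
#' @param n_days number of days (>= 1).
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return validated daily-climate data frame (stand_id, date, air_temp,
#'   precip, rh).
#' @export
simulate_daily_climate <- function(stand, start_date = "2023-09-01",
                                   n_days = 366L, seed = NULL) {
  if (!inherits(stand, "stand_truth"))
    abort_fs("`stand` must be a stand_truth object", "fs_argument_error")
  if (n_days < 1) abort_fs("n_days must be >= 1", "fs_argument_error")
  start <- parse_iso_date(start_date)
  dates <- seq(start, by = "1 day", length.out = n_days)
  coef <- air_sinusoid_coef(stand, start)
  wet <- assign_season(dates) == "wet"
  with_seed(seed, {
    air <- coef[["offset"]] + coef[["amp"]] * seasonal_phase(dates) +
      stats::rnorm(n_days, 0, stand$air_noise_sd)
    # Bernoulli-gamma rainfall; expected daily depth matches the seasonal
    # monthly mean divided by mean month length.
    p_rain <- ifelse(wet, 0.55, 0.25)
    daily_target <- ifelse(wet, stand$precip_wet, stand$precip_dry) / 30.44
    rain_day <- stats::runif(n_days) < p_rain
    depth <- stats::rgamma(n_days, shape = 0.7,
                           scale = daily_target / (p_rain * 0.7))
    precip <- ifelse(rain_day, depth, 0)
    rh <- pmin(100, pmax(0, ifelse(wet, stand$rh_wet, stand$rh_dry) +
                           stats::rnorm(n_days, 0, 1.0)))
    validate_climate(data.frame(stand_id = stand$stand_id, date = dates,
                                air_temp = air, precip = precip, rh = rh))
  })
}

#' Simulate daily soil temperature and moisture from a climate series
#'
#' Soil temperature applies the inverse of the stand's air-on-soil
#' calibration line (`soil = (air - intercept) / slope`) to the daily air
#' temperature, plus Gaussian noise. Soil moisture is a seasonal baseline
#' (dry/wet means from the truth) with two phenomenological mid-season dips
#' producing the characteristic W-shaped annual course, precipitation-driven
#' anomaly pulses, and Gaussian noise, clipped to (0, 100). The dip and
#' pulse terms are centred within each season so the noise-free seasonal
#' means equal the truth means exactly.
#'
#' @param climate validated daily-climate table for one stand.
#' @param stand the matching [stand_truth()].
#' @param seed integer seed or `NULL`.
#' @return data frame (stand_id, date, soil_temp, soil_moisture).
#' @export
simulate_soil_microclimate <- function(climate, stand, seed = NULL) {
  if (!nrow(climate)) abort_fs("climate series is empty", "fs_argument_error")
  if (stand$calib_slope == 0)
    abort_fs("degenerate calibration: slope is zero", "fs_degenerate_error")
  climate <- validate_climate(climate)
  wet <- assign_season(climate$date) == "wet"
  doy <- as.integer(format(climate$date, "%j"))
  dip <- function(center, width) {
    d <- pmin(abs(doy - center), 365.25 - abs(doy - center))
    exp(-0.5 * (d / width)^2)
  }
  base <- ifelse(wet, stand$moist_wet_mean, stand$moist_dry_mean)
  shape <- -0.12 * stand$moist_wet_mean * dip(201, 20) -
    0.12 * stand$moist_dry_mean * dip(20, 20)
  pulse <- 0.04 * climate$precip
  # centre the structured terms within each season so means are preserved
  for (m in list(wet, !wet)) if (any(m)) {
    shape[m] <- shape[m] - mean(shape[m])
    pulse[m] <- pulse[m] - mean(pulse[m])
  }
  with_seed(seed, {
    soil_temp <- (climate$air_temp - stand$calib_intercept) / stand$calib_slope +
      stats::rnorm(nrow(climate), 0, stand$temp_noise_sd)
    moist <- base + shape + pulse +
      stats::rnorm(nrow(climate), 0, stand$moist_noise_sd)
    data.frame(stand_id = stand$stand_id, date = climate$date,
               soil_temp = soil_temp,
               soil_moisture = pmin(99.9, pmax(0.1, moist)))
  })
}

#' Simulate a collar measurement campaign
#'
#' For every scheduled date and collar the true rate is the generative law
#' `a * exp(b * T) * W^c` evaluated at that day's soil microclimate, scaled
#' by a persistent mean-one lognormal collar offset; the observed rate
#' multiplies in mean-one lognormal noise with coefficient of variation
#' `rs_noise_cv`, and observed temperature/moisture receive additive
#' Gaussian measurement noise.
#'
#' @param stand a [stand_truth()].
#' @param microclimate output of [simulate_soil_microclimate()].
#' @param schedule `Date` vector of sampling dates (must lie within the
#'   microclimate series).
#' @param n_collars number of collars (>= 1).
#' @param n_plots plots the collars are split across.
#' @param seed integer seed or `NULL`.
#' @return validated measurement table.
#' @export
simulate_campaign <- function(stand, microclimate, schedule,
                              n_collars = 18L, n_plots = 3L, seed = NULL) {
  if (n_collars < 1) abort_fs("n_collars must be >= 1", "fs_argument_error")
  schedule <- parse_iso_date(schedule)
  idx <- match(schedule, microclimate$date)
  if (anyNA(idx))
    abort_fs("schedule dates missing from the microclimate series",
             "fs_argument_error")
  temp <- microclimate$soil_temp[idx]
  moist <- microclimate$soil_moisture[idx]
  if (any(moist <= 0) && stand$c_true != 0)
    abort_fs("moisture <= 0 with a non-zero moisture exponent",
             "fs_domain_error")
  n_dates <- length(schedule)
  collar <- sprintf("C%02d", seq_len(n_collars))
  plot <- sprintf("P%d", ((seq_len(n_collars) - 1L) %/%
                            ceiling(n_collars / n_plots)) + 1L)
  with_seed(seed, {
    collar_eff <- exp(stats::rnorm(n_collars, -stand$collar_sd^2 / 2,
                                   stand$collar_sd))
    grid_date <- rep(schedule, each = n_collars)
    grid_T <- rep(temp, each = n_collars)
    grid_W <- rep(moist, each = n_collars)
    grid_eff <- rep(collar_eff, times = n_dates)
    true_rs <- stand$a_true * exp(stand$b_true * grid_T) *
      grid_W^stand$c_true * grid_eff
    n <- length(true_rs)
    sdlog <- sqrt(log(1 + stand$rs_noise_cv^2))
    rs <- true_rs * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
    obs_T <- pmin(60, pmax(-10, grid_T + stats::rnorm(n, 0, stand$temp_noise_sd)))
    # floor at 0.1 vol%: probes never read exactly zero and the power-law
    # moisture term needs W > 0
    obs_W <- pmin(100, pmax(0.1, grid_W + stats::rnorm(n, 0, stand$moist_noise_sd)))
    validate_measurements(data.frame(
      stand_id = stand$stand_id,
      plot_id = rep(plot, times = n_dates),
      collar_id = rep(collar, times = n_dates),
      date = grid_date, rs = rs,
      soil_temp_10cm = obs_T, soil_moisture = obs_W))
  })
}

#' Simulate per-season soil chemistry for one stand
#'
#' Draws one dry-season and one wet-season record, each variable Normal
#' around the stand's tabulated mean with its tabulated sd, truncated to the
#' schema invariants (pH in (0,14), concentrations positive, SOC < SOM).
#'
#' @param stand a [stand_truth()] with a chemistry table.
#' @param seed integer seed or `NULL`.
#' @return validated chemistry table (two rows).
#' @export
simulate_chemistry <- function(stand, seed = NULL) {
  chem <- stand$chemistry
  if (is.null(chem))
    abort_fs("stand has no chemistry defaults", "fs_argument_error")
  with_seed(seed, {
    rows <- lapply(c("dry", "wet"), function(s) {
      sub <- chem[chem$season == s, ]
      vals <- stats::rnorm(nrow(sub), sub$mean, sub$sd)
      names(vals) <- sub$variable
      vals[["ph"]] <- min(13.99, max(0.01, vals[["ph"]]))
      for (v in setdiff(names(vals), "ph")) vals[[v]] <- max(1e-3, vals[[v]])
      if (vals[["soc"]] >= vals[["som"]]) {
        message(sprintf("%s/%s: truncated soc to keep soc < som",
                        stand$stand_id, s))
        vals[["soc"]] <- 0.97 * vals[["som"]]
      }
      cbind(data.frame(stand_id = stand$stand_id, season = s),
            as.data.frame(as.list(vals)))
    })
    validate_chemistry(do.call(rbind, rows))
  })
}

#' Generate a complete synthetic study bundle
#'
#' Composes [simulate_daily_climate()], [simulate_soil_microclimate()],
#' [simulate_campaign()] and [simulate_chemistry()] for every stand of the
#' configuration, drawing each stage from an independent sub-stream of the
#' master seed. The generative truth (and the true daily soil microclimate)
#' is stored alongside the data so recovery can be tested.
#'
#' @param config a [study_config()].
#' @param seed master integer seed.
#' @return a `study_bundle` with elements measurements, climate, chemistry,
#'   microclimate, truth, seed.
#' @export
generate_study <- function(config = study_config(), seed = 1L) {
  if (!inherits(config, "study_config"))
    abort_fs("`config` must be a study_config", "fs_argument_error")
  schedule <- campaign_schedule(config)
  parts <- lapply(seq_along(config$stands), function(i) {
    stand <- config$stands[[i]]
    climate <- simulate_daily_climate(stand, config$start_date, config$n_days,
                                      seed = derive_seed(seed, "climate", i))
    micro <- simulate_soil_microclimate(climate, stand,
                                        seed = derive_seed(seed, "micro", i))
    meas <- simulate_campaign(stand, micro, schedule,
                              n_collars = config$n_collars,
                              n_plots = config$n_plots,
                              seed = derive_seed(seed, "campaign", i))
    chem <- simulate_chemistry(stand, seed = derive_seed(seed, "chem", i))
    list(climate = climate, micro = micro, meas = meas, chem = chem)
  })
  structure(list(
    measurements = do.call(rbind, lapply(parts, `[[`, "meas")),
    climate      = do.call(rbind, lapply(parts, `[[`, "climate")),
    chemistry    = do.call(rbind, lapply(parts, `[[`, "chem")),
    microclimate = do.call(rbind, lapply(parts, `[[`, "micro")),
    truth = config$stands, config = config, seed = seed
  ), class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %d stands, %d measurements, %d climate days, seed %s\n",
              length(x$truth), nrow(x$measurements),
              nrow(x$climate), format(x$seed)))
  invisible(x)
}

#' Write a study bundle to a directory
#'
#' Writes `measurements.csv`, `climate_daily.csv`, `chemistry.csv` and
#' `truth.json` (generative parameters plus the seed).
#'
#' @param bundle a `study_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_measurements(bundle$measurements, file.path(dir, "measurements.csv"))
  write_climate(bundle$climate, file.path(dir, "climate_daily.csv"))
  write_chemistry(bundle$chemistry, file.path(dir, "chemistry.csv"))
  truth <- lapply(bundle$truth, function(s) unclass(s))
  jsonlite::write_json(list(seed = bundle$seed, truth = truth),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
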