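# Generative truth for the synthetic study.
#
# A stand_truth object carries everything the simulator needs for one
# forest stand: the bivariate respiration law Rs = a * exp(b*T) * W^c, an
# air-on-soil temperature calibration line (air = slope * soil + intercept,
# the direction in which such calibrations are conventionally printed),
# noise scales, seasonal moisture/climate envelopes and soil-chemistry
# means +/- sd for the dry and wet season.

#' Construct the generative truth for one stand
#'
#' @param stand_id short stand label, e.g. `"CA"`.
#' @param a_true,b_true,c_true parameters of the generative respiration law
#'   `Rs = a * exp(b * T) * W^c` (rate scale in umol CO2 m-2 s-1, b in 1/degC,
#'   c unitless).
#' @param calib_slope,calib_intercept air-on-soil calibration line
#'   `air = slope * soil + intercept`; the simulator inverts it to map daily
#'   air temperature to soil temperature.
#' @param rs_noise_cv coefficient of variation of the multiplicative
#'   lognormal collar observation noise (>= 0; 0 only for noise-free tests).
#' @param temp_noise_sd,moist_noise_sd additive Gaussian noise sd for soil
#'   temperature (degC) and moisture (%).
#' @param air_noise_sd day-to-day Gaussian sd of air temperature (degC).
#' @param collar_sd lognormal sd of persistent collar-to-collar offsets.
#' @param moist_dry_mean,moist_wet_mean seasonal mean volumetric soil
#'   moisture (%).
#' @param air_temp_dry,air_temp_wet seasonal mean air temperature envelope
#'   (degC); the wet value must exceed the dry value.
#' @param precip_dry,precip_wet monthly mean precipitation (mm) per season.
#' @param rh_dry,rh_wet seasonal mean relative humidity (%).
#' @param chemistry data frame with columns season, variable, mean, sd for
#'   the seven soil-chemistry variables, or `NULL` to skip chemistry.
#' @return an object of class `stand_truth`.
#' @seealso [default_stand_truths()] for the shipped four-stand defaults.
#' @export
stand_truth <- function(stand_id, a_true, b_true, c_true,
                        calib_slope, calib_intercept,
                        rs_noise_cv = 0.25,
                        temp_noise_sd = 0.3, moist_noise_sd = 1.0,
                        air_noise_sd = 1.2, collar_sd = 0.10,
                        moist_dry_mean, moist_wet_mean,
                        air_temp_dry, air_temp_wet,
                        precip_dry, precip_wet,
                        rh_dry, rh_wet,
                        chemistry = NULL) {
  for (v in c("a_true", "rs_noise_cv"))
    if (get(v) < 0 || (v == "a_true" && a_true <= 0))
      abort_fs(sprintf("`%s` must be positive", v), "fs_argument_error")
  if (calib_slope == 0)
    abort_fs("calib_slope must be non-zero", "fs_argument_error")
  if (moist_dry_mean <= 0 || moist_dry_mean >= 100 ||
      moist_wet_mean <= 0 || moist_wet_mean >= 100)
    abort_fs("moisture means must lie in (0, 100)", "fs_argument_error")
  if (air_temp_wet <= air_temp_dry)
    abort_fs("wet-season air temperature envelope must exceed the dry one",
             "fs_argument_error")
  structure(list(
    stand_id = stand_id,
    a_true = a_true, b_true = b_true, c_true = c_true,
    calib_slope = calib_slope, calib_intercept = calib_intercept,
    rs_noise_cv = rs_noise_cv, temp_noise_sd = temp_noise_sd,
    moist_noise_sd = moist_noise_sd, air_noise_sd = air_noise_sd,
    collar_sd = collar_sd,
    moist_dry_mean = moist_dry_mean, moist_wet_mean = moist_wet_mean,
    air_temp_dry = air_temp_dry, air_temp_wet = air_temp_wet,
    precip_dry = precip_dry, precip_wet = precip_wet,
    rh_dry = rh_dry, rh_wet = rh_wet,
    chemistry = chemistry
  ), class = "stand_truth")
}

#' @export
print.stand_truth <- function(x, ...) {
  cat(sprintf("<stand_truth %s> Rs = %.3f * exp(%.3f T) * W^%.3f\n",
              x$stand_id, x$a_true, x$b_true, x$c_true))
  cat(sprintf("  calibration: air = %.4f * soil + %.4f\n",
              x$calib_slope, x$calib_intercept))
  invisible(x)
}

chem_truth <- function(dry, wet) {
  data.frame(
    season   = rep(c("dry", "wet"), each = 7L),
    variable = rep(CHEM_VARS, 2L),
    mean = c(dry[, 1L], wet[, 1L]),
    sd   = c(dry[, 2L], wet[, 2L])
  )
}

#' Default four-stand generative truth
#'
#' The shipped defaults describe a four-stand tropical coastal shelter-forest
#' campaign (CA: *Casuarina* plantation, CO: coconut plantation, MF: mixed
#' plantation, SF: secondary forest). Respiration-law parameters, climate
#' envelopes and soil chemistry are the stand-level values reported for such
#' forests; the calibration lines are chosen so that the seasonal soil
#' temperature amplitudes (wet minus dry of 5.63/7.10/6.28/5.12 degC for
#' CA/CO/MF/SF) are consistent with the air-temperature envelopes, and
#' moisture means are anchored at a secondary-forest dry-season mean of
#' 22 vol% (see the methods vignette for the reasoning).
#'
#' @return named list of four [stand_truth()] objects (CA, CO, MF, SF).
#' @export
default_stand_truths <- function() {
  # air = slope * soil + intercept, slope = (wet-dry air)/(wet-dry soil),
  # line through the seasonal midpoint of both series.
  mk <- function(id, a, b, c, d_soil_dry, d_air_dry, d_air_wet, soil_amp,
                 m_dry, m_wet, p_dry, p_wet, rh_dry, rh_wet, chem) {
    slope <- (d_air_wet - d_air_dry) / soil_amp
    soil_mid <- d_soil_dry + soil_amp / 2
    air_mid <- (d_air_dry + d_air_wet) / 2
    stand_truth(id, a, b, c,
                calib_slope = slope,
                calib_intercept = air_mid - slope * soil_mid,
                moist_dry_mean = m_dry, moist_wet_mean = m_wet,
                air_temp_dry = d_air_dry, air_temp_wet = d_air_wet,
                precip_dry = p_dry, precip_wet = p_wet,
                rh_dry = rh_dry, rh_wet = rh_wet,
                chemistry = chem)
  }
  chem <- list(
    CA = chem_truth(
      dry = cbind(c(5.65, 6.60, 3.83, 0.37, 0.08, 3.98, 5.26),
                  c(0.16, 0.65, 0.38, 0.04, 0.01, 0.22, 0.04)),
      wet = cbind(c(4.19, 7.23, 4.19, 0.27, 0.10, 6.10, 1.36),
                  c(0.03, 0.22, 0.13, 0.03, 0.02, 0.26, 0.04))),
    CO = chem_truth(
      dry = cbind(c(5.32, 11.11, 6.44, 0.68, 0.51, 9.33, 67.86),
                  c(0.05, 0.70, 0.40, 0.07, 0.06, 0.39, 2.84)),
      wet = cbind(c(5.16, 9.10, 5.28, 0.49, 0.59, 4.20, 67.97),
                  c(0.04, 0.61, 0.08, 0.04, 0.07, 0.06, 2.26))),
    MF = chem_truth(
      dry = cbind(c(4.92, 9.82, 5.70, 0.47, 0.25, 4.04, 21.49),
                  c(0.04, 0.50, 0.29, 0.04, 0.03, 0.10, 1.04)),
      wet = cbind(c(4.56, 9.94, 5.77, 0.42, 0.25, 6.55, 26.62),
                  c(0.04, 0.40, 0.07, 0.02, 0.04, 0.14, 0.71))),
    SF = chem_truth(
      dry = cbind(c(5.27, 39.76, 23.06, 2.41, 0.91, 33.52, 9.80),
                  c(0.11, 1.44, 0.84, 0.08, 0.12, 0.59, 0.95)),
      wet = cbind(c(5.43, 34.20, 19.84, 1.97, 0.86, 10.98, 4.05),
                  c(0.03, 0.54, 0.31, 0.07, 0.16, 0.22, 0.08)))
  )
  list(
    CA = mk("CA", 0.132, 0.101, 0.094, d_soil_dry = 23.12,
            d_air_dry = 22.85, d_air_wet = 27.65, soil_amp = 5.63,
            m_dry = 5.59, m_wet = 7.55, p_dry = 39.65, p_wet = 244.65,
            rh_dry = 80.48, rh_wet = 82.95, chem = chem$CA),
    CO = mk("CO", 0.307, 0.066, 0.118, d_soil_dry = 23.31,
            d_air_dry = 22.90, d_air_wet = 27.28, soil_amp = 7.10,
            m_dry = 10.51, m_wet = 15.22, p_dry = 28.39, p_wet = 283.26,
            rh_dry = 79.78, rh_wet = 81.50, chem = chem$CO),
    MF = mk("MF", 0.128, 0.092, 0.199, d_soil_dry = 23.61,
            d_air_dry = 22.77, d_air_wet = 27.27, soil_amp = 6.28,
            m_dry = 6.11, m_wet = 7.04, p_dry = 35.53, p_wet = 255.08,
            rh_dry = 80.73, rh_wet = 83.43, chem = chem$MF),
    # The secondary forest's bivariate b is taken equal to its univariate
    # value 0.102 (a printed 0.01 elsewhere is a truncation artefact).
    SF = mk("SF", 0.290, 0.102, 0.052, d_soil_dry = 21.20,
            d_air_dry = 22.28, d_air_wet = 26.87, soil_amp = 5.12,
            m_dry = 22.00, m_wet = 27.18, p_dry = 28.83, p_wet = 254.56,
            rh_dry = 82.47, rh_wet = 85.32, chem = chem$SF)
  )
}

#' Default study configuration
#'
#' One study year sampled September through August (matching a campaign that
#' starts at the onset of the wet season), monthly sampling on the 10th, and
#' 18 collars per stand arranged as 3 plots of 6.
#'
#' @param stands named list of [stand_truth()] objects.
#' @param start_date first day of the simulated year (ISO-8601).
#' @param n_collars collars per stand.
#' @param n_plots plots per stand (collars are split evenly across plots).
#' @param sample_day day-of-month of the monthly campaign visit.
#' @return a `study_config` list.
#' @export
study_config <- function(stands = default_stand_truths(),
                         start_date = "2023-09-01",
                         n_collars = 18L, n_plots = 3L,
                         sample_day = 10L) {
  if (!length(stands)) abort_fs("config names no stands", "fs_argument_error")
  start <- parse_iso_date(start_date)
  end <- seq(start, by = "12 months", length.out = 2L)[2L] - 1L
  structure(list(stands = stands, start_date = start, end_date = end,
                 n_days = as.integer(end - start) + 1L,
                 n_collars = as.integer(n_collars),
                 n_plots = as.integer(n_plots),
                 sample_day = as.integer(sample_day)),
            class = "study_config")
}

# Monthly campaign dates covering the study year.
campaign_schedule <- function(config) {
  months <- seq(config$start_date, by = "1 month", length.out = 12L)
  as.Date(format(months, paste0("%Y-%m-", sprintf("%02d", config$sample_day))))
}
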