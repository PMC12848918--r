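# Fixture builders shared across test files. Everything is generated in
# code; no fixture files are read from disk.

# Minimal valid measurement table; vectors are recycled to equal length and
# collar ids made unique so the uniqueness invariant holds.
make_meas <- function(rs, temp = 25, w = 20, stand = "S1", date = NULL) {
  n <- max(length(rs), length(temp), length(w))
  data.frame(stand_id = stand, plot_id = "P1",
             collar_id = sprintf("C%03d", seq_len(n)),
             date = if (is.null(date)) rep(as.Date("2024-01-15"), n)
                    else rep_len(date, n),
             rs = rep_len(rs, n),
             soil_temp_10cm = rep_len(temp, n),
             soil_moisture = rep_len(w, n))
}

# A stand truth with every noise source switched off (and optionally a
# pinned calibration line), for exact-recovery tests.
noise_free_truth <- function(id = "X", a = 0.3, b = 0.09, c = 0.12,
                             slope = 1, intercept = 0,
                             m_dry = 10, m_wet = 15) {
  stand_truth(id, a, b, c, calib_slope = slope, calib_intercept = intercept,
              rs_noise_cv = 0, temp_noise_sd = 0, moist_noise_sd = 0,
              air_noise_sd = 0, collar_sd = 0,
              moist_dry_mean = m_dry, moist_wet_mean = m_wet,
              air_temp_dry = 22, air_temp_wet = 27,
              precip_dry = 30, precip_wet = 250,
              rh_dry = 80, rh_wet = 83)
}

monthly_schedule <- function(start = "2023-09-10", n = 12L) {
  seq(as.Date(start), by = "1 month", length.out = n)
}

# 10 environmental feature columns with the conventional names.
make_env_features <- function(n) {
  X <- as.data.frame(matrix(stats::rnorm(n * 10), n, 10))
  names(X) <- c("ph", "som", "soc", "tn", "tp", "an", "ap",
                "prcp", "temp", "rh")
  X
}

# Small default study used by several files (generated once per test run).
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_study(study_config(), seed = 42L)
    cache
  }
})
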