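# Validated CSV/JSON readers and writers for the three core tables.
#
# Schemas (fixed units, no per-file declarations):
#   measurements.csv : stand_id,plot_id,collar_id,date,rs,soil_temp_10cm,soil_moisture
#   climate_daily.csv: stand_id,date,air_temp,precip,rh
#   chemistry.csv    : stand_id,season,ph,som,soc,tn,tp,an,ap
# rs is in umol CO2 m-2 s-1, temperatures in deg C, moisture in volumetric %.

MEASUREMENT_COLS <- c("stand_id", "plot_id", "collar_id", "date",
                      "rs", "soil_temp_10cm", "soil_moisture")
CLIMATE_COLS   <- c("stand_id", "date", "air_temp", "precip", "rh")
CHEMISTRY_COLS <- c("stand_id", "season", "ph", "som", "soc", "tn", "tp", "an", "ap")
CHEM_VARS      <- c("ph", "som", "soc", "tn", "tp", "an", "ap")

check_schema <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    abort_fs(sprintf("%s table is missing column(s): %s", what,
                     paste(missing, collapse = ", ")), "fs_schema_error")
  df[cols]
}

# Drop rows with any missing core field, with a logged count (no imputation).
drop_incomplete <- function(df, what) {
  complete <- stats::complete.cases(df)
  if (any(!complete))
    message(sprintf("%s: dropped %d row(s) with missing fields",
                    what, sum(!complete)))
  df[complete, , drop = FALSE]
}

fail_rows <- function(bad, df, rule) {
  if (!any(bad)) return(invisible(NULL))
  abort_fs(sprintf("validation failed (%s) at row(s): %s", rule,
                   paste(utils::head(which(bad), 10L), collapse = ", ")),
           "fs_validation_error")
}

#' Validate a table of collar-level flux measurements
#'
#' Enforces the measurement invariants: `rs` finite and non-negative,
#' `soil_moisture` in \[0, 100\], `soil_temp_10cm` in \[-10, 60\], and
#' uniqueness of (stand_id, collar_id, date). Rows with missing core fields
#' are dropped with a logged count; invariant violations are errors naming
#' the offending rows.
#'
#' @param df a data frame with the measurement schema columns.
#' @return the validated data frame (`date` as `Date`), invisibly ordered as
#'   input.
#' @export
validate_measurements <- function(df) {
  df <- check_schema(df, MEASUREMENT_COLS, "measurements")
  df <- drop_incomplete(df, "measurements")
  df$date <- parse_iso_date(df$date)
  for (col in c("rs", "soil_temp_10cm", "soil_moisture"))
    df[[col]] <- as.numeric(df[[col]])
  fail_rows(!is.finite(df$rs) | df$rs < 0, df, "rs finite and >= 0")
  fail_rows(df$soil_moisture < 0 | df$soil_moisture > 100, df,
            "soil_moisture in [0, 100]")
  fail_rows(df$soil_temp_10cm < -10 | df$soil_temp_10cm > 60, df,
            "soil_temp_10cm in [-10, 60]")
  key <- paste(df$stand_id, df$collar_id, df$date)
  fail_rows(duplicated(key), df, "(stand_id, collar_id, date) unique")
  df
}

#' @rdname validate_measurements
#' @export
validate_climate <- function(df) {
  df <- check_schema(df, CLIMATE_COLS, "climate")
  df <- drop_incomplete(df, "climate")
  df$date <- parse_iso_date(df$date)
  for (col in c("air_temp", "precip", "rh")) df[[col]] <- as.numeric(df[[col]])
  fail_rows(df$precip < 0, df, "precip >= 0")
  fail_rows(df$rh < 0 | df$rh > 100, df, "rh in [0, 100]")
  fail_rows(duplicated(paste(df$stand_id, df$date)), df,
            "one record per stand per date")
  df
}

#' @rdname validate_measurements
#' @export
validate_chemistry <- function(df) {
  df <- check_schema(df, CHEMISTRY_COLS, "chemistry")
  df <- drop_incomplete(df, "chemistry")
  fail_rows(!df$season %in% c("dry", "wet"), df, "season in {dry, wet}")
  for (col in CHEM_VARS) df[[col]] <- as.numeric(df[[col]])
  fail_rows(df$ph <= 0 | df$ph >= 14, df, "ph in (0, 14)")
  for (col in c("som", "soc", "tn", "tp", "an", "ap"))
    fail_rows(df[[col]] <= 0, df, paste(col, "> 0"))
  fail_rows(df$soc >= df$som, df, "soc < som")
  df
}

#' Read and write the core study tables
#'
#' CSV readers validate every row against the schema invariants (see
#' [validate_measurements()]); writers emit rates to 4 decimals and
#' temperatures/moisture to 2, so a write/read round trip is lossless at the
#' declared precision. Dates are ISO-8601.
#'
#' @param path file path of a CSV with a header row.
#' @param df a validated table.
#' @return readers return the validated data frame; writers return `path`
#'   invisibly.
#' @export
read_measurements <- function(path) {
  validate_measurements(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_measurements
#' @export
read_climate <- function(path) {
  validate_climate(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_measurements
#' @export
read_chemistry <- function(path) {
  validate_chemistry(utils::read.csv(path, stringsAsFactors = FALSE))
}

round_cols <- function(df, digits) {
  for (col in names(digits)) df[[col]] <- round(df[[col]], digits[[col]])
  df
}

#' @rdname read_measurements
#' @export
write_measurements <- function(df, path) {
  df <- validate_measurements(df)
  df <- round_cols(df, c(rs = 4L, soil_temp_10cm = 2L, soil_moisture = 2L))
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_measurements
#' @export
write_climate <- function(df, path) {
  df <- validate_climate(df)
  df <- round_cols(df, c(air_temp = 2L, precip = 2L, rh = 2L))
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_measurements
#' @export
write_chemistry <- function(df, path) {
  df <- validate_chemistry(df)
  df <- round_cols(df, stats::setNames(rep(4L, length(CHEM_VARS)), CHEM_VARS))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Monthly stand-level means of a measured variable
#'
#' Aggregates collar-level records to stand x calendar-month means, the
#' granularity at which seasonal courses and air/soil temperature
#' calibrations operate. Groups with no data are absent, not zero-filled.
#'
#' @param records validated measurement table.
#' @param variable one of `"rs"`, `"soil_temp_10cm"`, `"soil_moisture"`.
#' @return data frame with columns stand_id, month (`"YYYY-MM"`), mean, sd, n.
#' @export
monthly_mean <- function(records, variable = c("rs", "soil_temp_10cm",
                                               "soil_moisture")) {
  variable <- match.arg(variable)
  records <- validate_measurements(records)
  ym <- format(records$date, "%Y-%m")
  key <- split(records[[variable]], paste(records$stand_id, ym, sep = "\t"))
  ids <- do.call(rbind, strsplit(names(key), "\t", fixed = TRUE))
  out <- data.frame(
    stand_id = ids[, 1L],
    month    = ids[, 2L],
    mean = vapply(key, mean, 0),
    sd   = vapply(key, stats::sd, 0),
    n    = vapply(key, length, 0L),
    row.names = NULL
  )
  out[order(out$stand_id, out$month), , drop = FALSE]
}
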