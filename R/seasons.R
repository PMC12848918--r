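#' Dry/wet season assignment
#'
#' The study region has a monsoon climate with a wet season from May to
#' October and a dry season from November to April. Season membership
#' depends on the calendar month only; days are never split.
#'
#' @param date a `Date` vector, or character coercible via ISO-8601
#'   (`YYYY-MM-DD`).
#' @return a character vector of `"dry"` / `"wet"`, one per input date.
#' @examples
#' assign_season(as.Date(c("2024-01-15", "2024-05-01", "2024-04-30")))
#' @export
assign_season <- function(date) {
  d <- parse_iso_date(date)
  ifelse(as.integer(format(d, "%m")) %in% 5:10, "wet", "dry")
}

#' Months belonging to a season
#'
#' @param label `"dry"` or `"wet"`.
#' @return integer vector of calendar months (1-12).
#' @export
season_months <- function(label = c("dry", "wet")) {
  label <- match.arg(label)
  if (label == "wet") 5:10 else c(11L, 12L, 1L, 2L, 3L, 4L)
}

# Strict ISO-8601 date parsing; any unparseable element is an error.
parse_iso_date <- function(x) {
  if (inherits(x, "Date")) {
    if (anyNA(x)) abort_fs("missing dates are not allowed", "fs_parse_error")
    return(x)
  }
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- is.na(d)
  if (any(bad))
    abort_fs(sprintf("unparseable ISO-8601 date(s): %s",
                     paste(utils::head(unique(x[bad]), 5L), collapse = ", ")),
             "fs_parse_error")
  d
}
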