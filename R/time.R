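#' Convert calendar dates to decimal years
#'
#' The decimal year is `year + (day_of_year - 1) / days_in_year`, the primary
#' time axis for the seasonal-trend model.
#'
#' @param date a `Date` vector.
#' @return numeric decimal years.
#' @export
decimal_year <- function(date) {
  stopifnot(inherits(date, "Date"))
  yr <- as.integer(format(date, "%Y"))
  jan1 <- as.Date(paste0(yr, "-01-01"))
  ndays <- ifelse(is_leap_year(yr), 366, 365)
  yr + as.numeric(date - jan1) / ndays
}

#' Convert decimal years to calendar dates
#'
#' Inverse of [decimal_year()] up to day resolution.
#'
#' @param t numeric decimal years.
#' @return a `Date` vector.
#' @export
decimal_year_to_date <- function(t) {
  yr <- floor(t)
  ndays <- ifelse(is_leap_year(yr), 366, 365)
  as.Date(paste0(yr, "-01-01")) + floor((t - yr) * ndays)
}

is_leap_year <- function(yr) {
  (yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0
}

#' Week-of-year for the periodic encoding
#'
#' ISO-8601 week number, clipped to 52 so that the sine/cosine encoding of
#' week-of-year sees an exact 52-week period (week 53 occurs in some years
#' and would otherwise wrap past a full turn).
#'
#' @param date a `Date` vector.
#' @return integer weeks in 1..52.
#' @export
iso_week <- function(date) {
  stopifnot(inherits(date, "Date"))
  pmin(as.integer(strftime(date, "%V")), 52L)
}
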