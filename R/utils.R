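# Internal date and misc helpers. All date arithmetic is in whole days on
# base Date objects; fixed conventions: 1 year = 365 d, 3 years = 1095 d,
# 6 months = 183 d (encoded in the config defaults, not here).

as_emr_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x, format = "%Y-%m-%d")
}

year_of <- function(d) as.integer(format(d, "%Y"))

jan1 <- function(year) as.Date(sprintf("%d-01-01", year))
dec31 <- function(year) as.Date(sprintf("%d-12-31", year))

#' Completed years of age at a given date
#'
#' @param birth_date,at `Date` vectors (recycled).
#' @return Integer vector of completed years.
#' @keywords internal
age_completed_years <- function(birth_date, at) {
  b <- as.POSIXlt(birth_date)
  a <- as.POSIXlt(at)
  age <- a$year - b$year
  not_yet <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  as.integer(age - not_yet)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
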