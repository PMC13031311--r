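#' Day-of-year index on a 365-day scale
#'
#' Maps calendar dates to an index in 1..365.  Non-leap years use the
#' ordinal day.  In leap years February 29 shares index 59 with February 28
#' and every later date uses ordinal minus one, so December 31 is always 365
#' and no day is discarded.
#'
#' @param dates a `Date` vector (or something coercible via [as.Date()]).
#' @return integer vector in 1..365.
#' @examples
#' day_of_year_index(as.Date(c("1963-01-01", "1963-03-01", "1964-02-29")))
#' @export
day_of_year_index <- function(dates) {
  dates <- as.Date(dates)
  lt <- as.POSIXlt(dates)
  doy <- lt$yday + 1L
  yr <- lt$year + 1900L
  leap <- (yr %% 4L == 0L & yr %% 100L != 0L) | yr %% 400L == 0L
  out <- ifelse(leap & doy >= 60L, doy - 1L, doy)
  as.integer(out)
}

#' Daily mean temperature from min/max
#'
#' The daily mean is the midpoint of the daily minimum and maximum.
#' Records with `tmin > tmax` are physically impossible and return `NA`
#' with a warning (callers treat them as rejected records).
#'
#' @param tmin,tmax numeric vectors, degrees Celsius.
#' @return numeric vector, degrees Celsius.
#' @examples
#' daily_mean_temperature(0, 10)     # 5
#' daily_mean_temperature(-10.4, 2.2) # -4.1
#' @export
daily_mean_temperature <- function(tmin, tmax) {
  bad <- !is.na(tmin) & !is.na(tmax) & tmin > tmax
  if (any(bad)) {
    warning(sprintf("%d record(s) with tmin > tmax rejected (set to NA)", sum(bad)))
  }
  out <- (tmin + tmax) / 2
  out[bad] <- NA_real_
  out
}

# internal: integer seed for a named pipeline stage derived from the run seed,
# kept below 2^31 so set.seed() accepts it
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 10007) %% 2147483629)
}
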