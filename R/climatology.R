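#' Station eligibility for climatology fitting
#'
#' A station is eligible when enough calendar years within the fit period
#' have substantial data: at least `min_years` years each containing at
#' least `min_days_per_year` valid daily records (valid: both temperatures
#' present and `tmin <= tmax`).
#'
#' @param records data.frame/data.table with columns `date`, `tmin`, `tmax`
#'   for one station.
#' @param period length-2 integer vector, first and last calendar year.
#' @param min_years minimum number of qualifying years (default 30).
#' @param min_days_per_year records required for a year to qualify (default 180).
#' @return logical flag.
#' @export
station_is_eligible <- function(records, period = c(1933L, 1971L),
                                min_years = 30L, min_days_per_year = 180L) {
  date <- as.Date(records$date)
  yr <- as.integer(format(date, "%Y"))
  ok <- yr >= period[1] & yr <= period[2] &
    !is.na(records$tmin) & !is.na(records$tmax) & records$tmin <= records$tmax
  if (!any(ok)) return(FALSE)
  per_year <- table(yr[ok])
  sum(per_year >= min_days_per_year) >= min_years
}

# internal: day-of-year index affinely rescaled to [-1, 1] for conditioning;
# predictions are invariant to this rescaling
.doy_scale <- function(doy) (doy - 183) / 182

.poly_basis <- function(z, degree) {
  out <- outer(z, 0:degree, `^`)
  colnames(out) <- paste0("z", 0:degree)
  out
}

#' Fit a station's long-run day-of-year climatology
#'
#' Ordinary least squares of the daily mean temperature on a degree-4
#' polynomial of the day-of-year index (rescaled to \eqn{[-1,1]} before
#' powering, for numerical conditioning).  All records in the fit period are
#' pooled, so each day-of-year is weighted by how often it was observed.
#'
#' @param records one station's records (`date`, `tmin`, `tmax`).
#' @param station_id station identifier used in messages and the result.
#' @param period first and last calendar year of the fit period.
#' @param degree polynomial degree (default 4).
#' @return an object of class `periclim_climatology`: list with
#'   `station_id`, `coefficients` (degree+1 values on the rescaled basis),
#'   `degree`, `fit_period`, `n_obs`, `residual_sd`.
#' @export
fit_station_climatology <- function(records, station_id = "station",
                                    period = c(1933L, 1971L), degree = 4L) {
  date <- as.Date(records$date)
  yr <- as.integer(format(date, "%Y"))
  keep <- yr >= period[1] & yr <= period[2]
  tmean <- suppressWarnings(daily_mean_temperature(records$tmin[keep], records$tmax[keep]))
  date <- date[keep]
  use <- !is.na(tmean)
  tmean <- tmean[use]
  date <- date[use]
  doy <- day_of_year_index(date)
  if (length(unique(doy)) < degree + 1L) {
    stop(sprintf("station %s: only %d distinct day-of-year values, cannot fit degree-%d climatology",
                 station_id, length(unique(doy)), degree))
  }
  X <- .poly_basis(.doy_scale(doy), degree)
  fit <- lm.fit(X, tmean)
  if (any(is.na(fit$coefficients))) {
    stop(sprintf("station %s: rank-deficient climatology design", station_id))
  }
  res <- fit$residuals
  structure(list(
    station_id = station_id,
    coefficients = unname(fit$coefficients),
    degree = as.integer(degree),
    fit_period = as.integer(period),
    n_obs = length(tmean),
    residual_sd = if (length(res) > degree + 1) sqrt(sum(res^2) / (length(res) - degree - 1L)) else 0
  ), class = "periclim_climatology")
}

#' Expected temperature from a fitted climatology
#'
#' Evaluates the fitted day-of-year polynomial at the dates' 365-day index.
#'
#' @param model a `periclim_climatology` object.
#' @param dates `Date` vector.
#' @return expected daily mean temperature, degrees Celsius.
#' @export
expected_temperature <- function(model, dates) {
  stopifnot(inherits(model, "periclim_climatology"))
  doy <- day_of_year_index(dates)
  expected_at_doy(model, doy)
}

#' @rdname expected_temperature
#' @param doy integer day-of-year index in 1..365.
#' @export
expected_at_doy <- function(model, doy) {
  drop(.poly_basis(.doy_scale(doy), model$degree) %*% model$coefficients)
}

#' @export
print.periclim_climatology <- function(x, ...) {
  cat(sprintf("Climatology for station %s: degree-%d polynomial, %d obs (%d-%d), residual SD %.2f degC\n",
              x$station_id, x$degree, x$n_obs, x$fit_period[1], x$fit_period[2], x$residual_sd))
  invisible(x)
}

#' Fit climatologies for every eligible station
#'
#' @param records all stations' records (`station_id`, `date`, `tmin`, `tmax`).
#' @param period fit period (first, last year).
#' @param min_years,min_days_per_year eligibility rule, see
#'   [station_is_eligible()].
#' @param degree polynomial degree.
#' @return named list of `periclim_climatology` objects, one per eligible
#'   station; ineligible stations are reported via `message()` and omitted.
#' @export
fit_climatologies <- function(records, period = c(1933L, 1971L), degree = 4L,
                              min_years = 30L, min_days_per_year = 180L) {
  records <- data.table::as.data.table(records)
  ids <- sort(unique(records$station_id))
  out <- list()
  dropped <- character(0)
  for (id in ids) {
    rec <- records[records$station_id == id]
    if (station_is_eligible(rec, period, min_years, min_days_per_year)) {
      out[[as.character(id)]] <- fit_station_climatology(rec, id, period, degree)
    } else {
      dropped <- c(dropped, as.character(id))
    }
  }
  if (length(dropped)) {
    message(sprintf("%d station(s) ineligible (<%d years with >=%d records): %s",
                    length(dropped), min_years, min_days_per_year,
                    paste(utils::head(dropped, 5), collapse = ", ")))
  }
  if (!length(out)) stop("no eligible stations")
  out
}

#' Daily temperature deviations (anomalies) for one station
#'
#' Deviation = observed daily mean minus the climatology expectation for
#' that day-of-year.  Records with `tmin > tmax` are rejected (absent from
#' the output).
#'
#' @param records one station's records.
#' @param model the station's fitted `periclim_climatology`.
#' @return data.table with `station_id`, `date`, `deviation` (degC).
#' @export
compute_deviations <- function(records, model) {
  stopifnot(inherits(model, "periclim_climatology"))
  date <- as.Date(records$date)
  tmean <- suppressWarnings(daily_mean_temperature(records$tmin, records$tmax))
  use <- !is.na(tmean)
  data.table::data.table(
    station_id = model$station_id,
    date = date[use],
    deviation = tmean[use] - expected_temperature(model, date[use])
  )
}

#' Deviations for a whole station network
#'
#' @param records all stations' records.
#' @param models named list of climatologies from [fit_climatologies()].
#' @return data.table `station_id`, `date`, `deviation`, covering stations
#'   present in `models` only.
#' @export
compute_all_deviations <- function(records, models) {
  records <- data.table::as.data.table(records)
  out <- lapply(models, function(m) {
    compute_deviations(records[records$station_id == m$station_id], m)
  })
  data.table::rbindlist(out)
}
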