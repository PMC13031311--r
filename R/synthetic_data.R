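#' Simulation configuration
#'
#' Defines the synthetic world: a station network over a UK-sized
#' latitude/longitude box with a latitudinal gradient, a shared seasonal
#' harmonic, a shared regional AR(1) daily anomaly plus independent station
#' noise, and a cohort whose continuous outcomes carry a known linear
#' effect of the regional anomaly on the true conception day, together with
#' area effects, a seasonal conception-timing (month-of-conception) effect,
#' sex and birth-year terms, and gestation-length noise in the estimated
#' conception date.
#'
#' @param n_stations number of stations placed uniformly in the box.
#' @param bbox named numeric `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param n_participants cohort size.
#' @param n_areas number of administrative areas (grid partition of the box).
#' @param year_range first and last calendar year of station records.
#' @param true_alpha named per-outcome effect, outcome units per degC of
#'   true conception-day anomaly.
#' @param seasonal_amp amplitude (degC) of the day-of-year harmonic.
#' @param seasonal_peak_doy day-of-year of the warm peak (mid-July).
#' @param base_temp mean temperature (degC) at the box's central latitude.
#' @param lat_gradient degC per degree latitude (negative: north is colder).
#' @param weather_sd stationary SD (degC) of the shared regional daily anomaly.
#' @param weather_ar1 lag-1 autocorrelation of the regional anomaly, in \[0,1).
#' @param station_noise_sd SD (degC) of independent per-station daily noise.
#' @param diurnal_range tmax - tmin (degC); records are mean -/+ half-range.
#' @param gestation_mean mean gestation length in days (266).
#' @param gestation_sd SD of gestation length in days (0 = estimated DOC is exact).
#' @param fertility_season_strength dimensionless knob scaling both the
#'   seasonality of conception timing and the seasonal month-of-conception
#'   effect on outcomes (0 = no confounding channel).
#' @param outcome_noise_sd named per-outcome residual SD.
#' @param outcome_intercept named per-outcome intercept.
#' @param seed integer run seed; stages derive their own substreams from it.
#' @return a `periclim_simconfig` list.
#' @export
sim_config <- function(n_stations = 25L,
                       bbox = c(lat_min = 50, lat_max = 58.5, lon_min = -6, lon_max = 1.8),
                       n_participants = 20000L,
                       n_areas = 24L,
                       year_range = c(1933L, 1971L),
                       true_alpha = c(bmi = 0.15, wc = 0.45, hba1c = 0.20, tg = 0.033, chol = 0.040),
                       seasonal_amp = 7,
                       seasonal_peak_doy = 197L,
                       base_temp = 9,
                       lat_gradient = -0.6,
                       weather_sd = 2,
                       weather_ar1 = 0.7,
                       station_noise_sd = 0.5,
                       diurnal_range = 7,
                       gestation_mean = 266L,
                       gestation_sd = 9,
                       fertility_season_strength = 0.5,
                       outcome_noise_sd = c(bmi = 4.5, wc = 12.5, hba1c = 6.0, tg = 0.95, chol = 1.05),
                       outcome_intercept = c(bmi = 26.5, wc = 88, hba1c = 35.5, tg = 1.7, chol = 5.65),
                       seed = 1L) {
  stopifnot(n_stations >= 1, n_participants >= 1, n_areas >= 2,
            bbox["lat_max"] > bbox["lat_min"], bbox["lon_max"] > bbox["lon_min"],
            weather_ar1 >= 0, weather_ar1 < 1,
            weather_sd >= 0, station_noise_sd >= 0, gestation_sd >= 0,
            all(outcome_noise_sd >= 0), year_range[2] >= year_range[1])
  outcomes <- names(true_alpha)
  stopifnot(!is.null(outcomes), identical(outcomes, names(outcome_noise_sd)),
            identical(outcomes, names(outcome_intercept)))
  structure(as.list(environment()), class = "periclim_simconfig")
}

#' Simulate a weather-station network
#'
#' Daily mean temperature at station s on day t is
#' `base + lat_gradient*(lat_s - lat_mid) + seasonal_amp*cos(2*pi*(doy-peak)/365)
#'  + a_t + eta_st`, where `a_t` is a shared regional AR(1) anomaly with
#' stationary SD `weather_sd` and lag-1 autocorrelation `weather_ar1`, and
#' `eta_st` is independent station noise.  Records are emitted as
#' `(tmin, tmax) = mean -/+ diurnal_range/2`.
#'
#' @param config a [sim_config()].
#' @return a `periclim_station_sim` list: `stations` (metadata),
#'   `records` (`station_id`, `date`, `tmin`, `tmax`),
#'   `regional_anomaly` (`date`, `anomaly` - the true shared anomaly path),
#'   and the `config`.
#' @export
simulate_station_network <- function(config) {
  stopifnot(inherits(config, "periclim_simconfig"))
  set.seed(stage_seed(config$seed, "stations"))
  bb <- config$bbox
  S <- as.integer(config$n_stations)
  stations <- data.table::data.table(
    station_id = sprintf("ST%03d", seq_len(S)),
    lat = runif(S, bb["lat_min"], bb["lat_max"]),
    lon = runif(S, bb["lon_min"], bb["lon_max"])
  )
  dates <- seq(as.Date(sprintf("%d-01-01", config$year_range[1])),
               as.Date(sprintf("%d-12-31", config$year_range[2])), by = "day")
  Tn <- length(dates)
  doy <- day_of_year_index(dates)
  phi <- config$weather_ar1
  innov_sd <- config$weather_sd * sqrt(1 - phi^2)
  a <- numeric(Tn)
  if (config$weather_sd > 0) {
    a <- as.numeric(stats::filter(rnorm(Tn, 0, innov_sd), phi, method = "recursive",
                                  init = rnorm(1, 0, config$weather_sd)))
  }
  seasonal <- config$seasonal_amp * cos(2 * pi * (doy - config$seasonal_peak_doy) / 365)
  lat_mid <- mean(bb[c("lat_min", "lat_max")])
  recs <- vector("list", S)
  for (s in seq_len(S)) {
    mu <- config$base_temp + config$lat_gradient * (stations$lat[s] - lat_mid) +
      seasonal + a +
      if (config$station_noise_sd > 0) rnorm(Tn, 0, config$station_noise_sd) else 0
    recs[[s]] <- data.table::data.table(
      station_id = stations$station_id[s], date = dates,
      tmin = mu - config$diurnal_range / 2, tmax = mu + config$diurnal_range / 2
    )
  }
  structure(list(
    stations = stations,
    records = data.table::rbindlist(recs),
    regional_anomaly = data.table::data.table(date = dates, anomaly = a),
    config = config
  ), class = "periclim_station_sim")
}

# internal: factor n_areas into the grid (rows x cols) closest to square
.area_grid <- function(n_areas) {
  divs <- which(n_areas %% seq_len(n_areas) == 0)
  r <- divs[which.min(abs(divs - sqrt(n_areas)))]
  c(rows = max(r, n_areas %/% r), cols = min(r, n_areas %/% r))
}

#' Simulate a cohort with known ground truth
#'
#' Participants are assigned an administrative area (grid cell of the box),
#' a birthplace uniform within the area, sex, and an assessment year.  The
#' true conception date is drawn from an area-specific seasonal fertility
#' distribution (von-Mises-style day-of-year weighting whose concentration
#' scales with `fertility_season_strength`); gestation length is
#' `Normal(gestation_mean, gestation_sd)` rounded to whole days and
#' truncated at 6 SD, and the birth date is conception plus gestation.
#' Each continuous outcome is intercept + area effect + seasonal
#' month-of-conception effect + sex effect + birth-year trend +
#' `true_alpha * (regional anomaly on the true conception day)` + noise.
#'
#' The ground truth records the true conception dates and true
#' conception-day anomalies; it is never consumed by the inference stage.
#'
#' @param config a [sim_config()].
#' @param network a `periclim_station_sim` from [simulate_station_network()].
#' @return list with `cohort` (data.table) and `truth` (list with
#'   `true_alpha`, per-participant `true_doc` and `true_anomaly`, and the
#'   per-area fertility parameters).
#' @export
simulate_cohort <- function(config, network) {
  stopifnot(inherits(config, "periclim_simconfig"),
            inherits(network, "periclim_station_sim"))
  set.seed(stage_seed(config$seed, "cohort"))
  bb <- config$bbox
  P <- as.integer(config$n_participants)
  K <- as.integer(config$n_areas)
  grid <- .area_grid(K)
  lat_br <- seq(bb["lat_min"], bb["lat_max"], length.out = grid["rows"] + 1L)
  lon_br <- seq(bb["lon_min"], bb["lon_max"], length.out = grid["cols"] + 1L)

  area <- sample.int(K, P, replace = TRUE)
  arow <- (area - 1L) %/% grid["cols"] + 1L
  acol <- (area - 1L) %% grid["cols"] + 1L
  lat <- runif(P, lat_br[arow], lat_br[arow + 1L])
  lon <- runif(P, lon_br[acol], lon_br[acol + 1L])
  sex <- sample(c("female", "male"), P, replace = TRUE)
  assess_year <- sample(2006:2010, P, replace = TRUE)

  anom <- network$regional_anomaly
  day_min <- min(as.integer(anom$date)); day_max <- max(as.integer(anom$date))
  gest_slack <- ceiling(6 * config$gestation_sd)
  # keep every estimated-DOC window (est. DOC = true DOC +/- gest_slack) in-range
  c_lo <- day_min + 35L + gest_slack
  c_hi <- day_max - 20L - gest_slack
  days <- c_lo:c_hi
  doy_days <- day_of_year_index(as.Date(days, origin = "1970-01-01"))

  fss <- config$fertility_season_strength
  peak_a <- round(355 + rnorm(K, 0, 20)) %% 365          # conception peaks near winter
  kappa_a <- 0.5 * fss * runif(K, 0.5, 1.5)              # area-scaled concentration
  true_doc <- integer(P)
  for (k in seq_len(K)) {
    idx <- which(area == k)
    if (!length(idx)) next
    w <- exp(kappa_a[k] * cos(2 * pi * (doy_days - peak_a[k]) / 365))
    true_doc[idx] <- sample(days, length(idx), replace = TRUE, prob = w)
  }
  gest <- round(rnorm(P, config$gestation_mean, config$gestation_sd))
  gest <- pmin(pmax(gest, config$gestation_mean - gest_slack),
               config$gestation_mean + gest_slack)
  birth_date <- as.Date(true_doc + gest, origin = "1970-01-01")

  true_anomaly <- anom$anomaly[true_doc - day_min + 1L]
  doy_doc <- day_of_year_index(as.Date(true_doc, origin = "1970-01-01"))
  season_conc <- cos(2 * pi * (doy_doc - config$seasonal_peak_doy) / 365)
  birth_year <- as.integer(format(birth_date, "%Y"))

  outcomes <- names(config$true_alpha)
  cohort <- data.table::data.table(
    participant_id = sprintf("P%06d", seq_len(P)),
    birth_date = birth_date, lat = lat, lon = lon,
    area_id = sprintf("A%02d", area), sex = sex, assess_year = assess_year
  )
  area_fx <- list()
  for (o in outcomes) {
    sdo <- config$outcome_noise_sd[[o]]
    area_fx[[o]] <- rnorm(K, 0, 0.3 * sdo)
    y <- config$outcome_intercept[[o]] +
      area_fx[[o]][area] +
      fss * sdo * season_conc +
      0.5 * sdo * (sex == "male") +
      0.01 * sdo * (birth_year - mean(config$year_range)) +
      config$true_alpha[[o]] * true_anomaly +
      rnorm(P, 0, sdo)
    cohort[[o]] <- y
  }
  truth <- list(
    true_alpha = config$true_alpha,
    participant_id = cohort$participant_id,
    true_doc = as.Date(true_doc, origin = "1970-01-01"),
    true_anomaly = true_anomaly,
    fertility = data.table::data.table(area_id = sprintf("A%02d", seq_len(K)),
                                       peak_doy = peak_a, kappa = kappa_a),
    area_effects = area_fx
  )
  list(cohort = cohort, truth = truth)
}

#' Simulate a complete synthetic world
#'
#' Convenience wrapper: station network plus cohort from one configuration.
#'
#' @param config a [sim_config()].
#' @return list `network`, `cohort`, `truth`.
#' @export
simulate_world <- function(config = sim_config()) {
  network <- simulate_station_network(config)
  cw <- simulate_cohort(config, network)
  list(network = network, cohort = cw$cohort, truth = cw$truth)
}
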