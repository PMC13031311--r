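# Small simulated worlds shared across test files.

tiny_config <- function(...) {
  defaults <- list(n_stations = 10L, n_participants = 300L, n_areas = 6L,
                   year_range = c(1933L, 1947L), seed = 11L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# stations + climatology + deviations for a small world (cached per session)
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_config(gestation_sd = 0)
      w <- simulate_world(cfg)
      models <- fit_climatologies(w$network$records, period = cfg$year_range,
                                  min_years = 12L)
      deviations <- compute_all_deviations(w$network$records, models)
      cache <<- list(config = cfg, world = w, models = models,
                     deviations = deviations)
    }
    cache
  }
})

# one noiseless station: pure harmonic + latitude offset, no weather
harmonic_station <- function(amp = 7, years = c(1940L, 1949L), lat = 52, lon = -1) {
  dates <- seq(as.Date(sprintf("%d-01-01", years[1])),
               as.Date(sprintf("%d-12-31", years[2])), by = "day")
  doy <- day_of_year_index(dates)
  mu <- 9 + amp * cos(2 * pi * (doy - 197) / 365)
  data.table::data.table(station_id = "H001", date = dates,
                         tmin = mu - 3, tmax = mu + 3)
}
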