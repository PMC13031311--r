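#' Read a station record table
#'
#' Delimited text with header `station_id,lat,lon,date,tmin,tmax`
#' (ISO-8601 dates, decimal degC).  Malformed rows (unparseable date or
#' temperature, invalid coordinates, `tmin > tmax`) are skipped and
#' counted; a later duplicate of a (station, date) pair is rejected.
#' Counts are attached as attribute `log` and reported via `message()`.
#'
#' @param path file path.
#' @return a `periclim_stations` list: `stations` (metadata: `station_id`,
#'   `lat`, `lon`) and `records` (`station_id`, `date`, `tmin`, `tmax`).
#' @export
read_station_table <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "station_id"))
  required <- c("station_id", "lat", "lon", "date", "tmin", "tmax")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop(sprintf("station table %s is missing column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  }
  n0 <- nrow(dt)
  dt$date <- as.Date(as.character(dt$date), format = "%Y-%m-%d")
  dt$tmin <- suppressWarnings(as.numeric(dt$tmin))
  dt$tmax <- suppressWarnings(as.numeric(dt$tmax))
  malformed <- is.na(dt$date) | is.na(dt$tmin) | is.na(dt$tmax) |
    is.na(dt$lat) | is.na(dt$lon) | abs(dt$lat) > 90 | abs(dt$lon) > 180
  inverted <- !malformed & dt$tmin > dt$tmax
  dt <- dt[!(malformed | inverted)]
  dup <- duplicated(dt[, c("station_id", "date")])
  dt <- dt[!dup]
  log <- c(n_rows = n0, n_malformed = sum(malformed),
           n_tmin_gt_tmax = sum(inverted), n_duplicate = sum(dup),
           n_kept = nrow(dt))
  if (log[["n_malformed"]] + log[["n_tmin_gt_tmax"]] + log[["n_duplicate"]] > 0) {
    message(sprintf("read_station_table: skipped %d malformed, %d tmin>tmax, %d duplicate row(s)",
                    log[["n_malformed"]], log[["n_tmin_gt_tmax"]], log[["n_duplicate"]]))
  }
  stations <- unique(dt[, c("station_id", "lat", "lon")])
  structure(list(stations = stations,
                 records = dt[, c("station_id", "date", "tmin", "tmax")],
                 log = log),
            class = "periclim_stations")
}

#' Write station records to delimited text
#'
#' @param network a `periclim_station_sim` or `periclim_stations` object.
#' @param path output path.
#' @export
write_station_table <- function(network, path) {
  recs <- data.table::as.data.table(network$records)
  meta <- data.table::as.data.table(network$stations)
  out <- merge(recs, meta, by = "station_id", sort = FALSE)
  data.table::setcolorder(out, c("station_id", "lat", "lon", "date", "tmin", "tmax"))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Exclusion accounting
#'
#' Retained sample size after removing the flagged exclusion groups;
#' asserts `retained = initial - sum(counts)`.
#'
#' @param initial initial row count.
#' @param exclusions named integer vector of exclusion counts.
#' @return retained count (integer).
#' @examples
#' sample_accounting(452149, c(unmappable = 7543, adopted = 7102))  # 437504
#' @export
sample_accounting <- function(initial, exclusions) {
  retained <- initial - sum(exclusions)
  stopifnot(retained >= 0)
  as.integer(retained)
}

#' Read a cohort table
#'
#' Delimited text with header containing `participant_id,birth_date,lat,
#' lon,area_id,sex,assess_year` plus outcome columns.  Optional 0/1 flag
#' columns `unmappable` and `adopted` mark rows to exclude (unmappable
#' birthplace; adopted participants); flagged rows are removed and the
#' accounting (`initial`, per-flag counts, `retained`) is attached as
#' attribute `accounting`.
#'
#' @param path file path.
#' @return data.table cohort.
#' @export
read_cohort_table <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = c("participant_id")))
  required <- c("participant_id", "birth_date", "lat", "lon", "area_id", "sex", "assess_year")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop(sprintf("cohort table %s is missing column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  }
  dt$birth_date <- as.Date(as.character(dt$birth_date), format = "%Y-%m-%d")
  bad_date <- is.na(dt$birth_date)
  if (any(bad_date)) {
    message(sprintf("read_cohort_table: %d row(s) with unparseable birth_date removed", sum(bad_date)))
    dt <- dt[!bad_date]
  }
  initial <- nrow(dt)
  counts <- c()
  for (flag in c("unmappable", "adopted")) {
    if (flag %in% names(dt)) {
      f <- dt[[flag]] %in% c(1, TRUE, "1", "TRUE")
      counts[flag] <- sum(f)
      dt <- dt[!f]
      dt[[flag]] <- NULL
    }
  }
  retained <- nrow(dt)
  if (length(counts)) {
    stopifnot(retained == sample_accounting(initial, counts))
    if (retained == 0) warning("all cohort rows excluded by flags")
  }
  data.table::setattr(dt, "accounting",
                      list(initial = initial, exclusions = counts, retained = retained))
  dt
}

#' Write a cohort table
#' @param cohort cohort data.frame.
#' @param path output path.
#' @export
write_cohort_table <- function(cohort, path) {
  data.table::fwrite(data.table::as.data.table(cohort), path)
  invisible(path)
}

#' Run the full pipeline on station and cohort inputs
#'
#' Climatology fitting, deviation computation, spatial linkage, exposure
#' construction, the regression suite, and scenario translation, writing
#' the results table, a run manifest (configuration + seed) and a short
#' human-readable report under `outdir`.  Deterministic given the seed.
#'
#' @param stations a `periclim_stations`/`periclim_station_sim` object or a
#'   path readable by [read_station_table()].
#' @param cohort a cohort data.frame or a path readable by
#'   [read_cohort_table()].
#' @param outdir output directory (created if absent).
#' @param linkage a [linkage_config()].
#' @param windows exposure windows to fit.
#' @param fit_period climatology fit period (years).
#' @param min_years,min_days_per_year station eligibility rule.
#' @param strata,binary,negative_controls,alt_fe passed to
#'   [run_analysis_suite()].
#' @param outcome_sds named SDs for the scenario table (default: sample SDs
#'   of the cohort outcomes).
#' @param seed run seed.
#' @return invisibly, a list with `results`, `exposure`, `scenarios`,
#'   `manifest`.
#' @export
run_pipeline <- function(stations, cohort, outdir,
                         linkage = linkage_config(),
                         windows = names(exposure_windows()),
                         fit_period = c(1933L, 1971L),
                         min_years = 30L, min_days_per_year = 180L,
                         strata = character(0), binary = TRUE,
                         negative_controls = FALSE, alt_fe = FALSE,
                         outcome_sds = NULL, seed = 1L) {
  if (is.character(stations)) stations <- read_station_table(stations)
  if (is.character(cohort)) cohort <- read_cohort_table(cohort)
  cohort <- data.table::as.data.table(cohort)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  models <- fit_climatologies(stations$records, period = fit_period,
                              min_years = min_years,
                              min_days_per_year = min_days_per_year)
  deviations <- compute_all_deviations(stations$records, models)
  expo <- build_exposure_table(cohort, stations$stations, deviations,
                               windows = windows, config = linkage)
  results <- run_analysis_suite(cohort, expo, windows = windows,
                                strata = strata, binary = binary,
                                negative_controls = negative_controls,
                                alt_fe = alt_fe, seed = seed)
  outcomes <- intersect(c("bmi", "wc", "hba1c", "tg", "chol"), names(cohort))
  if (is.null(outcome_sds)) {
    outcome_sds <- vapply(outcomes, function(o) sd(cohort[[o]], na.rm = TRUE), numeric(1))
  }
  scen <- scenario_table(results[results$stratum == "all" & results$family == "linear", ],
                         outcome_sds)

  data.table::fwrite(expo, file.path(outdir, "exposure.csv"))
  data.table::fwrite(results, file.path(outdir, "results.csv"))
  data.table::fwrite(scen, file.path(outdir, "scenarios.csv"))
  manifest <- list(
    seed = seed, linkage = unclass(linkage), windows = windows,
    fit_period = fit_period, min_years = min_years,
    min_days_per_year = min_days_per_year,
    n_stations = nrow(stations$stations), n_participants = nrow(cohort),
    n_unlinked = attr(expo, "n_unlinked"),
    outcome_sds = as.list(outcome_sds),
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report <- c(
    sprintf("periclim pipeline run (seed %d)", seed),
    sprintf("stations: %d (eligible: %d); participants: %d (unlinked: %d)",
            nrow(stations$stations), length(models), nrow(cohort),
            attr(expo, "n_unlinked")),
    sprintf("windows: %s; linkage: %s, radius %.0f km, power %.1f",
            paste(windows, collapse = ", "), linkage$mode,
            linkage$radius_km, linkage$idw_power),
    sprintf("models fitted: %d (%d failed)", nrow(results), sum(!is.na(results$error)))
  )
  writeLines(report, file.path(outdir, "report.txt"))
  invisible(list(results = results, exposure = expo, scenarios = scen,
                 manifest = manifest))
}
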