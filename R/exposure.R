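#' Periconceptional exposure windows
#'
#' Day offsets relative to the estimated date of conception (day 0).
#' "Till DOC" is read as up to but not including the conception day, so the
#' two-week window has 14 days and the widest window 56, reproducing the
#' 2-of-8-weeks dilution arithmetic (+1 degC over 14 of 56 days averages to
#' +0.25 degC).
#'
#' @return named list of integer offset vectors: `DOC` (day 0 only),
#'   `-2w;DOC` (-14..-1), `-3w;+1w` (-21..6), `-4w;+2w` (-28..13),
#'   `-5w;+3w` (-35..20).
#' @export
exposure_windows <- function() {
  list(
    "DOC"      = 0L,
    "-2w;DOC"  = -14L:-1L,
    "-3w;+1w"  = -21L:6L,
    "-4w;+2w"  = -28L:13L,
    "-5w;+3w"  = -35L:20L
  )
}

#' Estimated date of conception
#'
#' Birth date minus 266 days, the average human gestation length.
#'
#' @param birth_date `Date` vector.
#' @return `Date` vector.
#' @examples
#' estimate_doc(as.Date("1963-10-08"))  # 1963-01-15
#' @export
estimate_doc <- function(birth_date) {
  as.Date(birth_date) - 266L
}

#' Dates covered by a window around an estimated conception date
#'
#' @param window a window label from [exposure_windows()].
#' @param doc estimated conception `Date` (scalar).
#' @return contiguous `Date` vector.
#' @export
window_dates <- function(window, doc) {
  offs <- exposure_windows()[[window]]
  if (is.null(offs)) stop(sprintf("unknown exposure window '%s'", window))
  as.Date(doc) + offs
}

#' Mean anomaly over one periconceptional window
#'
#' Unweighted mean of the interpolated daily anomaly over the window's
#' dates, skipping days on which no in-radius station reports.  The
#' exposure is reported only when coverage (reported days / window length)
#' reaches `config$min_coverage`.
#'
#' @param loc `c(lat, lon)` birthplace.
#' @param doc estimated conception date.
#' @param window window label.
#' @param deviations station deviation table.
#' @param stations station metadata.
#' @param config a [linkage_config()].
#' @return list with `exposure` (degC or `NA`) and `coverage` in \[0,1\].
#' @export
mean_window_anomaly <- function(loc, doc, window, deviations, stations,
                                config = linkage_config()) {
  dates <- window_dates(window, doc)
  vals <- vapply(dates, function(d) {
    interpolate_daily_anomaly(loc, d, deviations, stations, config)
  }, numeric(1))
  coverage <- mean(!is.na(vals))
  exposure <- if (coverage >= config$min_coverage) mean(vals, na.rm = TRUE) else NA_real_
  list(exposure = exposure, coverage = coverage)
}

# internal: deviations long table -> list(mat [stations x days], avail,
# station_ids, day0) with columns indexed by integer day since day0
.deviation_matrix <- function(deviations, station_ids) {
  station_ids <- sort(station_ids)
  day <- as.integer(deviations$date)
  day0 <- min(day)
  Tn <- max(day) - day0 + 1L
  S <- length(station_ids)
  mat <- matrix(NA_real_, S, Tn)
  row <- match(deviations$station_id, station_ids)
  keep <- !is.na(row)
  mat[cbind(row[keep], day[keep] - day0 + 1L)] <- deviations$deviation[keep]
  list(mat = mat, avail = !is.na(mat), station_ids = station_ids, day0 = day0, n_days = Tn)
}

#' Exposure table for a cohort
#'
#' One row per participant and window with the mean interpolated anomaly
#' and its coverage.  Interpolation is per-day IDW (or nearest) with
#' weights renormalized over the stations reporting that day; for
#' participants whose in-radius stations report every window day the
#' per-day scheme collapses to a weighted sum of station window means,
#' which is used as a fast path.  Participants with no in-radius station
#' keep their rows with all-missing exposures; their count is attached as
#' attribute `n_unlinked`.
#'
#' @param cohort data.frame with `participant_id`, `birth_date`, `lat`, `lon`.
#' @param stations station metadata (`station_id`, `lat`, `lon`).
#' @param deviations deviation table from [compute_all_deviations()].
#' @param windows window labels (default: all five).
#' @param config a [linkage_config()].
#' @return data.table `participant_id`, `window`, `exposure`, `coverage`.
#' @export
build_exposure_table <- function(cohort, stations, deviations,
                                 windows = names(exposure_windows()),
                                 config = linkage_config()) {
  cohort <- data.table::as.data.table(cohort)
  stations <- data.table::as.data.table(stations)
  stations <- stations[order(stations$station_id)]
  dm <- .deviation_matrix(deviations, stations$station_id)
  S <- nrow(stations); P <- nrow(cohort)

  D <- matrix(0, P, S)  # participant x station distances
  for (s in seq_len(S)) {
    D[, s] <- geodesic_distance_km(cohort$lat, cohort$lon,
                                   stations$lat[s], stations$lon[s])
  }
  in_radius <- D <= config$radius_km
  if (config$mode == "idw") {
    W <- (1 / pmax(D, 1e-6)^config$idw_power) * in_radius
  } else {
    W <- matrix(0, P, S)
    has <- rowSums(in_radius) > 0
    Dm <- D; Dm[!in_radius] <- Inf
    nn <- max.col(-Dm[has, , drop = FALSE], ties.method = "first")  # smallest id on ties
    W[cbind(which(has), nn)] <- 1
  }
  unlinked <- rowSums(W) == 0

  doc_day <- as.integer(estimate_doc(cohort$birth_date))
  Dz <- dm$mat; Dz[!dm$avail] <- 0
  csum <- cbind(0, t(apply(Dz, 1, cumsum)))          # S x (T+1)
  acum <- cbind(0, t(apply(dm$avail, 1, cumsum)))    # S x (T+1)

  all_offs <- exposure_windows()
  out <- vector("list", length(windows))
  for (wi in seq_along(windows)) {
    offs <- all_offs[[windows[wi]]]
    if (is.null(offs)) stop(sprintf("unknown exposure window '%s'", windows[wi]))
    L <- length(offs)
    b <- doc_day + min(offs) - dm$day0 + 1L   # first column index
    e <- doc_day + max(offs) - dm$day0 + 1L   # last column index
    inside <- b >= 1L & e <= dm$n_days
    exposure <- rep(NA_real_, P)
    coverage <- rep(0, P)

    # station window sums / counts for rows with the window inside the span
    idx <- which(inside & !unlinked)
    if (length(idx)) {
      sumM <- matrix(0, length(idx), S); cntM <- matrix(0L, length(idx), S)
      for (s in seq_len(S)) {
        sumM[, s] <- csum[s, e[idx] + 1L] - csum[s, b[idx]]
        cntM[, s] <- acum[s, e[idx] + 1L] - acum[s, b[idx]]
      }
      Wi <- W[idx, , drop = FALSE]
      full <- rowSums((cntM < L) & (Wi > 0)) == 0   # all in-radius stations complete
      if (any(full)) {
        j <- which(full)
        Wn <- Wi[j, , drop = FALSE] / rowSums(Wi[j, , drop = FALSE])
        exposure[idx[j]] <- rowSums(Wn * sumM[j, , drop = FALSE]) / L
        coverage[idx[j]] <- 1
      }
      slow <- idx[!full]
    } else slow <- integer(0)
    slow <- c(slow, which(!inside & !unlinked))

    # general per-day renormalized path for gappy or partially covered rows
    for (i in slow) {
      days <- doc_day[i] + offs - dm$day0 + 1L
      ok_day <- days >= 1L & days <= dm$n_days
      w <- W[i, ]
      vals <- rep(NA_real_, L)
      if (any(ok_day)) {
        sub <- dm$mat[, days[ok_day], drop = FALSE]
        wm <- w * dm$avail[, days[ok_day], drop = FALSE]
        den <- colSums(wm)
        num <- colSums(ifelse(is.na(sub), 0, sub) * wm)
        v <- ifelse(den > 0, num / den, NA_real_)
        vals[ok_day] <- v
      }
      coverage[i] <- mean(!is.na(vals))
      if (coverage[i] >= config$min_coverage) exposure[i] <- mean(vals, na.rm = TRUE)
    }
    exposure[coverage < config$min_coverage] <- NA_real_

    out[[wi]] <- data.table::data.table(
      participant_id = cohort$participant_id,
      window = windows[wi], exposure = exposure, coverage = coverage
    )
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "n_unlinked", sum(unlinked))
  res
}
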