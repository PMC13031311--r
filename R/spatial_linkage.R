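#' Geodesic distance on the WGS84 ellipsoid (inverse Vincenty)
#'
#' Vectorized inverse Vincenty iteration (WGS84: a = 6378137 m,
#' f = 1/298.257223563), iterated to |change in lambda| < 1e-12 or 200
#' iterations.  Near-antipodal pairs for which the iteration does not
#' converge fall back to a great-circle evaluation on the mean-radius
#' sphere, with a message.  Symmetric and non-negative.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (recycled).
#' @return distance(s) in kilometres.
#' @examples
#' geodesic_distance_km(0, 0, 0, 1)  # 111.3195 km along the equator
#' @export
geodesic_distance_km <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  lat1 <- rep_len(as.numeric(lat1), n); lon1 <- rep_len(as.numeric(lon1), n)
  lat2 <- rep_len(as.numeric(lat2), n); lon2 <- rep_len(as.numeric(lon2), n)
  if (any(is.na(c(lat1, lon1, lat2, lon2))) ||
      any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop("invalid coordinates: latitude must be in [-90,90], longitude in [-180,180], no NAs")
  }
  a <- 6378137; f <- 1 / 298.257223563; b <- a * (1 - f)
  rad <- pi / 180
  U1 <- atan((1 - f) * tan(lat1 * rad)); U2 <- atan((1 - f) * tan(lat2 * rad))
  L <- (lon2 - lon1) * rad
  sinU1 <- sin(U1); cosU1 <- cos(U1); sinU2 <- sin(U2); cosU2 <- cos(U2)

  lambda <- L
  sin_sigma <- cos_sigma <- sigma <- cos_sq_alpha <- cos2sm <- numeric(n)
  active <- rep(TRUE, n)
  iter <- 0L
  while (any(active) && iter < 200L) {
    iter <- iter + 1L
    sl <- sin(lambda[active]); cl <- cos(lambda[active])
    ss <- sqrt((cosU2[active] * sl)^2 +
                 (cosU1[active] * sinU2[active] - sinU1[active] * cosU2[active] * cl)^2)
    cs <- sinU1[active] * sinU2[active] + cosU1[active] * cosU2[active] * cl
    sig <- atan2(ss, cs)
    sin_alpha <- ifelse(ss == 0, 0, cosU1[active] * cosU2[active] * sl / ss)
    c2a <- 1 - sin_alpha^2
    c2sm <- ifelse(c2a == 0, 0, cs - 2 * sinU1[active] * sinU2[active] / c2a)
    C <- f / 16 * c2a * (4 + f * (4 - 3 * c2a))
    lam_new <- L[active] + (1 - C) * f * sin_alpha *
      (sig + C * ss * (c2sm + C * cs * (-1 + 2 * c2sm^2)))
    delta <- abs(lam_new - lambda[active])
    sin_sigma[active] <- ss; cos_sigma[active] <- cs; sigma[active] <- sig
    cos_sq_alpha[active] <- c2a; cos2sm[active] <- c2sm
    lambda[active] <- lam_new
    done <- delta < 1e-12 | ss == 0
    idx <- which(active)
    active[idx[done]] <- FALSE
  }

  out <- numeric(n)
  conv <- !active
  if (any(conv)) {
    u2 <- cos_sq_alpha[conv] * (a^2 - b^2) / b^2
    A <- 1 + u2 / 16384 * (4096 + u2 * (-768 + u2 * (320 - 175 * u2)))
    B <- u2 / 1024 * (256 + u2 * (-128 + u2 * (74 - 47 * u2)))
    dsig <- B * sin_sigma[conv] *
      (cos2sm[conv] + B / 4 * (cos_sigma[conv] * (-1 + 2 * cos2sm[conv]^2) -
        B / 6 * cos2sm[conv] * (-3 + 4 * sin_sigma[conv]^2) * (-3 + 4 * cos2sm[conv]^2)))
    out[conv] <- b * A * (sigma[conv] - dsig) / 1000
  }
  if (any(active)) {
    # near-antipodal non-convergence: robust great-circle fallback
    message(sprintf("Vincenty did not converge for %d near-antipodal pair(s); using great-circle fallback", sum(active)))
    i <- active
    cs <- sin(lat1[i] * rad) * sin(lat2[i] * rad) +
      cos(lat1[i] * rad) * cos(lat2[i] * rad) * cos(L[i])
    out[i] <- 6371.0088 * acos(pmin(1, pmax(-1, cs)))
  }
  out[sin_sigma == 0 & conv] <- 0
  out
}

#' Linkage configuration
#'
#' @param radius_km search radius around a birthplace (inclusive), default 200.
#' @param idw_power inverse-distance power, default 1.
#' @param min_coverage minimum fraction of window days that must have an
#'   interpolated anomaly for an exposure to be reported, default 0.8.
#' @param mode `"idw"` (inverse-distance weighting) or `"nearest"`.
#' @return a `periclim_linkage` configuration list.
#' @export
linkage_config <- function(radius_km = 200, idw_power = 1,
                           min_coverage = 0.8, mode = c("idw", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(radius_km > 0, idw_power > 0, min_coverage > 0, min_coverage <= 1)
  structure(list(radius_km = radius_km, idw_power = idw_power,
                 min_coverage = min_coverage, mode = mode),
            class = "periclim_linkage")
}

#' Stations within a radius of a location
#'
#' @param loc numeric `c(lat, lon)`.
#' @param stations data.frame with `station_id`, `lat`, `lon`.
#' @param radius_km inclusive radius.
#' @return data.table of in-radius stations with `distance_km`, sorted by
#'   ascending distance with ties broken by station id.  May be empty.
#' @export
stations_within_radius <- function(loc, stations, radius_km = 200) {
  d <- geodesic_distance_km(loc[1], loc[2], stations$lat, stations$lon)
  keep <- d <= radius_km
  out <- data.table::data.table(
    station_id = stations$station_id[keep],
    lat = stations$lat[keep], lon = stations$lon[keep],
    distance_km = d[keep]
  )
  out[order(out$distance_km, out$station_id)]
}

#' Inverse-distance weights
#'
#' Weights proportional to `1 / max(d, 1e-6)^power`, normalized to sum to
#' one.  The 1e-6 km clamp means a location coincident with a station
#' effectively receives that station's value.
#'
#' @param distances non-negative distances in km (non-empty).
#' @param power positive IDW exponent.
#' @return weights summing to 1.
#' @export
idw_weights <- function(distances, power = 1) {
  if (length(distances) == 0) stop("idw_weights: empty distance list")
  if (any(distances < 0)) stop("idw_weights: negative distance")
  w <- 1 / pmax(distances, 1e-6)^power
  w / sum(w)
}

#' Interpolate the anomaly field at a location and date
#'
#' IDW (or nearest-neighbour) over the in-radius stations that report a
#' deviation on that date, with weights renormalized over the reporting
#' subset.  Returns `NA` when no in-radius station reports.
#'
#' @param loc `c(lat, lon)`.
#' @param date a `Date`.
#' @param deviations data.table `station_id`, `date`, `deviation`.
#' @param stations station metadata (`station_id`, `lat`, `lon`).
#' @param config a [linkage_config()].
#' @return interpolated deviation in degC, or `NA_real_`.
#' @export
interpolate_daily_anomaly <- function(loc, date, deviations, stations,
                                      config = linkage_config()) {
  near <- stations_within_radius(loc, stations, config$radius_km)
  if (nrow(near) == 0) return(NA_real_)
  target_day <- as.Date(date)
  keep <- deviations[["date"]] == target_day &
    deviations[["station_id"]] %in% near$station_id
  day <- as.data.frame(deviations)[keep, , drop = FALSE]
  if (nrow(day) == 0) return(NA_real_)
  m <- match(day$station_id, near$station_id)
  d <- near$distance_km[m]
  if (config$mode == "nearest") {
    ord <- order(d, day$station_id)
    return(day$deviation[ord[1]])
  }
  sum(idw_weights(d, config$idw_power) * day$deviation)
}
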