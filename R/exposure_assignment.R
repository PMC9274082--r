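#' Great-circle distance between points, in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km. This is the single
#' distance function used throughout the package: station selection, IDW2
#' interpolation and the synthetic generator all call it, so monitor-to-
#' residence distances are consistent everywhere.
#'
#' @param lon1,lat1 Longitude/latitude of the first point(s), decimal degrees.
#' @param lon2,lat2 Longitude/latitude of the second point(s), decimal degrees.
#'   Arguments are vectorised and recycled in the usual way.
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(0, 0, 1, 0)   # one degree of latitude ~ 111.19 km
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE))
    stop("latitude out of range [-90, 90]")
  if (any(abs(c(lon1, lon2)) > 360, na.rm = TRUE))
    stop("longitude out of range")
  r <- 6371.0
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  # clamp guards rounding for antipodal/identical points
  2 * r * asin(pmin(1, sqrt(pmax(a, 0))))
}

#' Select monitor stations for a residence
#'
#' Applies the nearest-station rules used for exposure interpolation: of the
#' stations reporting a value, take the up-to-`max_stations` closest within
#' `max_km`; but if any station lies within `near_km` of the residence, only
#' stations within `near_km` are eligible. Distance thresholds are inclusive.
#' Ties in distance are broken by station id so selection is deterministic.
#'
#' @param lon,lat Residence coordinates, decimal degrees.
#' @param stations Data frame with columns `station_id`, `lon`, `lat` and a
#'   `value` column holding the week's concentration (NA = not reporting; such
#'   stations are excluded before selection).
#' @param max_km Outer selection radius in km (default 50).
#' @param near_km Override radius in km (default 5): if any reporting station
#'   is at distance <= `near_km`, only those stations are used.
#' @param max_stations Cap on the number of selected stations (default 4).
#' @param cap_near Whether the `max_stations` cap also applies when the
#'   `near_km` override triggers (default TRUE).
#' @return Data frame of the selected stations with a `dist_km` column, ordered
#'   by ascending distance, or a zero-row data frame if no station qualifies
#'   ("no coverage" -- not an error).
#' @export
select_stations <- function(lon, lat, stations,
                            max_km = 50, near_km = 5,
                            max_stations = 4, cap_near = TRUE) {
  stopifnot(is.data.frame(stations),
            all(c("station_id", "lon", "lat", "value") %in% names(stations)))
  st <- stations[!is.na(stations$value), , drop = FALSE]
  if (nrow(st) == 0L) return(st[, c("station_id", "lon", "lat", "value")])
  st$dist_km <- haversine_km(lon, lat, st$lon, st$lat)
  st <- st[st$dist_km <= max_km, , drop = FALSE]
  if (nrow(st) == 0L) return(st)
  near <- st$dist_km <= near_km
  if (any(near)) {
    st <- st[near, , drop = FALSE]
    cap <- if (cap_near) max_stations else nrow(st)
  } else {
    cap <- max_stations
  }
  ord <- order(st$dist_km, st$station_id)
  st <- st[ord, , drop = FALSE]
  st <- utils::head(st, cap)
  rownames(st) <- NULL
  st
}

#' Inverse distance-squared (IDW2) interpolation
#'
#' Returns `sum(w_i v_i)` with weights `w_i = d_i^-2 / sum(d_j^-2)`. Stations
#' closer than `collocate_km` (default 1 m) are treated as collocated with the
#' residence and their plain mean is returned, avoiding the 1/d^2 blow-up.
#' The result always lies within the range of the station values.
#'
#' @param values Concentrations at the selected stations.
#' @param dist_km Matching distances in km.
#' @param collocate_km Collocation epsilon in km (default 0.001).
#' @return Interpolated concentration (scalar).
#' @export
idw2_interpolate <- function(values, dist_km, collocate_km = 0.001) {
  stopifnot(length(values) == length(dist_km), length(values) >= 1L)
  col <- dist_km < collocate_km
  if (any(col)) return(mean(values[col]))
  w <- 1 / dist_km^2
  sum(w * values) / sum(w)
}

# Selection + interpolation for one point across many calendar weeks.
# `series` is a stations x weeks matrix (rows aligned with `stations`).
# Fast path: when no station has missing weeks the selection is constant and
# the whole series collapses to one weighted matrix product.
.interpolate_point_series <- function(lon, lat, stations, series, weeks,
                                      opts = exposure_options()) {
  out <- rep(NA_real_, length(weeks))
  sub <- series[, weeks, drop = FALSE]
  if (!anyNA(sub)) {
    sel <- select_stations(lon, lat,
                           cbind(stations, value = 1),
                           max_km = opts$max_km, near_km = opts$near_km,
                           max_stations = opts$max_stations,
                           cap_near = opts$cap_near)
    if (nrow(sel) == 0L) return(out)
    idx <- match(sel$station_id, stations$station_id)
    col <- sel$dist_km < opts$collocate_km
    if (any(col)) {
      w <- as.numeric(col) / sum(col)
    } else {
      w <- 1 / sel$dist_km^2
      w <- w / sum(w)
    }
    return(as.numeric(w %*% sub[idx, , drop = FALSE]))
  }
  for (k in seq_along(weeks)) {
    sel <- select_stations(lon, lat,
                           cbind(stations, value = sub[, k]),
                           max_km = opts$max_km, near_km = opts$near_km,
                           max_stations = opts$max_stations,
                           cap_near = opts$cap_near)
    if (nrow(sel) > 0L)
      out[k] <- idw2_interpolate(sel$value, sel$dist_km, opts$collocate_km)
  }
  out
}

#' Exposure-assignment options
#'
#' Bundles the tunable constants of the station-selection and interpolation
#' rules so they are set in one place.
#'
#' @param max_km Outer station radius, km.
#' @param near_km Near-station override radius, km.
#' @param max_stations Maximum stations used per interpolation.
#' @param cap_near Apply the station cap inside the near radius too.
#' @param collocate_km Collocation epsilon, km.
#' @return A named list of class `exposure_options`.
#' @export
exposure_options <- function(max_km = 50, near_km = 5, max_stations = 4,
                             cap_near = TRUE, collocate_km = 0.001) {
  structure(list(max_km = max_km, near_km = near_km,
                 max_stations = max_stations, cap_near = cap_near,
                 collocate_km = collocate_km),
            class = "exposure_options")
}

# station table (long) -> list(stations = data.frame(station_id, lon, lat),
#                              series = matrix stations x weeks)
.station_series_matrix <- function(stations_df, pollutant) {
  st <- stations_df[stations_df$pollutant == pollutant, , drop = FALSE]
  if (nrow(st) == 0L) return(NULL)
  ids <- sort(unique(st$station_id))
  weeks <- sort(unique(st$week))
  series <- matrix(NA_real_, length(ids), max(weeks),
                   dimnames = list(ids, NULL))
  series[cbind(match(st$station_id, ids), st$week)] <- st$value
  meta <- unique(st[, c("station_id", "lon", "lat")])
  meta <- meta[match(ids, meta$station_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(stations = meta, series = series)
}

#' Assign weekly exposures to one subject
#'
#' Interpolates a pollutant field at the subject's residence(s) on the
#' 52-week preconception + pregnancy grid: weeks 1-13 are the 13 weeks before
#' conception, weeks 14-52 are gestational weeks 1-39. Each grid week is
#' mapped to the station calendar week containing its midpoint. A week during
#' which the subject moved is the duration-weighted average of the
#' interpolations at each residence. Grid weeks after birth (gestational week
#' beyond the completed gestational age) are filled with the subject's
#' trimester-3 mean and flagged `padded`; weeks with no station coverage are
#' flagged `missing`.
#'
#' @param residences Data frame with `start_date`, `end_date` (Date,
#'   half-open intervals), `lon`, `lat` for one subject, covering conception
#'   minus 13 weeks through birth.
#' @param stations_df Long-format station table (`station_id`, `lon`, `lat`,
#'   `pollutant`, `week`, `value`).
#' @param pollutant Pollutant name to interpolate.
#' @param conception_date Date of conception.
#' @param gestational_age Gestational age at birth, weeks.
#' @param study_start Date of calendar week 1 in the station series.
#' @param opts [exposure_options()].
#' @return Data frame with `week` (1..52), `value`, `flag`
#'   (`observed`/`padded`/`missing`).
#' @export
assign_weekly_exposures <- function(residences, stations_df, pollutant,
                                    conception_date, gestational_age,
                                    study_start, opts = exposure_options()) {
  net <- .station_series_matrix(stations_df, pollutant)
  .assign_weekly_core(residences, net, conception_date, gestational_age,
                      study_start, opts)
}

.assign_weekly_core <- function(residences, net, conception_date,
                                gestational_age, study_start,
                                opts = exposure_options()) {
  conception_date <- as.Date(conception_date)
  study_start <- as.Date(study_start)
  residences <- residences[order(residences$start_date), , drop = FALSE]
  residences$start_date <- as.Date(residences$start_date)
  residences$end_date <- as.Date(residences$end_date)

  grid_start <- conception_date - 91            # week 1 start
  birth_date <- conception_date + round(gestational_age * 7)
  gaps <- which(utils::head(residences$end_date, -1) !=
                  utils::tail(residences$start_date, -1))
  if (length(gaps) > 0L)
    stop(sprintf("residence history has a gap after %s",
                 residences$end_date[gaps[1]]))
  if (residences$start_date[1] > grid_start ||
      utils::tail(residences$end_date, 1) < birth_date)
    stop("residence history does not cover preconception through birth")

  n_weeks_grid <- 52L
  week_starts <- grid_start + (seq_len(n_weeks_grid) - 1L) * 7L
  cal_week <- as.integer(floor(as.numeric(week_starts + 3L - study_start) / 7)) + 1L
  if (is.null(net) || any(cal_week < 1L) || any(cal_week > ncol(net$series)))
    stop("station series does not cover the subject's calendar window")

  # per-residence interpolated value for every grid week, then blend by the
  # fraction of each week spent at each residence
  value <- rep(0, n_weeks_grid)
  weight_sum <- rep(0, n_weeks_grid)
  any_missing <- rep(FALSE, n_weeks_grid)
  for (r in seq_len(nrow(residences))) {
    ov_start <- pmax(as.numeric(week_starts), as.numeric(residences$start_date[r]))
    ov_end <- pmin(as.numeric(week_starts) + 7, as.numeric(residences$end_date[r]))
    frac <- pmax(0, ov_end - ov_start) / 7
    active <- which(frac > 0)
    if (length(active) == 0L) next
    vals <- .interpolate_point_series(residences$lon[r], residences$lat[r],
                                      net$stations, net$series,
                                      cal_week[active], opts)
    miss <- is.na(vals)
    any_missing[active][miss] <- TRUE
    value[active[!miss]] <- value[active[!miss]] + frac[active][!miss] * vals[!miss]
    weight_sum[active[!miss]] <- weight_sum[active[!miss]] + frac[active][!miss]
  }
  value <- ifelse(weight_sum > 0, value / weight_sum, NA_real_)
  flag <- ifelse(weight_sum > 0 & !any_missing, "observed", "missing")
  value[flag == "missing"] <- NA_real_

  # weeks past birth: completed gestational weeks occupy grid weeks
  # 14..(13 + floor(GA)); later weeks are padded with the trimester-3 mean
  last_obs_week <- 13L + as.integer(floor(gestational_age))
  if (last_obs_week < n_weeks_grid) {
    t3_weeks <- if (last_obs_week >= 40L) 40L:last_obs_week else integer(0)
    t3 <- value[t3_weeks][flag[t3_weeks] == "observed"]
    t3_mean <- if (length(t3) == 0L || all(is.na(t3))) NA_real_
               else mean(t3, na.rm = TRUE)
    pad <- (last_obs_week + 1L):n_weeks_grid
    value[pad] <- t3_mean
    flag[pad] <- ifelse(is.na(t3_mean), "missing", "padded")
  }
  data.frame(week = seq_len(n_weeks_grid), value = value, flag = flag,
             stringsAsFactors = FALSE)
}

#' Summarise a weekly exposure series into exposure periods
#'
#' Period means over observed (non-padded, non-missing) weeks of the 52-week
#' grid. With `boundaries = "weekly"` (default), trimesters are whole
#' gestational weeks: T1 = weeks 1-13 (grid 14-26), T2 = 14-26 (grid 27-39),
#' T3 = 27-birth (grid 40+); preconception is grid weeks 1-13 and pregnancy is
#' conception to birth. With `boundaries = "daily"`, the day-based definitions
#' (days 1-90 / 91-180 / 181-birth) are applied by weighting the boundary
#' weeks fractionally.
#'
#' @param series Data frame from [assign_weekly_exposures()].
#' @param gestational_age Gestational age at birth, weeks.
#' @param boundaries `"weekly"` or `"daily"` trimester boundary convention.
#' @return Data frame with one row per period (`preconception`, `trimester1`,
#'   `trimester2`, `trimester3`, `pregnancy`): `mean` and `n_weeks` (effective
#'   number of observed weeks; NA mean when no week is observed).
#' @export
summarize_periods <- function(series, gestational_age,
                              boundaries = c("weekly", "daily")) {
  boundaries <- match.arg(boundaries)
  stopifnot(nrow(series) == 52L)
  ga_days <- gestational_age * 7
  birth_week <- 13 + gestational_age           # fractional grid week of birth
  # weight of each grid week inside [a, b] (grid-week units, half-open)
  wk_weight <- function(a, b) {
    lo <- pmax(a, series$week - 1)
    hi <- pmin(b, series$week)
    pmax(0, hi - lo)
  }
  if (boundaries == "weekly") {
    spans <- list(preconception = c(0, 13),
                  trimester1 = c(13, 26),
                  trimester2 = c(26, 39),
                  trimester3 = c(39, min(birth_week, 52)),
                  pregnancy = c(13, min(birth_week, 52)))
  } else {
    spans <- list(preconception = c(0, 13),
                  trimester1 = c(13, 13 + 90 / 7),
                  trimester2 = c(13 + 90 / 7, 13 + 180 / 7),
                  trimester3 = c(13 + 180 / 7, min(13 + ga_days / 7, 52)),
                  pregnancy = c(13, min(13 + ga_days / 7, 52)))
  }
  obs <- series$flag == "observed" & !is.na(series$value)
  rows <- lapply(names(spans), function(p) {
    w <- wk_weight(spans[[p]][1], spans[[p]][2]) * obs
    tot <- sum(w)
    data.frame(period = p,
               mean = if (tot > 0) sum(w * series$value, na.rm = TRUE) / tot
                      else NA_real_,
               n_weeks = tot, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise correlations between exposure summaries
#'
#' Pearson (and optionally Spearman) correlations across pollutant-period
#' columns of a wide per-subject summary table. Columns with zero variance
#' yield `NA` entries and are listed in the `degenerate` attribute instead of
#' propagating through the whole matrix.
#'
#' @param summaries Data frame or matrix, subjects x (pollutant-period) means.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation matrix with a `degenerate` attribute naming
#'   zero-variance columns.
#' @export
exposure_correlations <- function(summaries, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.matrix(summaries)
  stopifnot(nrow(x) >= 3L)
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  degen <- colnames(x)[!is.na(sds) & sds == 0]
  cc <- suppressWarnings(
    stats::cor(x, use = "pairwise.complete.obs", method = method))
  cc[degen, ] <- NA_real_
  cc[, degen] <- NA_real_
  diag(cc) <- ifelse(colnames(x) %in% degen, NA_real_, 1)
  attr(cc, "degenerate") <- degen
  cc
}
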