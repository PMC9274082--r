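# Small fixtures shared across test files; everything is built in code.

# a 5-CpG clock in weeks with a known intercept
tiny_clock <- function(units = "weeks") {
  clock_model("tiny", intercept = 30,
              coefficients = c(cgA = 10, cgB = -4, cgC = 2, cgD = 6,
                               cgE = -1),
              output_units = units)
}

# well-conditioned 7-type reference on m CpGs
tiny_reference <- function(m = 40, seed = 42) {
  synthetic_cell_reference(n_cpgs = m, seed = seed)
}

# single-residence history covering conception - 13wk .. birth
one_residence <- function(subject_id, conception, ga, lon, lat) {
  data.frame(subject_id = subject_id,
             start_date = as.Date(conception) - 120,
             end_date = as.Date(conception) + round(ga * 7) + 30,
             lon = lon, lat = lat, stringsAsFactors = FALSE)
}

# station long table with a constant (or per-station) value over n_weeks
flat_station_table <- function(lons, lats, values, pollutant = "PM2.5",
                               n_weeks = 200) {
  do.call(rbind, lapply(seq_along(lons), function(i)
    data.frame(station_id = sprintf("ST%02d", i), lon = lons[i],
               lat = lats[i], pollutant = pollutant, week = seq_len(n_weeks),
               value = values[i], stringsAsFactors = FALSE)))
}

# independent spherical law-of-cosines distance (oracle for haversine)
slc_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  6371.0 * acos(pmin(1, pmax(-1,
    sin(lat1 * r) * sin(lat2 * r) +
      cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r))))
}

# brute-force IDW2 oracle: explicit weight loop
idw2_oracle <- function(values, dist_km, eps = 0.001) {
  col <- dist_km < eps
  if (any(col)) return(mean(values[col]))
  num <- 0; den <- 0
  for (i in seq_along(values)) {
    num <- num + values[i] / dist_km[i]^2
    den <- den + 1 / dist_km[i]^2
  }
  num / den
}

# exhaustive-scan station selection oracle
select_oracle <- function(lon, lat, stations, max_km = 50, near_km = 5,
                          max_stations = 4) {
  st <- stations[!is.na(stations$value), , drop = FALSE]
  if (nrow(st) == 0) return(character(0))
  d <- slc_km(lon, lat, st$lon, st$lat)
  st <- st[d <= max_km, , drop = FALSE]; d <- d[d <= max_km]
  if (length(d) == 0) return(character(0))
  if (any(d <= near_km)) { st <- st[d <= near_km, , drop = FALSE]; d <- d[d <= near_km] }
  ord <- order(d, st$station_id)
  head(st$station_id[ord], max_stations)
}
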