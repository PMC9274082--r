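test_that("haversine distance is a metric and matches the spherical oracle", {
  expect_equal(haversine_km(12.3, 45.6, 12.3, 45.6), 0)
  # one degree of arc, independent spherical-law-of-cosines oracle
  expect_equal(haversine_km(0, 0, 1, 0), 111.1949, tolerance = 1e-6)
  expect_equal(haversine_km(0, 0, 1, 0), slc_km(0, 0, 1, 0),
               tolerance = 1e-9)
  set.seed(1)
  for (i in 1:50) {
    p <- runif(4, -60, 60)
    expect_equal(haversine_km(p[1], p[2], p[3], p[4]),
                 haversine_km(p[3], p[4], p[1], p[2]))
    expect_equal(haversine_km(p[1], p[2], p[3], p[4]),
                 slc_km(p[1], p[2], p[3], p[4]), tolerance = 1e-7)
    expect_gte(haversine_km(p[1], p[2], p[3], p[4]), 0)
  }
  expect_error(haversine_km(0, 95, 0, 0), "latitude")
})

# station rows at given km due north of the origin (1 km ~ 1/111.195 deg lat)
stations_at_km <- function(km, values = seq_along(km)) {
  data.frame(station_id = sprintf("S%02d", seq_along(km)), lon = 0,
             lat = km / 111.19492664455873, value = values,
             stringsAsFactors = FALSE)
}

test_that("station selection follows the 5 km override and up-to-4 cap", {
  # any station within 5 km restricts selection to the <=5 km set
  sel <- select_stations(0, 0, stations_at_km(c(3, 4, 60)))
  expect_identical(sel$station_id, c("S01", "S02"))
  # otherwise the four nearest within 50 km
  sel <- select_stations(0, 0, stations_at_km(c(10, 20, 30, 40, 45)))
  expect_identical(sel$station_id, sprintf("S%02d", 1:4))
  # inclusive outer boundary
  sel <- select_stations(0, 0, stations_at_km(49.9))
  expect_identical(sel$station_id, "S01")
  # stations not reporting this week are excluded before selection
  st <- stations_at_km(c(3, 4, 60)); st$value[1] <- NA
  sel <- select_stations(0, 0, st)
  expect_identical(sel$station_id, "S02")
  # no station in range -> zero rows, not an error
  expect_identical(nrow(select_stations(0, 0, stations_at_km(80))), 0L)
  # >4 stations inside 5 km: cap binds by default, not with cap_near = FALSE
  st5 <- stations_at_km(c(1, 2, 3, 4, 4.5))
  expect_identical(nrow(select_stations(0, 0, st5)), 4L)
  expect_identical(nrow(select_stations(0, 0, st5, cap_near = FALSE)), 5L)
})

test_that("station selection matches an exhaustive-scan oracle on random geometries", {
  set.seed(7)
  for (i in 1:300) {
    n <- sample(1:8, 1)
    st <- data.frame(station_id = sprintf("S%02d", sample(n)),
                     lon = runif(n, -0.7, 0.7), lat = runif(n, -0.7, 0.7),
                     value = ifelse(runif(n) < 0.15, NA, runif(n, 5, 30)),
                     stringsAsFactors = FALSE)
    sel <- select_stations(0.1, -0.1, st)
    expect_identical(sel$station_id, select_oracle(0.1, -0.1, st))
  }
})

test_that("IDW2 interpolation is exact on worked cases and bounded by the data", {
  expect_equal(idw2_interpolate(7.3, 12), 7.3)
  # weights 1/1 and 1/4 normalise to 0.8 / 0.2
  expect_equal(idw2_interpolate(c(10, 40), c(1, 2)), 16.0)
  # convexity: equal values are a fixed point
  expect_equal(idw2_interpolate(rep(3.7, 4), c(2, 9, 20, 41)), 3.7)
  # collocated stations return their plain mean
  expect_equal(idw2_interpolate(c(5, 9, 100), c(0.0004, 0.0006, 3)), 7)
  set.seed(2)
  for (i in 1:200) {
    k <- sample(1:4, 1)
    v <- runif(k, 0, 50); d <- runif(k, 0.01, 50)
    out <- idw2_interpolate(v, d)
    expect_equal(out, idw2_oracle(v, d), tolerance = 1e-12)
    expect_gte(out, min(v) - 1e-12); expect_lte(out, max(v) + 1e-12)
    # weights are scale-free in distance
    expect_equal(idw2_interpolate(v, 3.7 * d), out, tolerance = 1e-12)
  }
})

test_that("weekly assignment handles constant fields, padding and moves", {
  conception <- as.Date("2010-03-01")
  start <- as.Date("2009-06-01")
  st <- flat_station_table(c(0.05, -0.04, 0.1), c(0.05, 0.02, -0.08),
                           values = c(12, 12, 12))
  res <- one_residence("A", conception, 39.1, 0, 0)
  s <- assign_weekly_exposures(res, st, "PM2.5", conception, 39.1, start)
  # constant field: every grid week equals the constant, nothing padded
  expect_equal(s$value, rep(12, 52))
  expect_identical(unique(s$flag), "observed")
  # GA 36: grid weeks 50-52 padded with the trimester-3 mean
  res36 <- one_residence("B", conception, 36, 0, 0)
  s36 <- assign_weekly_exposures(res36, st, "PM2.5", conception, 36, start)
  expect_identical(s36$flag, c(rep("observed", 49), rep("padded", 3)))
  expect_equal(s36$value[50:52], rep(12, 3))
})

test_that("a mid-week move blends the two fields by duration", {
  conception <- as.Date("2010-03-01")
  start <- as.Date("2009-06-01")
  # two separated station clusters with fields 10 and 20
  st <- rbind(flat_station_table(0, 0, 10),
              flat_station_table(3, 3, 20))
  st$station_id <- rep(c("N1", "F1"), each = 200)
  # move exactly mid-week in grid week 20: week starts conception-91+19*7
  wk20 <- conception - 91 + 19 * 7
  res <- data.frame(subject_id = "M",
                    start_date = c(conception - 120, wk20 + 3.5),
                    end_date = c(wk20 + 3.5, conception + 310),
                    lon = c(0, 3), lat = c(0, 3), stringsAsFactors = FALSE)
  s <- assign_weekly_exposures(res, st, "PM2.5", conception, 39.1, start)
  expect_equal(s$value[20], 15)
  expect_equal(s$value[19], 10)
  expect_equal(s$value[21], 20)
  # residence gap overlapping the window is an error naming the gap
  res_gap <- res; res_gap$start_date[2] <- res_gap$start_date[2] + 7
  expect_error(assign_weekly_exposures(res_gap, st, "PM2.5", conception,
                                       39.1, start), "gap")
})

test_that("period summaries use the week-grid trimester boundaries", {
  mk_series <- function(values, flags = rep("observed", 52))
    data.frame(week = 1:52, value = values, flag = flags,
               stringsAsFactors = FALSE)
  # constant series: every period mean is the constant
  ps <- summarize_periods(mk_series(rep(10, 52)), 39)
  expect_equal(ps$mean, rep(10, 5))
  # series equal to the week index: arithmetic means of the index ranges
  ps <- summarize_periods(mk_series(1:52), 39)
  expect_equal(ps$mean[ps$period == "preconception"], mean(1:13))  # 7
  expect_equal(ps$mean[ps$period == "pregnancy"], mean(14:52))     # 33
  expect_equal(ps$mean[ps$period == "trimester1"], mean(14:26))
  expect_equal(ps$mean[ps$period == "trimester2"], mean(27:39))
  expect_equal(ps$mean[ps$period == "trimester3"], mean(40:52))
  # all trimester-3 weeks padded -> T3 summary missing, others present
  flags <- c(rep("observed", 39), rep("padded", 13))
  ps <- summarize_periods(mk_series(1:52, flags), 39)
  expect_true(is.na(ps$mean[ps$period == "trimester3"]))
  expect_false(anyNA(ps$mean[ps$period != "trimester3"]))
  # pregnancy mean lies within the trimester means
  set.seed(3)
  for (i in 1:20) {
    v <- runif(52, 0, 30)
    ps <- summarize_periods(mk_series(v), 39)
    tm <- ps$mean[ps$period %in% c("trimester1", "trimester2", "trimester3")]
    pg <- ps$mean[ps$period == "pregnancy"]
    expect_gte(pg, min(tm) - 1e-12); expect_lte(pg, max(tm) + 1e-12)
  }
  # daily boundaries weight the trimester-boundary weeks fractionally
  psd <- summarize_periods(mk_series(1:52), 39, boundaries = "daily")
  w <- pmax(0, pmin(13 + 90 / 7, 1:52) - pmax(13, 0:51))
  expect_equal(psd$mean[psd$period == "trimester1"],
               sum(w * 1:52) / sum(w))
})

test_that("exposure correlations flag zero-variance columns instead of NaN", {
  set.seed(4)
  x <- rnorm(30)
  m <- cbind(a = x, b = -x, c = rnorm(30), d = rep(5, 30))
  cc <- exposure_correlations(m)
  expect_equal(cc["a", "a"], 1)
  expect_equal(cc["a", "b"], -1)
  expect_true(all(is.na(cc["d", ])))
  expect_identical(attr(cc, "degenerate"), "d")
  expect_false(anyNA(cc[c("a", "b", "c"), c("a", "b", "c")]))
})

test_that("seasonally anti-phased pollutants are negatively correlated", {
  cfg <- generator_config(n_subjects = 40, seed = 5,
                          seasonal_amplitude = 0.4, ar1_rho = 0.3)
  st <- generate_monitor_network(cfg)
  cg <- generate_cohort(cfg)
  no2 <- assign_cohort_exposures(cg$cohort, cg$residences, st, "NO2",
                                 cfg$study_start)$periods
  o3 <- assign_cohort_exposures(cg$cohort, cg$residences, st, "O3",
                                cfg$study_start)$periods
  m <- cbind(NO2_pre = no2$preconception, O3_pre = o3$preconception)
  cc <- exposure_correlations(m)
  expect_lt(cc["NO2_pre", "O3_pre"], 0)
  expect_equal(cc["NO2_pre", "O3_pre"],
               cor(m[, 1], m[, 2], use = "pairwise.complete.obs"))
})
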