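#' Configuration for the synthetic-cohort generator
#'
#' Defaults emulate the pooled two-site (East/West coast) cord-blood study the
#' pipeline targets: regional weekly pollutant fields with seasonal cycles and
#' AR(1) noise, gestational ages centred at 39.1 (SD 1.3) weeks, and covariate
#' frequencies matching the pooled cohort's descriptive table. All defaults
#' are overridable; the generator is fully seeded.
#'
#' @param n_subjects Number of subjects.
#' @param n_stations_per_region Monitor stations per region per pollutant.
#' @param regions Named list of bounding boxes `c(lon_min, lon_max, lat_min,
#'   lat_max)` in decimal degrees.
#' @param region_weights Sampling probabilities of residence region.
#' @param region_level_factor Multiplier applied to `pollutant_means` per
#'   region (named like `regions`).
#' @param pollutant_means Named mean concentrations: NO2/O3 in ppb, PM2.5/PM10
#'   in ug/m3.
#' @param pollutant_sds Stationary weekly SDs, same units.
#' @param seasonal_amplitude Seasonal sinusoid amplitude as a fraction of the
#'   regional mean.
#' @param seasonal_phase Named phase shift (radians) per pollutant; opposite
#'   phases make pollutants seasonally anticorrelated (ozone peaks in summer,
#'   NO2 in winter).
#' @param ar1_rho AR(1) autocorrelation of the weekly noise, in \[0, 1).
#' @param ga_mean_weeks,ga_sd_weeks Gestational age distribution (truncated to
#'   \[30, 43\] weeks at draw time).
#' @param mover_fraction Fraction of subjects with two residence intervals.
#' @param covariate_freqs Named list of categorical frequencies for `sex`,
#'   `race_ethnicity`, `education`, `birth_year_band`.
#' @param study_start Date of station calendar week 1.
#' @param n_weeks Length of the station series in weeks.
#' @param seed Integer seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    n_subjects = 332L,
    n_stations_per_region = 8L,
    regions = list(East = c(-75.6, -74.8, 39.6, 40.4),
                   West = c(-122.3, -121.5, 38.2, 39.0)),
    region_weights = c(East = 0.214, West = 0.786),
    region_level_factor = c(East = 1.12, West = 0.96),
    pollutant_means = c(NO2 = 11.1, O3 = 25.7, PM2.5 = 9.8, PM10 = 18.8),
    pollutant_sds = c(NO2 = 3.0, O3 = 4.3, PM2.5 = 2.0, PM10 = 3.8),
    seasonal_amplitude = 0.3,
    seasonal_phase = c(NO2 = pi, O3 = 0, PM2.5 = 0.5 * pi, PM10 = 0.3 * pi),
    ar1_rho = 0.7,
    ga_mean_weeks = 39.1,
    ga_sd_weeks = 1.3,
    mover_fraction = 0.10,
    covariate_freqs = list(
      sex = c(male = 0.578, female = 0.422),
      race_ethnicity = c(White = 0.578, Black = 0.056, Asian = 0.108,
                         Other = 0.065, Hispanic = 0.193),
      education = c(high_school = 0.100, college = 0.687, graduate = 0.213),
      birth_year_band = c(`2006-2009` = 0.190, `2010-2012` = 0.566,
                          `2013-2015` = 0.244)),
    study_start = as.Date("2004-11-29"),
    n_weeks = 620L,
    seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_stations_per_region = as.integer(n_stations_per_region),
              regions = regions, region_weights = region_weights,
              region_level_factor = region_level_factor,
              pollutant_means = pollutant_means,
              pollutant_sds = pollutant_sds,
              seasonal_amplitude = seasonal_amplitude,
              seasonal_phase = seasonal_phase,
              ar1_rho = ar1_rho,
              ga_mean_weeks = ga_mean_weeks, ga_sd_weeks = ga_sd_weeks,
              mover_fraction = mover_fraction,
              covariate_freqs = covariate_freqs,
              study_start = as.Date(study_start),
              n_weeks = as.integer(n_weeks),
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

#' @rdname generator_config
#' @param config A candidate configuration list.
#' @export
validate_generator_config <- function(config) {
  stopifnot(config$n_subjects >= 1L,
            config$ga_sd_weeks >= 0,
            config$ar1_rho >= 0, config$ar1_rho < 1,
            all(config$pollutant_means > 0),
            all(config$pollutant_sds >= 0),
            config$mover_fraction >= 0, config$mover_fraction <= 1)
  if (length(config$regions) == 0L)
    stop("configuration error: empty region list")
  for (b in config$regions) {
    if (length(b) != 4L || b[1] >= b[2] || b[3] >= b[4])
      stop("configuration error: degenerate region bounding box")
  }
  invisible(config)
}

# one AR(1) path with stationary sd `sd_target`, mean 0
.ar1_series <- function(n, rho, sd_target) {
  if (sd_target == 0) return(rep(0, n))
  innov_sd <- sd_target * sqrt(1 - rho^2)
  e <- stats::rnorm(n, 0, innov_sd)
  as.numeric(stats::filter(e, rho, method = "recursive",
                           init = stats::rnorm(1, 0, sd_target)))
}

#' Generate a synthetic monitor-station network
#'
#' Places stations uniformly inside each region's bounding box and simulates a
#' weekly concentration series per station and pollutant: regional mean plus a
#' seasonal sinusoid (amplitude `seasonal_amplitude` x mean, 52-week period)
#' plus AR(1) noise with the configured stationary SD, truncated at zero.
#'
#' @param config A [generator_config()].
#' @return Long-format data frame: `station_id`, `region`, `lon`, `lat`,
#'   `pollutant`, `week`, `value`.
#' @export
generate_monitor_network <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed + 101L)
  pollutants <- names(config$pollutant_means)
  weeks <- seq_len(config$n_weeks)
  out <- list()
  for (rg in names(config$regions)) {
    box <- config$regions[[rg]]
    for (pol in pollutants) {
      mu <- config$pollutant_means[[pol]] * config$region_level_factor[[rg]]
      amp <- config$seasonal_amplitude * mu
      phase <- config$seasonal_phase[[pol]]
      seasonal <- amp * sin(2 * pi * weeks / 52 + phase)
      for (s in seq_len(config$n_stations_per_region)) {
        lon <- stats::runif(1, box[1], box[2])
        lat <- stats::runif(1, box[3], box[4])
        noise <- .ar1_series(config$n_weeks, config$ar1_rho,
                             config$pollutant_sds[[pol]])
        vals <- pmax(0, mu + seasonal + noise)
        out[[length(out) + 1L]] <- data.frame(
          station_id = sprintf("%s_%s_%02d", rg, pol, s),
          region = rg, lon = lon, lat = lat, pollutant = pol,
          week = weeks, value = vals, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Generate a synthetic cohort with residence histories
#'
#' Draws gestational ages from a truncated normal, birth dates inside the
#' configured birth-year bands, covariates from the configured categorical
#' frequencies, one home location per subject inside its region, and a second
#' residence interval for a configurable fraction of movers. Residence
#' intervals are half-open and cover 13 weeks before conception through birth.
#'
#' @param config A [generator_config()].
#' @return List with `cohort` (one row per subject) and `residences`
#'   (subject_id, start_date, end_date, lon, lat).
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed + 202L)
  n <- config$n_subjects
  ga <- .rtruncnorm(n, config$ga_mean_weeks, config$ga_sd_weeks, 30, 43)

  bands <- config$covariate_freqs$birth_year_band
  band <- sample(names(bands), n, replace = TRUE, prob = bands)
  band_range <- lapply(strsplit(names(bands), "-"), as.integer)
  names(band_range) <- names(bands)
  birth_year <- vapply(band, function(b) {
    r <- band_range[[b]]; sample(seq(r[1], r[2]), 1L)
  }, integer(1))
  birth_date <- as.Date(sprintf("%d-01-01", birth_year)) +
    sample(0:364, n, replace = TRUE)
  conception_date <- birth_date - round(ga * 7)

  region <- sample(names(config$regions), n, replace = TRUE,
                   prob = config$region_weights[names(config$regions)])
  draw_cat <- function(freqs) sample(names(freqs), n, TRUE, prob = freqs)
  cohort <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    region = region,
    gestational_age = ga,
    conception_date = conception_date,
    birth_date = birth_date,
    sex = draw_cat(config$covariate_freqs$sex),
    race_ethnicity = draw_cat(config$covariate_freqs$race_ethnicity),
    education = draw_cat(config$covariate_freqs$education),
    birth_year_band = band,
    stringsAsFactors = FALSE)

  res <- vector("list", n)
  mover <- stats::runif(n) < config$mover_fraction
  for (i in seq_len(n)) {
    box <- config$regions[[region[i]]]
    lon <- stats::runif(1, box[1], box[2])
    lat <- stats::runif(1, box[3], box[4])
    start <- conception_date[i] - 120L
    end <- birth_date[i] + 30L
    if (mover[i]) {
      move_day <- conception_date[i] - 91L +
        sample.int(as.integer(birth_date[i] - (conception_date[i] - 91L)), 1L)
      lon2 <- stats::runif(1, box[1], box[2])
      lat2 <- stats::runif(1, box[3], box[4])
      res[[i]] <- data.frame(
        subject_id = cohort$subject_id[i],
        start_date = c(start, move_day), end_date = c(move_day, end),
        lon = c(lon, lon2), lat = c(lat, lat2), stringsAsFactors = FALSE)
    } else {
      res[[i]] <- data.frame(
        subject_id = cohort$subject_id[i],
        start_date = start, end_date = end, lon = lon, lat = lat,
        stringsAsFactors = FALSE)
    }
  }
  list(cohort = cohort, residences = do.call(rbind, res))
}

#' Synthetic cell-type methylation reference
#'
#' Random but reproducible CpG x 7 cell-type beta profiles for the cord-blood
#' cell types used in deconvolution. Profiles are drawn from Beta(2, 2) so
#' they are well inside (0, 1) and linearly independent with overwhelming
#' probability.
#'
#' @param n_cpgs Number of reference CpGs.
#' @param seed Integer seed.
#' @return Matrix CpG x 7 with cell-type column names.
#' @export
synthetic_cell_reference <- function(n_cpgs = 400L, seed = 1L) {
  set.seed(seed + 303L)
  types <- c("Bcell", "CD4T", "CD8T", "Mono", "Gran", "nRBC", "NK")
  R <- matrix(stats::rbeta(n_cpgs * length(types), 2, 2), n_cpgs,
              dimnames = list(sprintf("cg3%07d", seq_len(n_cpgs)), types))
  R
}

# pooled-cohort mean cell fractions (B, CD4T, CD8T, Mono, Gran, nRBC, NK)
.default_cell_means <- function() {
  m <- c(Bcell = 10.3, CD4T = 18.9, CD8T = 12.1, Mono = 8.8,
         Gran = 44.1, nRBC = 9.5, NK = 0.5)
  m / sum(m)
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

#' Generate methylation beta matrices with a known clock signal
#'
#' Constructs a samples x CpGs beta matrix so that the supplied clock's linear
#' predictor returns each subject's target epigenetic age exactly before
#' noise: clock-CpG betas are set to `0.5 + delta_i * coef_j`, the minimum-norm
#' adjustment from 0.5 along the coefficient direction that solves
#' `intercept + sum(coef * beta) = target`. Non-clock CpGs are convex mixtures
#' of the cell-reference profiles under per-subject Dirichlet cell
#' proportions. Gaussian noise is added on the beta scale and values are
#' clipped to \[0, 1\] (clip count reported).
#'
#' @param cohort Cohort data frame from [generate_cohort()].
#' @param clock A [clock_model()].
#' @param cell_reference CpG x cell-type matrix ([synthetic_cell_reference()]).
#' @param noise_sd Beta-scale noise SD (default 0.005).
#' @param seed Integer seed.
#' @param target_ages Target epigenetic ages in weeks; default gestational age
#'   plus `planted_acceleration`.
#' @param planted_acceleration Scalar or per-subject vector of planted
#'   acceleration, weeks (default 0).
#' @param cell_alpha Dirichlet concentration (default 50 x pooled means).
#' @return List: `betas` (matrix), `truth` (list with `true_epigenetic_age`,
#'   `true_cell_proportions`), `n_clipped`.
#' @export
generate_methylation <- function(cohort, clock, cell_reference,
                                 noise_sd = 0.005, seed = 1L,
                                 target_ages = NULL,
                                 planted_acceleration = 0,
                                 cell_alpha = NULL) {
  n <- nrow(cohort)
  if (is.null(target_ages))
    target_ages <- cohort$gestational_age + planted_acceleration
  stopifnot(length(target_ages) == n)
  set.seed(seed + 404L)

  if (is.null(cell_alpha)) cell_alpha <- 50 * .default_cell_means()
  P <- .rdirichlet(n, cell_alpha)
  rownames(P) <- cohort$subject_id

  coefs <- clock$coefficients
  target_units <- if (clock$output_units == "days") target_ages * 7 else target_ages
  s1 <- sum(coefs); s2 <- sum(coefs^2)
  delta <- (target_units - clock$intercept - 0.5 * s1) / s2
  clock_betas <- 0.5 + outer(delta, coefs)       # n x n_clock
  bad <- which(apply(clock_betas, 1, function(r) any(r < 0 | r > 1)))
  if (length(bad) > 0L)
    stop(sprintf("target age unreachable with betas in [0,1] for subject %s",
                 cohort$subject_id[bad[1]]))

  nonclock <- setdiff(rownames(cell_reference), names(coefs))
  mix <- P %*% t(cell_reference[nonclock, , drop = FALSE])   # n x n_nonclock
  betas <- cbind(clock_betas, mix)
  colnames(betas) <- c(names(coefs), nonclock)
  rownames(betas) <- cohort$subject_id

  n_clipped <- 0L
  if (noise_sd > 0) {
    betas <- betas + stats::rnorm(length(betas), 0, noise_sd)
    n_clipped <- sum(betas < 0 | betas > 1)
    betas[] <- pmin(1, pmax(0, betas))
  }
  list(betas = betas,
       truth = list(true_epigenetic_age = stats::setNames(target_ages,
                                                          cohort$subject_id),
                    true_cell_proportions = P),
       n_clipped = n_clipped)
}

#' Smooth lag-effect curve concentrated on a window
#'
#' A Gaussian bump over the 52-week grid, the package's canonical planted lag
#' effect: with the defaults it is negative, centred mid-grid and effectively
#' confined to weeks 12-29 (|effect| < 14% of the peak outside 2 SDs).
#'
#' @param amplitude Peak effect, weeks of acceleration per concentration unit.
#' @param center Peak week on the 1..52 grid.
#' @param sd Width of the bump in weeks.
#' @param n_weeks Grid length.
#' @return Numeric vector of length `n_weeks`.
#' @export
gaussian_lag_curve <- function(amplitude = -0.03, center = 20.5, sd = 4.25,
                               n_weeks = 52L) {
  amplitude * exp(-0.5 * ((seq_len(n_weeks) - center) / sd)^2)
}

#' Plant a distributed-lag effect on weekly exposures
#'
#' Per subject, the true acceleration is the lag-weighted sum of the 52 weekly
#' exposures plus Gaussian noise:
#' `accel_i = sum_l lag[l] * X[i, l] + N(0, noise_sd^2)`.
#'
#' @param weekly Exposure matrix, subjects x 52 weeks (complete).
#' @param lag_function Numeric vector of length 52, or a function of the week
#'   index; must be defined (non-NA) on every week.
#' @param noise_sd Noise SD, weeks.
#' @param seed Integer seed.
#' @return List: `acceleration` (numeric vector) and `truth` (the lag curve).
#' @export
plant_lag_effect <- function(weekly, lag_function, noise_sd = 1, seed = 1L) {
  weekly <- as.matrix(weekly)
  stopifnot(ncol(weekly) == 52L, !anyNA(weekly))
  lag <- if (is.function(lag_function)) lag_function(1:52) else lag_function
  if (length(lag) != 52L || anyNA(lag))
    stop("lag function must be defined on all 52 weeks")
  set.seed(seed + 505L)
  accel <- drop(weekly %*% lag) +
    if (noise_sd > 0) stats::rnorm(nrow(weekly), 0, noise_sd) else 0
  list(acceleration = as.numeric(accel), truth = lag)
}

#' Plant a period-average effect
#'
#' True acceleration is a linear effect of a period-mean exposure (reported
#' per 10 concentration units) plus optional covariate offsets and noise.
#'
#' @param period_mean Per-subject period-average exposure.
#' @param effect_per_10 Effect in weeks per 10 concentration units.
#' @param noise_sd Noise SD, weeks.
#' @param offset Optional per-subject offset (covariate effects), weeks.
#' @param seed Integer seed.
#' @return Numeric acceleration vector.
#' @export
plant_period_effect <- function(period_mean, effect_per_10, noise_sd = 1,
                                offset = 0, seed = 1L) {
  set.seed(seed + 606L)
  (effect_per_10 / 10) * period_mean + offset +
    if (noise_sd > 0) stats::rnorm(length(period_mean), 0, noise_sd) else 0
}
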