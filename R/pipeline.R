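#' Assign weekly exposures and period summaries for a whole cohort
#'
#' Loops [assign_weekly_exposures()] and [summarize_periods()] over every
#' subject for one pollutant, building the station series matrix once.
#'
#' @param cohort Cohort data frame (needs `subject_id`, `conception_date`,
#'   `gestational_age`).
#' @param residences Residence-history data frame.
#' @param stations_df Long-format station table.
#' @param pollutant Pollutant to interpolate.
#' @param study_start Date of station calendar week 1.
#' @param opts [exposure_options()].
#' @param boundaries Trimester boundary convention, see [summarize_periods()].
#' @return List: `weekly` (long data frame subject_id, pollutant, week, value,
#'   flag), `weekly_matrix` (subjects x 52), `periods` (wide data frame of
#'   period means per subject).
#' @export
assign_cohort_exposures <- function(cohort, residences, stations_df, pollutant,
                                    study_start, opts = exposure_options(),
                                    boundaries = "weekly") {
  n <- nrow(cohort)
  wk <- matrix(NA_real_, n, 52,
               dimnames = list(cohort$subject_id, NULL))
  flags <- matrix("missing", n, 52)
  period_names <- c("preconception", "trimester1", "trimester2", "trimester3",
                    "pregnancy")
  pmeans <- matrix(NA_real_, n, 5,
                   dimnames = list(cohort$subject_id, period_names))
  net <- .station_series_matrix(stations_df, pollutant)
  res_split <- split(residences, residences$subject_id)
  for (i in seq_len(n)) {
    sid <- cohort$subject_id[i]
    series <- .assign_weekly_core(res_split[[sid]], net,
                                  cohort$conception_date[i],
                                  cohort$gestational_age[i],
                                  study_start, opts)
    wk[i, ] <- series$value
    flags[i, ] <- series$flag
    ps <- summarize_periods(series, cohort$gestational_age[i], boundaries)
    pmeans[i, ] <- ps$mean[match(period_names, ps$period)]
  }
  long <- data.frame(subject_id = rep(cohort$subject_id, each = 52),
                     pollutant = pollutant,
                     week = rep(1:52, n),
                     value = as.numeric(t(wk)),
                     flag = as.character(t(flags)),
                     stringsAsFactors = FALSE)
  list(weekly = long, weekly_matrix = wk, flags = flags,
       periods = data.frame(subject_id = cohort$subject_id, pmeans,
                            check.names = FALSE, stringsAsFactors = FALSE))
}

#' Default pipeline run configuration
#'
#' @param synth Named list of [generator_config()] overrides.
#' @param pollutants Pollutants carried through the pipeline.
#' @param clocks Bundled clock names to evaluate.
#' @param covariates Covariate columns used in all adjusted models.
#' @param scale_per Reporting scale (concentration units).
#' @param mutual Also fit mutually adjusted period models.
#' @param dlm_df,dlm_kind Lag-basis degrees of freedom and kind.
#' @param dlm_compare Also rank ns/poly/df alternatives by AIC.
#' @param beta_noise_sd Beta-scale methylation noise SD.
#' @param accel_noise_sd Outcome noise SD, weeks.
#' @param planted_lag Either NULL or a list (pollutant, amplitude, center, sd)
#'   describing the planted lag-effect curve.
#' @param seed Global seed; per-stage substreams are derived from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(synth = list(),
                       pollutants = c("PM2.5", "PM10"),
                       clocks = c("knight", "bohlin"),
                       covariates = c("sex", "race_ethnicity", "education",
                                      "birth_year_band", "region"),
                       scale_per = 10,
                       mutual = TRUE,
                       dlm_df = 4L, dlm_kind = "ns", dlm_compare = FALSE,
                       beta_noise_sd = 0.005,
                       accel_noise_sd = 1,
                       planted_lag = list(pollutant = "PM2.5",
                                          amplitude = -0.03,
                                          center = 20.5, sd = 4.25),
                       seed = 1L) {
  structure(list(synth = synth, pollutants = pollutants, clocks = clocks,
                 covariates = covariates, scale_per = scale_per,
                 mutual = mutual, dlm_df = as.integer(dlm_df),
                 dlm_kind = dlm_kind, dlm_compare = dlm_compare,
                 beta_noise_sd = beta_noise_sd,
                 accel_noise_sd = accel_noise_sd,
                 planted_lag = planted_lag, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file whose top-level keys match [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

# deterministic per-stage substreams from the global seed
.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + stage * 1009L) %% 2147483647L
}

#' Run the full synthetic pipeline
#'
#' Executes synth -> assign -> clock -> fit -> dlm in order on a seeded
#' synthetic cohort: generates the monitor network, cohort and residence
#' histories; interpolates weekly exposures and period summaries per
#' pollutant; plants the configured true lag effect; builds beta matrices
#' encoding gestational age plus the planted acceleration; predicts epigenetic
#' age per clock, estimates cell proportions and residualises to age
#' acceleration; fits individual and mutually adjusted period models; and fits
#' the weekly distributed-lag model per pollutant and clock.
#'
#' @param config A [run_config()].
#' @param outdir Optional output directory; when given, writes stations.csv,
#'   residences.csv, cohort.csv, betas.csv, exposures.csv, periods.csv,
#'   period_results.csv, lag_curves.csv, windows.json, truth.json and
#'   manifest.json.
#' @return List with `cohort`, `exposures` (per pollutant), `acceleration`
#'   (per clock), `period_results`, `lag_curves`, `windows`, `truth`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  gc_args <- config$synth
  gc_args$seed <- .stage_seed(config$seed, 1L)
  gcfg <- do.call(generator_config, gc_args)

  stations <- generate_monitor_network(gcfg)
  cg <- generate_cohort(gcfg)
  cohort <- cg$cohort

  exposures <- lapply(config$pollutants, function(p)
    assign_cohort_exposures(cohort, cg$residences, stations, p,
                            gcfg$study_start))
  names(exposures) <- config$pollutants

  # planted truth: lag effect of one pollutant's weekly series
  lag_truth <- NULL
  planted_accel <- rep(0, nrow(cohort))
  if (!is.null(config$planted_lag)) {
    pl <- config$planted_lag
    if (!pl$pollutant %in% config$pollutants)
      stop("planted_lag pollutant is not among the configured pollutants")
    lag_truth <- gaussian_lag_curve(pl$amplitude, pl$center, pl$sd)
    wkm <- exposures[[pl$pollutant]]$weekly_matrix
    # subjects without full station coverage carry no planted exposure signal;
    # they are excluded from the exposure models by complete-case handling
    complete <- !apply(is.na(wkm), 1L, any)
    wkm_fill <- wkm
    if (any(!complete))
      wkm_fill[!complete, ] <- rep(colMeans(wkm, na.rm = TRUE),
                                   each = sum(!complete))
    wkm_fill[is.na(wkm_fill)] <- mean(wkm, na.rm = TRUE)
    planted <- plant_lag_effect(wkm_fill, lag_truth, config$accel_noise_sd,
                                seed = .stage_seed(config$seed, 2L))
    planted_accel <- planted$acceleration
  }

  cell_ref <- synthetic_cell_reference(seed = .stage_seed(config$seed, 3L))
  clock_objs <- lapply(config$clocks, load_bundled_clock)
  names(clock_objs) <- config$clocks

  # one beta matrix encodes all clocks' targets? each clock has its own CpGs,
  # so the same matrix can carry both clocks' planted signal
  betas <- NULL
  truth <- list(true_lag_function = lag_truth)
  accel_tabs <- list()
  for (ck in config$clocks) {
    gm <- generate_methylation(cohort, clock_objs[[ck]], cell_ref,
                               noise_sd = config$beta_noise_sd,
                               seed = .stage_seed(config$seed, 4L),
                               planted_acceleration = planted_accel)
    if (is.null(betas)) {
      betas <- gm$betas
      truth$true_cell_proportions <- gm$truth$true_cell_proportions
      truth$true_epigenetic_age <- gm$truth$true_epigenetic_age
    } else {
      new_cols <- setdiff(colnames(gm$betas), colnames(betas))
      betas <- cbind(betas, gm$betas[, new_cols, drop = FALSE])
    }
  }
  cellp <- estimate_cell_proportions(betas, cell_ref)
  for (ck in config$clocks) {
    ea <- predict_epigenetic_age(betas, clock_objs[[ck]])
    accel_tabs[[ck]] <- compute_age_acceleration(ea, cohort$gestational_age,
                                                 cellp)
  }

  covars <- cohort[, config$covariates, drop = FALSE]
  period_names <- c("preconception", "trimester1", "trimester2", "trimester3",
                    "pregnancy")
  rows <- list()
  for (ck in config$clocks) {
    for (p in config$pollutants) {
      d <- cbind(acceleration = accel_tabs[[ck]]$acceleration,
                 exposures[[p]]$periods[, period_names], covars)
      for (per in period_names) {
        r <- fit_period_model(d, "acceleration",
                              model_spec(per, config$covariates,
                                         config$scale_per))
        rows[[length(rows) + 1L]] <- cbind(
          clock = ck, pollutant = p, period = per, model_type = "individual",
          r[, c("beta", "se", "ci_low", "ci_high", "p_value", "n_used")])
      }
      if (config$mutual) {
        for (grp in list(c("preconception", "pregnancy"),
                         c("trimester1", "trimester2", "trimester3"))) {
          r <- fit_mutually_adjusted(d, "acceleration", grp, config$covariates,
                                     config$scale_per)
          rows[[length(rows) + 1L]] <- cbind(
            clock = ck, pollutant = p, period = r$term,
            model_type = "mutually_adjusted",
            r[, c("beta", "se", "ci_low", "ci_high", "p_value", "n_used")])
        }
      }
    }
  }
  period_results <- do.call(rbind, rows)
  rownames(period_results) <- NULL

  basis <- lag_basis(df = config$dlm_df, kind = config$dlm_kind)
  curves <- list(); windows <- list(); aic_tables <- list()
  for (ck in config$clocks) {
    for (p in config$pollutants) {
      wkm <- exposures[[p]]$weekly_matrix
      ok <- !apply(is.na(wkm), 1L, any)
      fit <- fit_dlm(build_cross_basis(wkm[ok, , drop = FALSE], basis),
                     accel_tabs[[ck]]$acceleration[ok],
                     covars[ok, , drop = FALSE])
      le <- lag_effects(fit, basis, scale = config$scale_per)
      curves[[length(curves) + 1L]] <- cbind(clock = ck, pollutant = p,
                                             le$curve)
      windows[[paste(ck, p, sep = ".")]] <- le$windows
      if (config$dlm_compare) {
        cands <- list(lag_basis(df = 3L), lag_basis(df = 4L),
                      lag_basis(df = 5L), lag_basis(df = 4L, kind = "poly"))
        aic_tables[[paste(ck, p, sep = ".")]] <-
          compare_bases(wkm, accel_tabs[[ck]]$acceleration, cands, covars)
      }
    }
  }
  lag_curves <- do.call(rbind, curves)
  rownames(lag_curves) <- NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("prenatalDLM")),
    seed = config$seed,
    config_hash = sum(utf8ToInt(paste(deparse(unclass(config)),
                                      collapse = ""))),
    n_subjects = nrow(cohort),
    n_stations = length(unique(stations$station_id)),
    stages = list(
      synth = nrow(cohort),
      assign = nrow(cohort),
      clock = nrow(betas),
      fit = unique(period_results$n_used),
      dlm = unique(vapply(config$clocks, function(ck)
        nrow(accel_tabs[[ck]]), integer(1)))))

  result <- list(cohort = cohort, stations = stations,
                 residences = cg$residences,
                 exposures = exposures, betas = betas,
                 cell_proportions = cellp,
                 acceleration = accel_tabs,
                 period_results = period_results,
                 lag_curves = lag_curves, windows = windows,
                 aic_tables = aic_tables,
                 truth = truth, manifest = manifest)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    .write_csv6(stations, file.path(outdir, "stations.csv"))
    .write_csv6(cg$residences, file.path(outdir, "residences.csv"))
    .write_csv6(cohort, file.path(outdir, "cohort.csv"))
    write_betas_csv(betas, file.path(outdir, "betas.csv"))
    .write_csv6(do.call(rbind, lapply(exposures, `[[`, "weekly")),
                file.path(outdir, "exposures.csv"))
    .write_csv6(do.call(rbind, lapply(names(exposures), function(p)
      cbind(pollutant = p, exposures[[p]]$periods))),
      file.path(outdir, "periods.csv"))
    .write_csv6(period_results, file.path(outdir, "period_results.csv"))
    .write_csv6(lag_curves, file.path(outdir, "lag_curves.csv"))
    jsonlite::write_json(windows, file.path(outdir, "windows.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
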