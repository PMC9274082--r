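#' Specify a period-average exposure model
#'
#' Describes one linear model of residual age acceleration (weeks) on one or
#' more period-average exposures, with covariate adjustment. Exposure
#' coefficients are reported per `scale_per` concentration units (default 10,
#' the reporting convention for all pollutants).
#'
#' @param exposures Character vector of exposure column names (one for an
#'   individual model; several for a mutually adjusted model).
#' @param covariates Character vector of covariate column names (categorical
#'   covariates are expanded by reference-level coding inside the fit).
#' @param scale_per Concentration units per reported coefficient unit.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(exposures, covariates = character(0), scale_per = 10,
                       conf_level = 0.95) {
  stopifnot(length(exposures) >= 1L, scale_per > 0,
            conf_level > 0, conf_level < 1)
  structure(list(exposures = exposures, covariates = covariates,
                 scale_per = scale_per, conf_level = conf_level),
            class = "model_spec")
}

# OLS with t-based CIs; returns tidy rows for the requested terms.
.fit_ols <- function(data, outcome, exposures, covariates, scale_per,
                     conf_level) {
  rhs_vars <- c(exposures, covariates)
  if (anyDuplicated(rhs_vars))
    stop(sprintf("singular design; aliased terms: %s",
                 paste(unique(rhs_vars[duplicated(rhs_vars)]), collapse = ", ")))
  vars <- c(outcome, rhs_vars)
  miss <- setdiff(vars, names(data))
  if (length(miss) > 0L)
    stop(sprintf("columns not found: %s", paste(miss, collapse = ", ")))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
            drop = FALSE]
  n_used <- nrow(d)
  rhs <- paste(vapply(c(exposures, covariates),
                      function(v) sprintf("`%s`", v), ""), collapse = " + ")
  fml <- stats::as.formula(sprintf("`%s` ~ %s", outcome, rhs))
  p_expected <- length(exposures) + length(covariates) + 1L
  if (n_used < p_expected + 5L)
    stop(sprintf("too few complete cases (%d) for %d parameters",
                 n_used, p_expected))
  fit <- stats::lm(fml, data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop(sprintf("singular design; aliased terms: %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")))
  sm <- summary(fit)$coefficients
  df_res <- fit$df.residual
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df_res)
  rows <- lapply(exposures, function(e) {
    nm <- sprintf("`%s`", e)
    nm <- if (nm %in% rownames(sm)) nm else e
    b <- sm[nm, "Estimate"] * scale_per
    se <- sm[nm, "Std. Error"] * scale_per
    data.frame(term = e, beta = b, se = se,
               ci_low = b - tcrit * se, ci_high = b + tcrit * se,
               p_value = sm[nm, "Pr(>|t|)"], n_used = n_used,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), fit = fit)
}

#' Fit an individual period-average exposure model
#'
#' Ordinary least squares of age acceleration on one period-average exposure
#' plus covariates, with listwise deletion of incomplete cases. The exposure
#' coefficient, its classical SE and its t-based confidence interval are
#' reported per `scale_per` (default 10) concentration units.
#'
#' @param data Data frame joining acceleration, period exposure means and
#'   covariates (one row per subject).
#' @param outcome Outcome column name (acceleration, weeks).
#' @param spec A [model_spec()] with a single exposure.
#' @return One-row data frame: `term`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `p_value`, `n_used`.
#' @export
fit_period_model <- function(data, outcome, spec) {
  stopifnot(inherits(spec, "model_spec"))
  .fit_ols(data, outcome, spec$exposures, spec$covariates, spec$scale_per,
           spec$conf_level)
}

#' Fit a mutually adjusted multi-period model
#'
#' One model containing all listed period terms for a pollutant (for example
#' preconception + pregnancy, or the three trimesters) plus covariates, so the
#' period estimates are mutually adjusted for each other.
#'
#' @param data Data frame as in [fit_period_model()].
#' @param outcome Outcome column name.
#' @param period_columns Character vector (>= 2) of period exposure columns.
#' @param covariates Covariate column names.
#' @param scale_per Reporting scale (default 10 units).
#' @param conf_level Confidence level.
#' @return Data frame with one row per period term.
#' @export
fit_mutually_adjusted <- function(data, outcome, period_columns,
                                  covariates = character(0), scale_per = 10,
                                  conf_level = 0.95) {
  stopifnot(length(period_columns) >= 2L)
  .fit_ols(data, outcome, period_columns, covariates, scale_per, conf_level)
}

#' Change-in-estimate confounder screening
#'
#' One-candidate-at-a-time screening against a core model: for each candidate
#' covariate, the exposure coefficient from the core model (exposure plus any
#' forced covariates) is compared with the coefficient after adding that
#' candidate alone; the candidate is retained when the relative change
#' `|beta_with - beta_without| / |beta_without|` meets the threshold (default
#' 15%). Candidates are evaluated in their declared order. When the core
#' coefficient is exactly zero the relative change is undefined and the
#' candidate is flagged `indeterminate` rather than silently retained.
#'
#' @param data Data frame of outcome, exposure and covariates.
#' @param outcome Outcome column name.
#' @param exposure Exposure column name.
#' @param candidates Character vector of candidate covariate columns.
#' @param forced Covariates always kept in the core model.
#' @param threshold Retention threshold as a fraction (default 0.15).
#' @param scale_per Reporting scale passed through to the fits.
#' @return Data frame per candidate: `candidate`, `beta_without`, `beta_with`,
#'   `rel_change`, `decision` (`retained`/`dropped`/`indeterminate`); the
#'   retained set is in attribute `retained`.
#' @export
change_in_estimate_screen <- function(data, outcome, exposure, candidates,
                                      forced = character(0), threshold = 0.15,
                                      scale_per = 10) {
  base <- .fit_ols(data, outcome, exposure, forced, scale_per, 0.95)
  b0 <- base$beta[1]
  rows <- lapply(candidates, function(cand) {
    with_fit <- .fit_ols(data, outcome, exposure, c(forced, cand), scale_per,
                         0.95)
    b1 <- with_fit$beta[1]
    if (b0 == 0) {
      data.frame(candidate = cand, beta_without = b0, beta_with = b1,
                 rel_change = NA_real_, decision = "indeterminate",
                 stringsAsFactors = FALSE)
    } else {
      rc <- abs(b1 - b0) / abs(b0)
      data.frame(candidate = cand, beta_without = b0, beta_with = b1,
                 rel_change = rc,
                 decision = if (rc >= threshold) "retained" else "dropped",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "retained") <- out$candidate[out$decision == "retained"]
  out
}
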