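#' Construct a lag basis over the 52-week grid
#'
#' Builds the lag-dimension basis matrix `B` (weeks x df) of a distributed-lag
#' model. Three kinds are supported:
#' \describe{
#'   \item{`ns`}{natural cubic spline: a constant-in-lag column plus a natural
#'     cubic spline with `df - 1` columns, boundary knots at the grid extremes
#'     and interior knots at equally spaced quantiles of the lag range. The
#'     constant column is counted in `df`, so `df = 4` gives the conventional
#'     4-parameter smooth lag curve with linear tails beyond the boundaries.}
#'   \item{`poly`}{orthogonal polynomials of degree `df - 1` plus constant.}
#'   \item{`unconstrained`}{the identity: one free coefficient per week
#'     (`df` is forced to the number of lags), equivalent to a saturated
#'     per-week regression.}
#' }
#'
#' @param lags Integer lag grid (default 1:52).
#' @param df Degrees of freedom (columns of `B`), counting the constant.
#' @param kind `"ns"`, `"poly"` or `"unconstrained"`.
#' @param knots Optional interior knot locations (ns only), inside the lag
#'   range.
#' @return A list of class `lag_basis`: `lags`, `B` (length(lags) x df, full
#'   column rank), `df`, `kind`, `knots`, `boundary_knots`.
#' @export
lag_basis <- function(lags = 1:52, df = 4L, kind = c("ns", "poly",
                                                     "unconstrained"),
                      knots = NULL) {
  kind <- match.arg(kind)
  n <- length(lags)
  if (kind == "unconstrained") {
    B <- diag(n)
    df <- n
    knots <- numeric(0); bknots <- range(lags)
  } else if (kind == "poly") {
    stopifnot(df >= 2L, df < n)
    B <- cbind(1, stats::poly(lags, degree = df - 1L))
    knots <- numeric(0); bknots <- range(lags)
  } else {
    stopifnot(df >= 2L, df < n)
    bknots <- range(lags)
    if (is.null(knots)) {
      k <- df - 2L   # interior knots of an ns with df-1 columns
      knots <- if (k > 0L)
        stats::quantile(lags, probs = seq_len(k) / (k + 1L), names = FALSE)
      else numeric(0)
    }
    if (length(knots) > 0L && (any(knots <= bknots[1]) ||
                               any(knots >= bknots[2])))
      stop("interior knots must lie strictly inside the lag range")
    if (length(knots) != df - 2L)
      stop("df inconsistent with knot count: need df - 2 interior knots")
    B <- cbind(1, splines::ns(lags, knots = if (length(knots)) knots else NULL,
                              Boundary.knots = bknots))
  }
  B <- unname(as.matrix(B))
  if (qr(B)$rank < ncol(B)) stop("lag basis is rank deficient")
  structure(list(lags = lags, B = B, df = as.integer(df), kind = kind,
                 knots = knots, boundary_knots = bknots),
            class = "lag_basis")
}

#' Evaluate a natural-spline lag basis at arbitrary lag values
#'
#' Used to inspect tail behaviour (the natural spline is linear beyond its
#' boundary knots) and to interpolate lag curves off the integer grid.
#'
#' @param basis A [lag_basis()] of kind `"ns"` or `"poly"`.
#' @param at Numeric lag values.
#' @return Matrix length(at) x df.
#' @export
eval_lag_basis <- function(basis, at) {
  if (basis$kind == "ns") {
    cbind(1, splines::ns(at,
                         knots = if (length(basis$knots)) basis$knots else NULL,
                         Boundary.knots = basis$boundary_knots))
  } else if (basis$kind == "poly") {
    p <- stats::poly(basis$lags, degree = basis$df - 1L)
    cbind(1, stats::predict(p, at))
  } else {
    stop("unconstrained basis has no off-grid evaluation")
  }
}

#' Build the cross-basis design matrix
#'
#' Projects the subjects x weeks exposure matrix onto the lag basis:
#' `design = X B`, an n x df matrix whose OLS coefficients parameterise the
#' smooth lag curve.
#'
#' @param weekly Exposure matrix, subjects x length(basis$lags), complete.
#' @param basis A [lag_basis()].
#' @return Matrix n x df with columns `lagbasis1..lagbasisdf`.
#' @export
build_cross_basis <- function(weekly, basis) {
  weekly <- as.matrix(weekly)
  if (ncol(weekly) != nrow(basis$B))
    stop(sprintf("dimension mismatch: %d exposure weeks vs %d basis rows",
                 ncol(weekly), nrow(basis$B)))
  if (anyNA(weekly))
    stop("weekly exposures must be complete (apply the padding policy first)")
  D <- weekly %*% basis$B
  colnames(D) <- sprintf("lagbasis%d", seq_len(ncol(D)))
  D
}

#' Fit a distributed-lag model by OLS
#'
#' Regresses the acceleration outcome on `[cross-basis | covariates |
#' intercept]`. The cross-basis coefficient vector `theta` and its covariance
#' block `Sigma` are extracted for lag-curve construction; the Gaussian AIC
#' `n log(rss / n) + 2k` is recorded for basis comparison (k counts all mean
#' parameters).
#'
#' @param design Cross-basis matrix from [build_cross_basis()].
#' @param outcome Numeric outcome (acceleration, weeks).
#' @param covariates Optional data frame of covariates (factors allowed).
#' @return A list of class `crossbasis_fit`: `theta`, `Sigma`, `coef_all`,
#'   `n`, `rss`, `df_residual`, `aic`, `case_index`.
#' @export
fit_dlm <- function(design, outcome, covariates = NULL) {
  design <- as.matrix(design)
  n_all <- length(outcome)
  stopifnot(nrow(design) == n_all)
  if (is.null(covariates)) {
    Z <- matrix(1, n_all, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n_all)
    Z <- stats::model.matrix(~ ., data = covariates)
  }
  keep <- stats::complete.cases(cbind(design, Z, outcome))
  X <- cbind(design, Z)[keep, , drop = FALSE]
  y <- outcome[keep]
  n <- length(y)
  k <- ncol(X)
  if (n < k + 5L) stop("too few complete cases for the DLM design")
  qx <- qr(X)
  if (qx$rank < k) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):k]]
    stop(sprintf("singular DLM design; aliased: %s",
                 paste(aliased, collapse = ", ")))
  }
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  df_res <- n - k
  sigma2 <- rss / df_res
  V <- sigma2 * chol2inv(chol(crossprod(X)))
  dimnames(V) <- list(colnames(X), colnames(X))
  idx <- seq_len(ncol(design))
  structure(list(theta = beta[idx],
                 Sigma = V[idx, idx, drop = FALSE],
                 coef_all = beta, vcov_all = V,
                 n = n, rss = rss, df_residual = df_res,
                 aic = n * log(rss / n) + 2 * k,
                 case_index = which(keep)),
            class = "crossbasis_fit")
}

#' Lag-specific effects with delta-method confidence intervals
#'
#' Maps the fitted cross-basis coefficients back to per-week effects:
#' `beta_l = scale * B_l theta` with variance
#' `scale^2 * B_l Sigma B_l'`, pointwise normal 95% CIs, and the maximal
#' consecutive-week windows whose CI excludes zero.
#'
#' @param fit A `crossbasis_fit` from [fit_dlm()].
#' @param basis The [lag_basis()] used to build the design.
#' @param scale Report effects per this many concentration units (default 10).
#' @param conf_level Confidence level (default 0.95, normal quantile).
#' @return A list of class `lag_effect_curve`: `curve` (data frame week, beta,
#'   se, ci_low, ci_high, significant) and `windows` (data frame start, end).
#' @export
lag_effects <- function(fit, basis, scale = 10, conf_level = 0.95) {
  stopifnot(inherits(fit, "crossbasis_fit"),
            length(fit$theta) == ncol(basis$B))
  B <- basis$B
  beta <- scale * drop(B %*% fit$theta)
  se <- scale * sqrt(pmax(0, rowSums((B %*% fit$Sigma) * B)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- beta - z * se
  hi <- beta + z * se
  sig <- lo > 0 | hi < 0
  curve <- data.frame(week = basis$lags, beta = beta, se = se,
                      ci_low = lo, ci_high = hi, significant = sig)
  structure(list(curve = curve, windows = significant_windows(curve)),
            class = "lag_effect_curve")
}

#' Maximal significant windows of a lag curve
#'
#' Returns the maximal runs of consecutive weeks whose confidence interval
#' excludes zero, as disjoint ordered (start, end) spans.
#'
#' @param curve Data frame with columns `week` and `significant`.
#' @return Data frame with columns `start`, `end` (possibly zero rows).
#' @export
significant_windows <- function(curve) {
  sig <- curve$significant
  if (!any(sig)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = curve$week[starts[keep]], end = curve$week[ends[keep]])
}

#' Compare candidate lag bases by AIC
#'
#' Fits the same outcome/covariate data under each candidate basis on an
#' identical case set and ranks the fits by Gaussian AIC; ties go to the
#' smaller df.
#'
#' @param weekly Exposure matrix subjects x weeks.
#' @param outcome Acceleration outcome.
#' @param candidates List of [lag_basis()] objects (>= 2).
#' @param covariates Optional covariate data frame.
#' @return Data frame (kind, df, aic, rank) ordered as supplied, with the
#'   selected index in attribute `selected`.
#' @export
compare_bases <- function(weekly, outcome, candidates, covariates = NULL) {
  stopifnot(length(candidates) >= 2L)
  fits <- lapply(candidates, function(b)
    fit_dlm(build_cross_basis(weekly, b), outcome, covariates))
  cases <- lapply(fits, `[[`, "case_index")
  if (!all(vapply(cases, identical, logical(1), cases[[1]])))
    stop("candidates were fitted on differing case sets")
  tab <- data.frame(kind = vapply(candidates, `[[`, "", "kind"),
                    df = vapply(candidates, function(b) b$df, integer(1)),
                    aic = vapply(fits, `[[`, numeric(1), "aic"))
  ord <- order(tab$aic, tab$df)
  tab$rank <- match(seq_len(nrow(tab)), ord)
  attr(tab, "selected") <- ord[1]
  tab
}
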