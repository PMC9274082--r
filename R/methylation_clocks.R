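#' Define a linear epigenetic-clock model
#'
#' An epigenetic clock here is a linear predictor over CpG beta values:
#' `age = intercept + sum(coef_j * beta_j)`. Output units are explicit because
#' published cord-blood clocks differ (some predict gestational age in weeks,
#' others in days); [predict_epigenetic_age()] always returns weeks.
#'
#' @param name Clock name.
#' @param intercept Intercept, in `output_units`.
#' @param coefficients Named numeric vector, CpG id -> weight.
#' @param output_units `"weeks"` or `"days"`.
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(name, intercept, coefficients,
                        output_units = c("weeks", "days")) {
  output_units <- match.arg(output_units)
  stopifnot(length(coefficients) > 0, !is.null(names(coefficients)),
            !anyDuplicated(names(coefficients)))
  structure(list(name = name, intercept = intercept,
                 coefficients = coefficients, output_units = output_units,
                 n_cpgs = length(coefficients)),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %s: %d CpGs, intercept %.3f, units %s\n",
              x$name, x$n_cpgs, x$intercept, x$output_units))
  invisible(x)
}

#' Read a clock coefficient table
#'
#' Expects a CSV with columns `cpg_id` and `coefficient`; the intercept is the
#' row with the reserved id `(Intercept)`.
#'
#' @param path CSV file path.
#' @param name Clock name (defaults to the file name).
#' @param output_units `"weeks"` or `"days"`.
#' @return A [clock_model()].
#' @export
read_clock_csv <- function(path, name = basename(path),
                           output_units = c("weeks", "days")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cpg_id", "coefficient") %in% names(tab)))
  ic <- tab$cpg_id == "(Intercept)"
  if (sum(ic) != 1L) stop("clock table needs exactly one (Intercept) row")
  coefs <- stats::setNames(tab$coefficient[!ic], tab$cpg_id[!ic])
  clock_model(name, tab$coefficient[ic], coefs, match.arg(output_units))
}

#' Load a bundled cord-blood clock
#'
#' The package ships synthetic stand-in coefficient tables for the two
#' cord-blood gestational-age clocks it targets: a 148-CpG clock reported in
#' weeks ("knight") and a 96-CpG clock reported in days ("bohlin"). The tables
#' reproduce the published clocks' dimensions and unit conventions but their
#' coefficient values are simulated (see the files' provenance headers);
#' they drive the generator and pipeline, not biological inference.
#'
#' @param which `"knight"` or `"bohlin"`.
#' @return A [clock_model()].
#' @export
load_bundled_clock <- function(which = c("knight", "bohlin")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0(which, "_clock_synthetic.csv"),
                      package = "prenatalDLM", mustWork = TRUE)
  read_clock_csv(path, name = which,
                 output_units = if (which == "bohlin") "days" else "weeks")
}

.check_beta_matrix <- function(betas) {
  stopifnot(is.matrix(betas), !is.null(rownames(betas)),
            !is.null(colnames(betas)))
  rng <- range(betas, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("beta values must lie in [0, 1]")
  invisible(betas)
}

#' Calibrate a beta matrix to a gold-standard distribution
#'
#' Per-sample monotone quantile mapping of each sample's beta distribution
#' onto a fixed reference ("gold standard") distribution, the between-sample
#' normalisation contract of gold-standard beta-mixture calibration: after
#' mapping, every sample's empirical distribution matches the reference while
#' within-sample rank order is preserved. Values stay in [0, 1] because the
#' reference lies in [0, 1].
#'
#' @param betas Samples x CpGs matrix in \[0, 1\] with dimnames.
#' @param gold_standard Named numeric vector: reference beta per CpG (a mean
#'   across training arrays, typically). Only CpGs shared with `betas` are
#'   used; at least 10 must be shared.
#' @return Calibrated matrix, same shape and dimnames as `betas`.
#' @export
calibrate_to_gold_standard <- function(betas, gold_standard) {
  .check_beta_matrix(betas)
  shared <- intersect(colnames(betas), names(gold_standard))
  if (length(shared) < 10L)
    stop("fewer than 10 CpGs shared with the gold standard")
  ref <- sort(as.numeric(gold_standard[shared]))
  out <- betas
  for (i in seq_len(nrow(betas))) {
    x <- betas[i, ]
    # ranks -> reference quantiles (inverse-ECDF lookup, so a sample whose
    # distribution already equals the gold standard maps to itself exactly);
    # ties share their average quantile
    q <- (rank(x, ties.method = "average") - 0.5) / length(x)
    out[i, ] <- stats::quantile(ref, probs = q, type = 1, names = FALSE)
  }
  out
}

#' Impute missing clock CpGs by simple random sampling
#'
#' Any clock CpG absent from the beta matrix is added as a new column filled,
#' per sample, by sampling with replacement from that CpG's reference
#' (gold-standard training) distribution. Deterministic under a fixed seed.
#'
#' @param betas Samples x CpGs matrix.
#' @param clock A [clock_model()].
#' @param reference_betas Named list or matrix giving, per CpG, the reference
#'   distribution to sample from (a numeric vector per CpG; a matrix is read
#'   as CpG columns).
#' @param seed Integer seed.
#' @return List with `betas` (augmented matrix) and `imputed` (character
#'   vector of imputed CpG ids).
#' @export
impute_missing_clock_cpgs <- function(betas, clock, reference_betas, seed = 1L) {
  .check_beta_matrix(betas)
  missing_cpgs <- setdiff(names(clock$coefficients), colnames(betas))
  if (length(missing_cpgs) == 0L)
    return(list(betas = betas, imputed = character(0)))
  get_ref <- function(cpg) {
    v <- if (is.matrix(reference_betas)) reference_betas[, cpg]
         else reference_betas[[cpg]]
    v[!is.na(v)]
  }
  avail <- if (is.matrix(reference_betas)) colnames(reference_betas)
           else names(reference_betas)
  absent <- setdiff(missing_cpgs, avail)
  if (length(absent) > 0L)
    stop(sprintf("clock CpG(s) absent from the reference too: %s",
                 paste(absent, collapse = ", ")))
  set.seed(seed)
  add <- vapply(missing_cpgs, function(cpg) {
    sample(get_ref(cpg), size = nrow(betas), replace = TRUE)
  }, numeric(nrow(betas)))
  out <- cbind(betas, matrix(add, nrow = nrow(betas),
                             dimnames = list(rownames(betas), missing_cpgs)))
  list(betas = out, imputed = missing_cpgs)
}

#' Predict epigenetic gestational age
#'
#' Evaluates the clock's linear predictor per sample and converts to weeks
#' (clocks declared in days are divided by 7). All clock CpGs must be present;
#' use [impute_missing_clock_cpgs()] first -- imputation is explicit, never
#' silent.
#'
#' @param betas Samples x CpGs matrix.
#' @param clock A [clock_model()].
#' @return Named numeric vector of epigenetic ages in weeks.
#' @export
predict_epigenetic_age <- function(betas, clock) {
  .check_beta_matrix(betas)
  need <- names(clock$coefficients)
  miss <- setdiff(need, colnames(betas))
  if (length(miss) > 0L)
    stop(sprintf("missing clock CpG(s): %s%s",
                 paste(utils::head(miss, 5), collapse = ", "),
                 if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5)
                 else ""))
  age <- clock$intercept +
    drop(betas[, need, drop = FALSE] %*% clock$coefficients)
  if (clock$output_units == "days") age <- age / 7
  stats::setNames(age, rownames(betas))
}

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves `min || A x - b ||^2` subject to `x >= 0`.
#'
#' @param A Design matrix.
#' @param b Response vector.
#' @param tol Dual-feasibility tolerance.
#' @return Numeric solution vector.
#' @keywords internal
nnls_fit <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- rep(0, n)
  passive <- rep(FALSE, n)
  w <- drop(crossprod(A, b))                     # gradient at x = 0
  iter_max <- 3L * n
  for (iter in seq_len(iter_max * 10L)) {
    if (all(passive) || max(w[!passive]) <= tol * max(1, max(abs(w)))) break
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- rep(0, n)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- drop(qr.coef(qr(Ap), b))
      s[passive][is.na(s[passive])] <- 0
      if (all(s[passive] > tol)) { x <- s; break }
      neg <- passive & (s <= tol)
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & (x > tol)
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Estimate cell-type proportions by constrained projection
#'
#' Reference-based deconvolution of bulk cord-blood methylation: per sample,
#' minimises `|| beta - R p ||^2` over `p >= 0`, where `R` is the CpG x
#' cell-type reference profile matrix (7 cord-blood cell types: B cells,
#' CD4+/CD8+ T cells, monocytes, granulocytes, nucleated RBCs, NK cells). By
#' default the solution is renormalised to sum to 1.
#'
#' @param betas Samples x CpGs matrix.
#' @param reference CpG x cell-type matrix in \[0, 1\] with dimnames; at least
#'   as many shared CpGs as cell types, and full column rank on them.
#' @param renormalize Rescale each solution to sum to 1 (default TRUE).
#' @return Samples x cell-types matrix of proportions.
#' @export
estimate_cell_proportions <- function(betas, reference, renormalize = TRUE) {
  .check_beta_matrix(betas)
  stopifnot(is.matrix(reference), !is.null(rownames(reference)))
  shared <- intersect(colnames(betas), rownames(reference))
  k <- ncol(reference)
  if (length(shared) < k)
    stop("need at least as many shared reference CpGs as cell types")
  R <- reference[shared, , drop = FALSE]
  if (qr(R)$rank < k)
    stop("reference profiles are rank-deficient on the shared CpGs")
  B <- betas[, shared, drop = FALSE]
  # unconstrained solve for all samples at once; by the KKT conditions it is
  # the NNLS solution whenever it is already nonnegative, so the active-set
  # solver only runs on the samples that actually hit the boundary
  P <- t(qr.coef(qr(R), t(B)))
  bdry <- which(apply(P, 1, function(p) any(p < 0)))
  for (i in bdry) P[i, ] <- nnls_fit(R, B[i, ])
  colnames(P) <- colnames(reference)
  if (renormalize) {
    tot <- rowSums(P)
    bad <- tot <= 0
    P[!bad, ] <- P[!bad, , drop = FALSE] / tot[!bad]
    if (any(bad)) P[bad, ] <- NA_real_
  }
  P
}

#' Residual epigenetic age acceleration
#'
#' Age acceleration is the residual from an ordinary least squares regression
#' of epigenetic age on chronological gestational age, adjusting for cell-type
#' proportions. When proportions sum to one, one cell type (by default the
#' most abundant, granulocytes) is dropped to avoid exact collinearity with
#' the intercept. Residuals have mean zero and are orthogonal to every
#' regressor; positive values mean epigenetically older than expected.
#'
#' @param epigenetic_age Numeric vector, weeks.
#' @param gestational_age Numeric vector, weeks.
#' @param cell_proportions Samples x cell-types matrix; may be NULL to skip
#'   cell adjustment.
#' @param drop_cell Column to drop when proportions are compositional;
#'   defaults to the cell type with the largest mean. Use NA to keep all.
#' @return Data frame: `subject`, `epigenetic_age`, `gestational_age`,
#'   `acceleration` (weeks), plus the cell-proportion columns used.
#' @export
compute_age_acceleration <- function(epigenetic_age, gestational_age,
                                     cell_proportions = NULL,
                                     drop_cell = NULL) {
  n <- length(epigenetic_age)
  stopifnot(length(gestational_age) == n, n >= 10L,
            !anyNA(epigenetic_age), !anyNA(gestational_age))
  X <- data.frame(gestational_age = gestational_age)
  if (!is.null(cell_proportions)) {
    cp <- as.matrix(cell_proportions)
    stopifnot(nrow(cp) == n, !anyNA(cp))
    compositional <- all(abs(rowSums(cp) - 1) < 1e-6)
    if (is.null(drop_cell) && compositional)
      drop_cell <- colnames(cp)[which.max(colMeans(cp))]
    if (!is.null(drop_cell) && !is.na(drop_cell))
      cp <- cp[, setdiff(colnames(cp), drop_cell), drop = FALSE]
    X <- cbind(X, as.data.frame(cp))
  }
  fit <- stats::lm(epigenetic_age ~ ., data = X)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("collinear acceleration design; aliased: %s",
                 paste(bad, collapse = ", ")))
  }
  subj <- names(epigenetic_age)
  if (is.null(subj)) subj <- as.character(seq_len(n))
  out <- data.frame(subject = subj,
                    epigenetic_age = as.numeric(epigenetic_age),
                    gestational_age = gestational_age,
                    acceleration = as.numeric(stats::resid(fit)),
                    stringsAsFactors = FALSE)
  if (!is.null(cell_proportions))
    out <- cbind(out, as.data.frame(as.matrix(cell_proportions)))
  out
}
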