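rand_betas <- function(n, cpgs, seed = 1) {
  set.seed(seed)
  matrix(runif(n * length(cpgs)), n,
         dimnames = list(sprintf("smp%02d", seq_len(n)), cpgs))
}

test_that("bundled clock tables have the expected shape and units", {
  kn <- load_bundled_clock("knight")
  bo <- load_bundled_clock("bohlin")
  expect_s3_class(kn, "clock_model")
  expect_identical(kn$n_cpgs, 148L)
  expect_identical(bo$n_cpgs, 96L)
  expect_identical(kn$output_units, "weeks")
  expect_identical(bo$output_units, "days")
  expect_error(clock_model("empty", 0, numeric(0)))
})

test_that("gold-standard calibration is an identity on matching distributions", {
  set.seed(21)
  cpgs <- sprintf("cg%03d", 1:60)
  gs <- setNames(runif(60), cpgs)
  # sample whose values are exactly the gold-standard multiset
  b <- matrix(sample(gs), 1, dimnames = list("s1", cpgs))
  out <- calibrate_to_gold_standard(b, gs)
  expect_equal(out, b, tolerance = 1e-12)
  # fewer than 10 shared CpGs is an error
  expect_error(calibrate_to_gold_standard(b, gs[1:5]), "10")
})

test_that("calibration maps shifted samples onto gold-standard quantiles", {
  set.seed(22)
  cpgs <- sprintf("cg%03d", 1:200)
  gs <- setNames(sort(runif(200, 0.05, 0.85)), cpgs)
  shifted <- gs + 0.1; shifted[shifted > 1] <- 1
  b <- rbind(s1 = shifted[cpgs])
  colnames(b) <- cpgs
  out <- calibrate_to_gold_standard(b, gs)
  # empirical-CDF oracle: sorted output equals sorted gold standard
  expect_equal(sort(out[1, ]), sort(unname(gs)), ignore_attr = TRUE,
               tolerance = 1e-12)
  # rank order within the sample is preserved
  expect_identical(rank(out[1, ]), rank(b[1, ]))
  expect_equal(cor(out[1, ], b[1, ], method = "spearman"), 1)
  # degenerate constant sample maps to the gold-standard median
  bc <- matrix(0.5, 1, 201, dimnames = list("s1", c(cpgs, "cg999")))
  outc <- calibrate_to_gold_standard(bc, gs)
  expect_equal(unique(as.numeric(outc)), quantile(gs, 0.5, type = 1,
                                                  names = FALSE))
})

test_that("calibration preserves within-sample rank order on random samples", {
  set.seed(23)
  cpgs <- sprintf("cg%03d", 1:150)
  gs <- setNames(rbeta(150, 0.5, 0.5), cpgs)
  b <- rand_betas(8, cpgs, seed = 23)
  out <- calibrate_to_gold_standard(b, gs)
  expect_true(all(out >= 0 & out <= 1))
  for (i in 1:8)
    expect_equal(cor(out[i, ], b[i, ], method = "spearman"), 1)
})

test_that("missing clock CpGs are imputed from the reference, deterministically", {
  clk <- tiny_clock()
  full <- rand_betas(12, names(clk$coefficients), seed = 24)
  # nothing missing: input returned unchanged
  same <- impute_missing_clock_cpgs(full, clk, full, seed = 1)
  expect_identical(same$betas, full)
  expect_length(same$imputed, 0)
  # drop 2 of 5 clock CpGs; reference provides their distributions
  part <- full[, c("cgA", "cgC", "cgE")]
  imp <- impute_missing_clock_cpgs(part, clk, full, seed = 5)
  expect_setequal(imp$imputed, c("cgB", "cgD"))
  expect_identical(dim(imp$betas), c(12L, 5L))
  for (cpg in imp$imputed)
    expect_true(all(imp$betas[, cpg] %in% full[, cpg]))
  # determinism under a fixed seed
  imp2 <- impute_missing_clock_cpgs(part, clk, full, seed = 5)
  expect_identical(imp$betas, imp2$betas)
  # CpG absent from the reference is a named error
  expect_error(impute_missing_clock_cpgs(part, clk,
                                         full[, c("cgA", "cgB", "cgC")],
                                         seed = 1), "cgD")
})

test_that("clock prediction is the linear predictor, converted to weeks", {
  one <- clock_model("one", intercept = 30, coefficients = c(cgX = 10))
  b <- matrix(0.5, 1, 1, dimnames = list("s", "cgX"))
  expect_equal(unname(predict_epigenetic_age(b, one)), 35)
  # all betas zero -> intercept, with day-to-week conversion
  oned <- clock_model("oned", intercept = 273, coefficients = c(cgX = 10),
                      output_units = "days")
  b0 <- matrix(0, 1, 1, dimnames = list("s", "cgX"))
  expect_equal(unname(predict_epigenetic_age(b0, oned)), 39)
  # linearity: convex mixtures of beta rows mix the predictions
  clk <- tiny_clock()
  b <- rand_betas(2, names(clk$coefficients), seed = 25)
  lam <- 0.3
  mixed <- rbind(mix = lam * b[1, ] + (1 - lam) * b[2, ])
  p <- predict_epigenetic_age(rbind(b, mixed), clk)
  expect_equal(unname(p[3]), lam * p[[1]] + (1 - lam) * p[[2]],
               tolerance = 1e-12)
  # brute-force dot product oracle
  expect_equal(unname(p[1]),
               clk$intercept + sum(clk$coefficients * b[1, ]))
  # missing clock CpGs are a named error, never silently imputed
  expect_error(predict_epigenetic_age(b[, -2, drop = FALSE], clk), "cgB")
})

test_that("NNLS matches the quadratic-programming oracle", {
  set.seed(26)
  for (i in 1:40) {
    m <- sample(8:20, 1); k <- sample(2:6, 1)
    A <- matrix(runif(m * k), m)
    b <- runif(m)
    ours <- nnls_fit(A, b)
    oracle <- pracma::lsqnonneg(A, b)$x
    expect_equal(ours, oracle, tolerance = 1e-8, ignore_attr = TRUE)
    expect_true(all(ours >= 0))
  }
})

test_that("deconvolution recovers pure samples and noiseless mixtures", {
  ref <- tiny_reference(m = 60)
  # pure type k -> indicator vector
  pure <- t(ref)
  rownames(pure) <- colnames(ref)
  P <- estimate_cell_proportions(pure, ref)
  expect_equal(unname(P), diag(7), tolerance = 1e-8)
  # 0.3 / 0.7 two-profile mixture
  mix <- rbind(m1 = 0.3 * ref[, 1] + 0.7 * ref[, 2])
  P <- estimate_cell_proportions(mix, ref)
  expect_equal(unname(P[1, ]), c(0.3, 0.7, 0, 0, 0, 0, 0), tolerance = 1e-6)
  # mean of all profiles -> uniform (verified against the constrained oracle)
  avg <- rbind(m = rowMeans(ref))
  P <- estimate_cell_proportions(avg, ref)
  oracle <- pracma::lsqnonneg(ref, rowMeans(ref))$x
  expect_equal(unname(P[1, ]), oracle / sum(oracle), tolerance = 1e-6)
  expect_equal(unname(P[1, ]), rep(1 / 7, 7), tolerance = 1e-6)
  # rank-deficient reference errors
  bad <- ref; bad[, 2] <- bad[, 1]
  expect_error(estimate_cell_proportions(mix, bad), "rank")
})

test_that("deconvolution recovers random mixtures, noiselessly and under noise", {
  set.seed(27)
  ref <- tiny_reference(m = 120)
  n <- 60
  g <- matrix(rgamma(n * 7, shape = 1), n)
  truth <- g / rowSums(g)
  clean <- truth %*% t(ref)
  dimnames(clean) <- list(sprintf("s%02d", 1:n), rownames(ref))
  P <- estimate_cell_proportions(clean, ref)
  expect_lt(max(abs(P - truth)), 1e-6)
  noisy <- clean + rnorm(length(clean), 0, 0.01)
  noisy[] <- pmin(1, pmax(0, noisy))
  Pn <- estimate_cell_proportions(noisy, ref)
  expect_lt(sqrt(mean((Pn - truth)^2)), 0.03)
})

test_that("age acceleration is the cell-adjusted OLS residual", {
  set.seed(28)
  n <- 60
  ga <- rnorm(n, 39.1, 1.3)
  cp <- matrix(rgamma(n * 7, 2), n); cp <- cp / rowSums(cp)
  colnames(cp) <- colnames(tiny_reference())
  # epigenetic age identical to GA, constant cell proportions: all residuals 0
  cpc <- matrix(rep(c(0.1, 0.1, 0.1, 0.1, 0.4, 0.1, 0.1), each = n), n)
  colnames(cpc) <- colnames(cp)
  acc <- compute_age_acceleration(ga, ga, NULL)
  expect_equal(acc$acceleration, rep(0, n), tolerance = 1e-10)
  # balanced +/-1 design: residuals exactly +/-1 (closed-form OLS)
  ga2 <- rep(ga[1:30], 2)
  epi <- ga2 + rep(c(1, -1), each = 30)
  acc2 <- compute_age_acceleration(epi, ga2, NULL)
  expect_equal(acc2$acceleration, rep(c(1, -1), each = 30),
               tolerance = 1e-10)
  # residual properties: mean zero, orthogonal to GA and cell proportions
  epi3 <- ga + rnorm(n, 0, 1.5)
  acc3 <- compute_age_acceleration(epi3, ga, cp)
  expect_equal(mean(acc3$acceleration), 0, tolerance = 1e-10)
  expect_lt(abs(cor(acc3$acceleration, ga)), 1e-8)
  for (j in 1:6)  # the dropped column is recovered by the others
    expect_lt(abs(sum(acc3$acceleration * cp[, j])), 1e-8)
  # invariance to a constant shift of epigenetic age
  acc4 <- compute_age_acceleration(epi3 + 5, ga, cp)
  expect_equal(acc4$acceleration, acc3$acceleration, tolerance = 1e-10)
  # collinear design errors with the offending column named
  cpbad <- cp; cpbad[, 2] <- 2 * cp[, 1]
  expect_error(compute_age_acceleration(epi3, ga, cbind(cpbad, dup = cpbad[, 1] * 3)),
               "collinear|aliased")
})
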