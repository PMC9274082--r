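---
title: "Methods: prenatal exposure windows and epigenetic gestational-age acceleration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prenatal exposure windows and epigenetic gestational-age acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prenatalDLM)
```

# The analysis this package implements

Cord-blood DNA methylation can be summarised by *epigenetic gestational-age
clocks*: linear predictors over CpG beta values whose output approximates
gestational age at birth. The residual of epigenetic age regressed on
chronological gestational age — after adjusting for cell composition — is
*epigenetic age acceleration*: positive values mean the newborn's methylome
looks older than its gestational age, negative values younger. prenatalDLM
implements the full chain used to ask whether prenatal ambient air pollution
(NO~2~, O~3~, PM~2.5~, PM~10~) shifts this residual, and in which weeks of
the preconception-plus-pregnancy window the methylome is most vulnerable.

The chain has five stages, each an exported module:

1. **Exposure assignment.** Weekly pollutant concentrations at maternal
   residences are interpolated from monitor stations by inverse
   distance-squared weighting (IDW2): the up-to-four closest stations within
   50 km are used, except that when any station lies within 5 km only the
   stations within 5 km are used. Weekly values are laid out on a 52-week
   grid — weeks 1–13 are the 13 preconception weeks, weeks 14–52 gestational
   weeks 1–39 — and averaged into preconception, trimester and whole-pregnancy
   windows.
2. **Clocks.** Beta matrices are calibrated to a gold-standard distribution,
   missing clock CpGs imputed by simple random sampling from the reference
   distribution, epigenetic age computed as `intercept + sum(coef * beta)`,
   and cell proportions estimated by constrained projection onto a 7-cell-type
   cord-blood reference (non-negative least squares, renormalised to sum
   to 1).
3. **Acceleration.** OLS residual of epigenetic age on gestational age plus
   cell proportions.
4. **Period models.** Linear models of acceleration on period-average
   exposures, reported in weeks per 10 concentration units with t-based 95%
   CIs; individual models per period, mutually adjusted models across
   periods, and a 15% change-in-estimate confounder screen.
5. **Distributed-lag models.** All 52 weekly exposures enter one model
   through a lag-dimension basis: the design is `X B` where `X` is the
   subjects-by-52 exposure matrix and `B` a 52-by-df basis. Lag-specific
   effects are `beta_l = scale * B_l theta` with delta-method variances
   `scale^2 * B_l Sigma B_l'`, pointwise normal CIs, and significant exposure
   windows reported as maximal runs of weeks whose CI excludes zero.

# The synthetic-cohort generator

The real cohorts this design targets are access-restricted, so the package
ships a fully seeded generator whose defaults reproduce the published
study conditions: two recruitment regions (East/West, sampled 21.4%/78.6%),
gestational age truncated-normal with mean 39.1 and SD 1.3 weeks (support
[30, 43]), pooled pollutant levels 11.1 ppb NO~2~, 25.7 ppb O~3~, 9.8 µg/m³
PM~2.5~, 18.8 µg/m³ PM~10~ with the matching SDs, covariate frequencies
matching the pooled descriptive table, and mean cell proportions matching the
reported cord-blood composition (stored as fractions; percentage versus
fraction scaling is irrelevant to residuals in a model with an intercept).

Choices the study conditions do not pin down were fixed once, on
plausibility:

* **Weekly field structure.** Station series are regional mean × a regional
  level factor (1.12 East / 0.96 West, reflecting the reported East–West
  contrast), plus a seasonal sinusoid with amplitude 0.3 × mean — ozone
  peaking in summer, NO~2~ in winter, so their seasonal phases oppose — plus
  AR(1) noise with lag-1 correlation 0.7 and stationary SD equal to the
  configured pollutant SD, truncated at zero.
* **Geography.** Each region is a metropolitan-scale bounding box
  (0.8° ≈ 70–90 km across) holding 8 stations per pollutant; residences fall
  in the same boxes. Residences near a box corner can legitimately be beyond
  50 km of every station; such subject-weeks are flagged `missing` and the
  affected subjects drop out of exposure models by listwise deletion, which
  is why the per-period Ns vary, as in the original design.
* **Mobility.** 10% of subjects move once during the window (the source
  design records residential history but not a mobility rate; this is a free
  parameter).
* **Cell proportions.** Dirichlet with concentration 50 around the published
  mean composition — SDs of the right order without matching any specific
  cell type exactly.
* **Planted lag effect.** A Gaussian bump `amplitude * exp(-((l - 20.5) /
  4.25)^2 / 2)` with amplitude −0.03 weeks per unit: 2 SDs span weeks 12–29,
  the window highlighted by the motivating analysis.

Methylation matrices are constructed to *invert* the clock exactly: clock-CpG
betas are `0.5 + delta_i * coef_j`, the minimum-norm adjustment along the
coefficient direction solving `intercept + sum(coef * beta) = target age`,
with an error naming the first subject whose target is unreachable inside
[0, 1]. Non-clock CpGs are convex mixtures of the cell reference under the
true proportions. Gaussian beta-scale noise (default SD 0.005) is added and
clipped to [0, 1], with the clip count reported.

What the generator does **not** emulate: real AQS spatial covariance and
terrain, probe chemistry and batch artifacts, genuine biological covariance
between methylation and covariates, and any outcome pathway other than the
planted one. Passing recovery tests therefore demonstrates that the
*estimation machinery* is correct and calibrated under the stated data model,
not that the epidemiological findings replicate.

## Bundled clock tables

The two bundled coefficient tables reproduce the published cord-blood
clocks' dimensions and unit conventions — 148 CpG terms in weeks, 96 CpG
terms in days (converted to weeks at prediction time) — but are synthetic
stand-ins: coefficient magnitudes are bounded draws chosen so every
gestational-age target in [30, 43] weeks is reachable with betas in [0, 1].
They are labelled synthetic in their filenames and must be replaced by the
published tables (via `read_clock_csv()`) for real-data work.

# Numerical and design choices

* **Distances.** One haversine (R = 6371 km) is the single source of truth
  for generator and assignment; thresholds are inclusive (`d <= 5`,
  `d <= 50`). Stations closer than 0.001 km are treated as collocated and
  averaged, avoiding the 1/d² blow-up below geocoding precision.
* **5 km override cap.** Whether the up-to-four cap binds inside 5 km is not
  documented in the motivating design; both behaviours are implemented
  (`cap_near`), default capped.
* **Calendar.** Each subject's grid week maps to the station calendar week
  containing its midpoint (start + 3 days). A week spanning a move is the
  duration-weighted blend of the two residences' interpolations.
* **Early births.** Grid weeks after the last completed gestational week are
  padded with the subject's observed trimester-3 mean and flagged; period
  means use only observed weeks. Trimester boundaries default to whole
  gestational weeks (1–13 / 14–26 / 27–birth); the day-count definitions
  (1–90 / 91–180 / 181–birth) are available via `boundaries = "daily"`,
  which weights the boundary weeks fractionally.
* **Calibration.** "Gold-standard" calibration is implemented as per-sample
  monotone quantile mapping onto the reference distribution (inverse-ECDF
  lookup), which preserves within-sample ranks exactly and is the identity
  when the sample already matches the reference. This captures the
  between-sample normalisation contract of gold-standard beta-mixture
  calibration in an exactly testable form.
* **Imputation.** "Simple random sampling" imputation is read as sampling
  with replacement from the missing CpG's reference distribution,
  deterministic under a fixed seed — an interpretation, documented as such.
* **Deconvolution.** The active-set (Lawson–Hanson) NNLS solver is written
  in-package; a vectorised unconstrained solve handles the samples whose
  solution is already interior (by the KKT conditions it equals the NNLS
  solution there), with the active-set iteration only for boundary cases.
  Renormalisation to sum to 1 is on by default; in the acceleration
  regression one compositional column (the most abundant, granulocytes) is
  dropped to avoid collinearity with the intercept.
* **Period models.** Classical SEs and t-based CIs (at n ≈ 332 these are
  indistinguishable from 1.96·SE); listwise deletion with `n_used` reported;
  exposure coefficients multiplied by `scale_per` (default 10). The
  change-in-estimate screen is one-candidate-at-a-time against the core
  model, candidates evaluated in declared order; a zero core coefficient
  flags the candidate `indeterminate` rather than retaining it silently.
  "Region" enters as the two-level East/West factor by default.
* **Lag basis.** `df` counts a constant-in-lag column plus a natural cubic
  spline with `df − 1` columns, boundary knots at weeks 1 and 52 and interior
  knots at equally spaced quantiles. The constant column lets a uniform lag
  effect be represented; the convention is explicit so SEs are reproducible
  under either reading of "4 df". Polynomial and unconstrained (saturated)
  alternatives share the interface; AIC is Gaussian,
  `n log(rss/n) + 2k`, with ties broken toward smaller df.
* **Recovery-study df.** The DLM recovery study (`dlm_recovery_study()`)
  fits a 12-df spline: projecting the default bump onto 12 df leaves a
  maximum approximation error below 5·10⁻⁴ weeks per unit, an order of
  magnitude under the sampling SE at n = 1500, so pointwise CI coverage
  measures estimator calibration rather than basis misspecification. The
  pipeline's reporting default remains 4 df, the parsimonious choice for
  real cohort sizes.
* **Problem sizes.** The validation studies default to 200 replicates at
  n = 1500 (lag recovery) and 100 replicates at n = 332 (end-to-end period
  recovery) — large enough for the binomial tolerances they are judged
  against, small enough to run routinely.
* **Seeding.** All generator entry points take explicit seeds;
  `run_pipeline()` expands one global seed into fixed per-stage substreams,
  so identical config + seed gives byte-identical outputs.

# Limitations

IDW2 with a four-station cap is the only interpolator (no kriging or
land-use regression); the DLM is linear in exposure with pointwise (not
simultaneous) CIs and no penalisation; no multiple-testing correction is
applied, matching the motivating analysis; raw array processing (IDAT,
detection p-values, probe filtering) is out of scope — inputs are assumed to
be clean beta matrices.
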