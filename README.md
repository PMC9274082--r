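# prenatalDLM

Tools for studying whether prenatal ambient air pollution shifts the
**epigenetic gestational age** of newborns — and in *which weeks* of
pregnancy the methylome is vulnerable.

Cord-blood DNA methylation supports linear "clock" predictors of gestational
age, `age = b0 + Σ b_j β_j` over CpG beta values. The residual of predicted
epigenetic age regressed on chronological gestational age, adjusted for
cord-blood cell composition, is **epigenetic age acceleration** (weeks;
positive = older-looking methylome). prenatalDLM implements the full analysis
chain for relating that residual to prenatal pollutant exposure:

* **Exposure assignment** — weekly NO₂/O₃/PM₂.₅/PM₁₀ concentrations at
  maternal residences, interpolated from monitor stations by inverse
  distance-squared weighting (IDW2) using the up-to-four closest stations
  within 50 km (stations within 5 km override the wider set), on a 52-week
  grid: weeks 1–13 preconception, weeks 14–52 pregnancy. Period averages for
  preconception, trimesters 1–3 and whole pregnancy.
* **Clocks and acceleration** — gold-standard quantile calibration of beta
  matrices, random-sampling imputation of missing clock CpGs, linear clock
  prediction (weeks or days, converted), 7-cell-type reference-based
  deconvolution by non-negative least squares, and cell-adjusted OLS
  residualisation.
* **Period models** — acceleration on period-average exposure plus
  covariates, reported in weeks per 10 concentration units with t-based 95%
  CIs; individual and mutually adjusted period models; 15% change-in-estimate
  confounder screening.
* **Distributed-lag models (DLMs)** — all 52 weekly exposures in one model
  through a natural-cubic-spline lag basis (default 4 df; polynomial and
  saturated alternatives, AIC comparison). Week-specific effects
  `β_l = 10 · B_l θ` with delta-method pointwise 95% CIs and maximal
  significant exposure windows.
* **Synthetic cohorts** — a fully seeded generator (monitor networks with
  seasonal + AR(1) weekly fields, residence histories with movers,
  covariates, beta matrices that encode chosen target ages exactly, planted
  period- or lag-effects) so the whole chain is testable without restricted
  cohort data.

The bundled clock coefficient tables are *synthetic stand-ins* that match the
published cord-blood clocks' dimensions (148 CpGs in weeks; 96 CpGs in days);
supply real published tables via `read_clock_csv()` for real-data work.

## Worked example

```r
library(prenatalDLM)

cfg <- run_config(synth = list(n_subjects = 332), pollutants = "PM2.5",
                  clocks = "knight", seed = 20)
res <- run_pipeline(cfg)

subset(res$period_results, model_type == "individual",
       select = c(period, beta, se, ci_low, ci_high, p_value, n_used))
#>         period   beta    se ci_low ci_high  p_value n_used
#>  preconception  0.509 0.333 -0.147   1.165 1.28e-01    332
#>     trimester1 -3.329 0.276 -3.873  -2.785 8.15e-28    332
#>     trimester2 -0.414 0.317 -1.038   0.210 1.93e-01    332
#>     trimester3  3.102 0.289  2.534   3.670 3.32e-23    332
#>      pregnancy -1.720 0.761 -3.216  -0.224 2.44e-02    332
```

The generator plants a smooth negative lag effect (peak −0.03 weeks of
acceleration per µg/m³) on weeks 12–29 of the 52-week grid — late
preconception through gestational week 16. The period models see it as
strong deceleration for trimester 1, but the mirrored *positive* trimester-3
coefficient is an artifact of seasonality: T1 and T3 means sit half a
seasonal cycle apart and are anti-correlated, which is exactly why mutually
adjusted models and DLMs are needed. The DLM resolves the timing:

```r
res$windows[["knight.PM2.5"]]
#>  start end
#>     10  30
#>     42  44

res$lag_curves[res$lag_curves$week %in% 18:21,
               c("week", "beta", "ci_low", "ci_high", "significant")]
#>  week   beta ci_low ci_high significant
#>    18 -0.163 -0.230 -0.0948        TRUE
#>    19 -0.164 -0.231 -0.0966        TRUE
#>    20 -0.162 -0.228 -0.0969        TRUE
#>    21 -0.158 -0.221 -0.0957        TRUE
```

The detected window (weeks 10–30) brackets the planted weeks 12–29; the
4-df spline attenuates the peak (−0.16 per 10 µg/m³ against a planted
−0.3) — the price of a parsimonious lag basis — and the short second
window is the kind of pointwise-CI false positive the vignette discusses.
`res$manifest` records seeds, sizes and per-stage subject counts;
`run_pipeline(cfg, outdir = "out")` writes all tables as CSV/JSON.

A thin CLI over the same functions ships at `inst/cli/prenatalDLM.R`
(subcommands `synth`, `assign`, `clock`, `fit`, `dlm`, `run`). The methods
vignette (`vignettes/prenatal-windows.Rmd`) documents the model, the
generator's assumptions and every numerical choice.

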