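# troutgrowth

Tools for asking how supplementation stocking reshapes the growth and body
condition of Lake Trout (*Salvelinus namaycush*) populations when the
hatchery source and the recipient lake carry contrasting ecotypes — a
large, fast-growing piscivorous form stocked into lakes that hold either
piscivorous or small, slow-growing planktivorous populations. The package
is aimed at fisheries scientists and quantitative ecologists who combine
otolith growth histories with individual admixture proportions from a
population-genomic assignment analysis.

## What it computes

- **Genetic origin classification.** Each fish in a stocked lake carries an
  admixture proportion attributed to the stocking source(s),
  `Q_source`, with a bootstrap SE. The fish is classified *stocked* when
  `Q_source + SE >= 0.90`, *local* when `Q_source + SE <= 0.10`, and
  *hybrid* otherwise (`classify_origin()`, `summarize_origins()`).
- **Growth-history reconstruction.** Total length relates to otolith radius
  through the power law `L = u S^v`, fitted per ecotype on the log scale
  (`fit_power_regression()`, with `compare_slopes()` testing slope
  homogeneity between ecotypes). Length-at-age is back-calculated under the
  body proportional hypothesis `L_i = (S_i / S)^v L` (`back_calculate()`).
- **Von Bertalanffy growth modelling.** `fit_vbgm()` fits
  `L_t = L_inf (1 - exp(-K (t - t0)))` by nonlinear least squares with
  Ford-Walford starting values, per fish or pooled per population, and
  returns a classed fit with `print`, `summary`, `coef`, `predict`, `plot`
  and `residuals` methods. `bootstrap_se()` adds nonparametric case-
  resampling SEs (999 replicates by default); `filter_fits()` drops
  individual fits whose SE exceeds 25% of the estimate; `omega()` reports
  the early-life growth rate `L_inf * K` (mm/yr).
- **Body condition.** Standard weight from the species log-log equation
  `log10(Ws) = -5.681 + 3.2462 log10(TL)`, relative weight
  `Wr = 100 W / Ws`, Welch comparisons between ecotypes, and regressions of
  Wr on length, age, or percent local genetic assignment (`regress_wr()`).
- **Population inference.** Nested linear mixed-effects models with lake as
  a random intercept: `(TL, age) ~ ecotype + stocking-within-ecotype + sex`
  and `(L_inf, omega, Wr) ~ ecotype + origin-within-ecotype + sex`
  (`fit_mixed()`, `report_tables()`).
- **Synthetic cohorts.** Because raw survey data of this kind are rarely
  deposited, `simulate_cohort()` generates complete studies — fish table,
  otolith profiles, admixture records, ground truth — with the statistical
  structure the analysis assumes, so every stage is testable end to end
  (`run_pipeline()` chains the stages over CSV tables).

## Worked example

Fit a pooled population growth model on a simulated planktivorous lake
(30 fish, 2% observation noise) and recover the ancestry-condition line:

```r
library(troutgrowth)

d <- simulate_length_at_age(n_fish = 30, linf = 464, k = 0.13, t0 = -0.43,
                            measurement_cv = 0.02, seed = 1)
fit <- fit_vbgm(d$age, d$length_mm, boot_reps = 199, seed = 2)
summary(fit)
#> Von Bertalanffy growth model
#>      estimate     se
#> linf 461.8309 2.3290
#> k      0.1320 0.0015
#> t0    -0.4057 0.0140
#> omega = 60.95 mm/yr; residual SE = 5.32 mm on 368 points
#> bootstrap: 199 replicates, 0 failed

x <- simulate_wr_ancestry(157, slope = 0.15, intercept = 88.6,
                          sigma = wr_sigma_for_r2(0.15, c(0, 100), 0.22),
                          seed = 3)
regress_wr(x$pct_local, x$wr)
#> Wr regression: y = 0.16x + 88.7, p = 3.5e-11, adjR2 = 0.24, n = 157

summarize_origins(rep(c("local", "hybrid", "stocked"), c(37, 17, 13)),
                  rep("McFee", 67))
#>    lake  n n_local n_hybrid n_stocked pct_local pct_hybrid pct_stocked
#> 1 McFee 67      37       17        13      55.2       25.4        19.4
```

The fitted asymptotic length (462 mm) and growth coefficient (0.132/yr)
recover the generating values (464 mm, 0.13/yr) within their bootstrap
SEs; the condition regression recovers the generating ancestry line, with
a positive slope meaning fish of more local ancestry are in better
condition; the origin summary reports within-lake percentages of each
genetic origin.

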