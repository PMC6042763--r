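---
title: "Methods: growth, condition and genetic origin in stocked Lake Trout populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth, condition and genetic origin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Supplementation stocking releases hatchery-reared fish into existing wild
populations. When the hatchery broodstock derives from a piscivorous Lake
Trout ecotype and the recipient lake holds a planktivorous population, the
stocked fish and their hybrids grow under a trophic regime their genetics
did not evolve in. The analytical chain this package implements asks three
questions of a multi-lake survey: (i) what fraction of each stocked
population is of local, hybrid or stocked genetic origin; (ii) how do
individual growth trajectories — reconstructed from otolith annuli — differ
among ecotypes, stocking histories and genetic origins; and (iii) is body
condition related to the proportion of local genetic ancestry.

## Origin classification

Admixture proportions `Q` per inferred genetic cluster, with bootstrap
standard errors, are taken as given (the upstream SNP genotyping and
clustering are out of scope). For lakes stocked from two source
populations the source proportion is the sum over source clusters, so
`Q_source = 1 - Q_local`. The classification rule is a pair of inclusive
thresholds on `Q_source + SE`: stocked at `>= 0.90`, local at `<= 0.10`,
hybrid between. Adding (rather than subtracting) the SE on the local
boundary is asymmetric — it shrinks the local class — but it is the rule as
published in this literature, so it is the default; `symmetric_se = TRUE`
selects the variant `Q_source - SE <= 0.10` in which measurement
uncertainty widens the hybrid band on both sides. Reported within-lake
percentages are rounded half-up to one decimal, matching how such tables
are conventionally printed (IEEE round-half-even would alter ties).

## Growth reconstruction

**Length-otolith calibration.** Total length at capture is regressed on
otolith radius at capture through `L = u S^v`, estimated by ordinary least
squares on `ln L = v ln S + ln u`. The regression is fitted per ecotype;
`compare_slopes()` tests the ecotype-by-`ln S` interaction in the pooled
model with an F statistic on `(1, n - 4)` degrees of freedom (for two
groups this is exactly the squared interaction t statistic). When the
exponents genuinely differ, pooling produces a visibly weaker log-scale
fit, which is the operational reason for ecotype-specific calibration.

**Back-calculation.** Length at annulus `i` follows the body proportional
hypothesis, `L_i = (S_i / S)^v L`. The capture radius enters only as the
denominator `S`, never as an extra annulus; the capture-year partial
increment is therefore excluded from growth fitting. An annulus radius
exceeding the capture radius is physically impossible, so such fish are
flagged and excluded from growth fitting rather than silently truncated.

**Von Bertalanffy fitting.** The growth model
`L_t = L_inf (1 - exp(-K (t - t0)))` is fitted by least squares to
back-calculated length-at-age, per fish and pooled per population.
Starting values come from the Ford-Walford construction: regressing mean
length at age `t + 1` on mean length at age `t` gives slope
`b = exp(-K)` and intercept `a = L_inf (1 - b)`; `t0` is recovered by
averaging `t + ln(1 - L_t / L_inf) / K` over ages below the asymptote.
When the Walford slope falls outside `(0, 1)` — flat or non-monotone
series — conservative fallback starts are used
(`L_inf = 1.1 * max length, K = 0.2, t0 = 0`). Optimization is
Levenberg-Marquardt least squares capped at 500 iterations, restarted once
from the fallback starts on failure; a fit that still fails, or lands at a
non-positive `K` or `L_inf`, is marked non-converged and excluded
downstream.

**Uncertainty and retention.** Standard errors come from nonparametric
case resampling of the `(age, length)` observations within the series
being fitted (999 replicates by default; each replicate restarts from the
point estimates). Replicate failures are counted, and SEs based on fewer
than half the replicates are flagged unreliable. Individual fits are
retained only when both `SE(L_inf)/L_inf` and `SE(K)/K` are at or below
0.25; the rule is deliberately not applied to `t0`, whose estimate sits
near zero, making a relative SE meaningless. Early-life growth rate is
summarized as `omega = L_inf * K` (mm/yr), the analytic slope of the curve
at `t0`; it is invariant to additive re-indexing of age, which the test
suite checks directly.

## Body condition

Standard weight uses the species-wide equation
`log10 Ws = -5.681 + 3.2462 log10 TL` (TL in mm, Ws in g), and relative
weight is `Wr = 100 W / Ws`. Before Wr is compared across groups, its
comparability is validated the way the field does: a Welch unequal-variance
t test of mean Wr between ecotypes in unstocked lakes, and regressions of
Wr on length and on age in unstocked lakes, all expected null. The
ancestry analysis regresses Wr on *percent* local assignment (0-100), not
proportion: a slope of 0.15 per percentage point spans 15 Wr units across
the ancestry range, which is the natural scale for reading the effect, and
is the scale on which published slopes of this relationship are printed.
Adjusted R-squared uses the simple-regression form
`1 - (1 - R2)(n - 1)/(n - 2)`.

## Population models

Two nested fixed-effect families are fitted with a random intercept per
lake, by REML through `nlme::lme`:

- `TL` and `age` on ecotype (reference: piscivorous), stocking history
  nested within ecotype (reference: unstocked), and sex (reference:
  female) — all lakes;
- `L_inf`, `omega` and `Wr` on ecotype, genetic origin nested within
  ecotype (reference: stocked, so `Local-` and `Hybrid-` terms are
  contrasts against stocked fish), and sex — stocked lakes only, with
  individual growth parameters restricted to retained fits.

Nested dummies are ecotype-specific, so e.g. the hybrid effect is
estimated separately within each ecotype, and term labels carry the
`Hybrid-planktivorous` form. p-values use the fitted model's t statistics
with containment-style (inner-outer) denominator degrees of freedom, the
convention of the fitting tool; the report records the method, since df
conventions differ across mixed-model software and p-values near the 0.05
boundary can change with them. If the random-intercept variance is
unidentifiable (e.g. one fish per lake) or the fit fails, the model falls
back to fixed-effects OLS with a logged warning rather than reporting a
spurious variance component.

## The synthetic cohort generator

`simulate_cohort()` exists so the entire chain is exercisable and testable
without field data. Its defaults *are* the study conditions the package
targets: a 2 ecotype x stocked/unstocked design over ten lakes with
per-lake sample sizes between 18 and 84; ages from a discretized normal
(mean 12 yr, SD 3.45) truncated to 4-28 yr; individual Von Bertalanffy
parameters as lognormal variation (CV 0.08) around ecotype-by-origin cell
means, with stocked fish keeping piscivorous-like asymptotic lengths in
both recipient ecotypes and hybrids intermediate; ecotype-specific
length-otolith power laws (piscivorous `u = 0.27, v = 1.03`;
planktivorous `u = 0.811, v = 0.85`); stocked-lake origin mixtures in the
published range (local fractions from roughly 18% to 55%); and an
ancestry-condition line per ecotype (planktivorous slope 0.15, intercept
88.6; piscivorous slope 0.03, intercept 89.1) with residual SD 8.15,
chosen analytically so the population R-squared of the planktivorous
regression is about 0.22.

Key generative choices, made once:

- **Otolith model.** The literature this package serves does not state how
  annuli relate to length, so annuli are placed by exact inversion of the
  length-radius power law with a single multiplicative per-fish deviation
  (log-scale SD 0.05) shared by all annuli and the capture radius. This
  makes the body proportional hypothesis the *correct* estimator for
  simulated fish — the deviation cancels in `S_i / S` — turning recovery
  tests into clean oracles. Optional per-annulus noise exists
  (`annulus_noise_sd`) but defaults to zero, since within-otolith
  measurement error is rarely quantified.
- **Capture timing.** Capture occurs half a growth season after the last
  completed annulus, so the capture radius always exceeds the last annulus
  radius and the observed length sits slightly above the last
  back-calculated length, as in real data.
- **Ancestry.** `Q_local` is drawn per origin from Beta distributions:
  concentrated near 1 for local fish, near 0 for stocked fish, and a broad
  Beta truncated to (0.10, 0.90) for hybrids; simulated bootstrap SEs are
  half-normal with scale 0.01. No generative model for admixture output is
  published; threshold-consistent Beta draws are the simplest family that
  reproduces the classification structure.
- **Condition in unstocked lakes.** The ancestry-condition line applies to
  stocked lakes. In unstocked lakes every fish is fully local, and true Wr
  is drawn around 100 independent of length and age, which is what the
  comparability checks assume and test. Extending the stocked-lake line to
  unstocked fish would build an ecotype difference in condition into
  populations that are supposed to be locally adapted.
- **One seed.** All draws flow from a single generator seeded once per
  cohort, so identical configurations give byte-identical output tables.

What the generator does **not** emulate: sequencing reads, SNP genotypes
or the admixture likelihood (Q and SE are drawn directly); multi-
generation demography; reader disagreement in age estimation; and any
environmental covariance between lakes beyond the random intercept.
Passing recovery tests therefore demonstrates that the estimators are
correct under the stated generative assumptions — not that those
assumptions exhaust real survey data.

## Problem sizes and numerical tolerances

The test suite and the reproduction script run recovery experiments at the
scale of the design they emulate: ancestry regressions at n = 157 (full
stocked planktivorous pool) and n = 68 (hybrid-only subset) over 20-100
seeded replicates; pooled Von Bertalanffy recovery on 30-fish lakes with
2% multiplicative observation noise and 199 bootstrap replicates per fit
(the package default is 999; 199 keeps replicated experiments brisk while
leaving bootstrap-SE noise well below the 3-SE recovery bands used).
Exactness checks (power-law round trips, Ford-Walford on on-curve data,
BPH identities) assert at 1e-6 to 1e-9 relative error; calibration checks
(Welch type-I error, permutation-null uniformity, mixed-model CI coverage)
run at 2,000 replicates or 100 simulated datasets and assert the nominal
rates with binomial slack.

## Known limitations

- The individual-fit bootstrap resamples back-calculated points within a
  fish, which treats back-calculated lengths as exchangeable observations;
  serial correlation along a trajectory is ignored, as it is in the
  standard workflow this package mirrors.
- The 25% relative-SE retention rule is a convention, not an optimality
  result; it is exposed as `se_filter` in the pipeline configuration.
- Mixed-model p-values depend on the denominator-df convention; no attempt
  is made to reproduce another tool's p-values exactly, only the
  estimates, SEs and report structure.
- Whether individual growth fits should include all completed annuli or
  exclude the final year is not settled in the field; the default fits all
  completed annuli (the capture-year partial increment is never included).
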