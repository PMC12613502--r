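---
title: "Small-area estimation of pregnancy-related mortality: model, adjustment, and calibration"
author: "pregsae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area estimation of pregnancy-related mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pregsae)
```

## The estimation problem

Pregnancy-related deaths are rare: of order 0.5–4 deaths per 100,000
females aged 15–44 per year. Tabulated by county, racial/ethnic
population (AIAN, Asian, Black, Latina, White), 5-year age band (10–14
through 50–54) and year (2000–2019), almost every cell contains zero
deaths, and direct rates (deaths over person-years) are either zero or
absurdly large. Three further problems compound the sparsity:

1. **Small areas.** County-level rates cannot be estimated directly;
   strength must be borrowed across space, age, time, race, and
   covariates.
2. **Certificate-race misreporting.** The race/ethnicity recorded on a
   death certificate disagrees with self-reported race for a
   non-negligible share of deaths — most severely for AIAN decedents,
   who are often recorded as White. Rates modeled from certificate data
   are therefore biased per race.
3. **Consistency.** Correcting race-specific rates changes all-race
   county totals unless a post-hoc calibration restores them.

`pregsae` implements the resulting three-stage pipeline — hierarchical
Poisson small-area model with approximate-posterior draws, draw-wise
classification-ratio adjustment, and two-stage iterative proportional
fitting (IPF) — together with the summarization rules used for
reporting (age standardization, percentile uncertainty intervals,
posterior-probability significance, small-population masking, percent
changes, county-change bookkeeping, rankings). Because the underlying
vital-registration microdata are restricted, the package ships a
synthetic-data module that emulates their structure with fully known
parameters, so every stage is testable end to end.

## Stage 1: the small-area model

Deaths $D_{c,r,a,t}$ in county $c$, race $r$, age band $a$, year $t$
are modeled as Poisson with person-years offset:

$$D_{c,r,a,t} \sim \mathrm{Poisson}\!\left(P_{c,r,a,t}\,
  e^{\eta_{c,r,a,t}}\right),\qquad
\eta = \alpha + \beta_r + \gamma^{\top} x_{c(,r)} + \delta_r\,(t -
\bar t) + \phi_a + u_c\ (+\,\psi_t).$$

* $\alpha$, $\beta_r$ (race indicators), covariate slopes $\gamma$, and
  race-specific linear year slopes $\delta_r$ are fixed effects, held
  near-identifiable by a tiny ridge ($10^{-4}$ precision).
* $\phi_a$ are iid Gaussian age-band effects with SD $\sigma_a$.
* $u_c$ are county effects with a proper conditional autoregressive
  (CAR) prior: precision $\tau\,(D - \rho A)$ built from the county
  adjacency graph ($A$ adjacency, $D$ degree diagonal), with
  $\rho = 0.95$ by default. A proper CAR ($\rho < 1$) is sampleable and
  needs no sum-to-zero bookkeeping while behaving like an intrinsic CAR
  for $\rho$ near 1.
* $\psi_t$, an optional shared first-order random-walk year effect, is
  off by default; the default temporal structure is the race-specific
  linear slopes. The exact published spline/interaction structure of
  the original analysis is not reproduced; linear trends plus an
  optional RW capture the same qualitative shape and are testable.

**Fitting.** The latent vector (all fixed and random effects) is
maximized by sparse Newton iterations on the penalized Poisson
log-likelihood. Variance hyperparameters ($\sigma_a$, the CAR scale,
and the RW SD when enabled) are optimized on the log scale against a
Laplace approximation to the marginal likelihood, with weak half-normal
penalties (scale 1.5 on the SD scale) for stability when many strata
are empty. The posterior is then approximated as Gaussian at the mode
with covariance the inverse negative Hessian — the classical Laplace
approximation that desk-scale penalized-likelihood tools provide — and
1000 draws of every stratum rate are simulated by pushing latent draws
through the log link, scaled to deaths per 100,000.

Numerical policies, fixed for reproducibility:

* Newton convergence: max gradient below
  $10^{-6}(1 + \sum|D|)$; failure raises an explicit error carrying
  diagnostics, never a silent result.
* Positive-definiteness repair: jitter of $10^{-8}\times$ mean diagonal,
  escalated tenfold to at most $10^{-4}$, then failure.
* Zero-death strata receive no continuity correction — the likelihood
  handles them, and corrections bias log-linear fits.
* One-dimensional hyperparameter searches use Brent's method; higher
  dimensions use Nelder–Mead with relative tolerance $10^{-4}$.
* Fractional deaths (a by-product of garbage-code redistribution) enter
  the likelihood through the obvious extension
  $d\log\mu - \mu$; no re-rounding.

## Stage 2: misclassification adjustment

A classification ratio for race $r$ is the number of deaths of
population $r$ by self-report divided by the number recorded as $r$ on
death certificates. Stage 2 multiplies every draw of every stratum by
its race's ratio (`adjustDraws()`): a deterministic, draw-wise,
positivity-preserving operation. No extra uncertainty is propagated
from ratio estimation, matching the described procedure; ratios enter
at race level by default, with the same table schema accepting
race-by-age-band ratios (a region dimension is not implemented — the
draws carry no region key and the main analysis applies race-level
ratios).

In the synthetic pipeline the ratios are re-estimated from the linked
tables the generator produces (`estimateRatios()`), with the
certificate denominator taken **after** garbage-code redistribution —
the same table the model is fitted to — so that the adjustment converts
exactly the basis the model estimates. Cells with zero self-report or
zero certificate deaths yield an explicitly undefined (`NA`) ratio with
a warning, never a silent default.

## Stage 3: two-stage raking

Adjustment changes race-specific totals, so adjusted draws no longer
add up to each county's all-race expected deaths. Raking repairs this
on the expected-death-count scale (IPF margins are additive in counts,
not rates), independently per draw:

* **Stage A** margins: all-race expected deaths per (county, age band,
  year) cell, taken from the *unadjusted* draws — the guarantee that
  misclassification adjustment does not change a county's overall
  mortality.
* **Stage B** margins: benchmark (race, age band, year) totals at the
  aggregate (national by default) level, computed from the adjusted
  counts after making them consistent with the stage-A cell totals.
  Building the benchmark from adjusted counts is essential: a benchmark
  from unadjusted counts would simply undo the adjustment.

The two margins are alternated until both hold within relative
tolerance $10^{-8}$ (at most 1000 iterations), ending on a stage-A pass
so county totals hold to rounding error. Because draws are independent,
the kernel (compiled, in-place) iterates each draw separately. Zero
cells are IPF fixed points; a zero cell blocking a positive target is a
structural infeasibility and raises an error naming the margin rather
than perturbing the data. Stage order (A then B, iterated) removes any
order sensitivity. With the default benchmark construction the margins
are mutually consistent and the loop converges in one pass; externally
supplied benchmarks may take more iterations. Consistency across causes
of death is out of scope for this single-cause package; the geographic
benchmark margin plays that role. Masking-eligible small strata are
raked like all others — masking is display-only.

`ipfRake()` exposes the same algorithm for a single nonnegative table
and is cross-checked in the test suite against an independent IPF
(`stats::loglin`) to $10^{-8}$.

## Summaries

* **Point estimates and 95% uncertainty intervals**: mean of the draws
  and their 2.5th/97.5th percentiles. Percentiles use linear
  interpolation between order statistics (R's type 7); the convention
  is fixed because no single convention is universal and
  reproducibility requires one.
* **Age standardization**: weighted sum of age-specific rates over the
  six bands 15–19 … 40–44. Weights are a configuration input
  (`standardPopulation()`), uniform by default; users with the 2010
  Census distribution supply it directly. Bands outside 15–44 are
  modeled but excluded from standardized reporting.
* **Aggregate geographies**: population-weighted means of age-specific
  rates per draw, then standardization.
* **Significance**: a difference is statistically significant when the
  posterior probability of a positive difference lies strictly outside
  $[0.025, 0.975]$.
* **Percent change** between two years is computed draw-wise,
  $100\,(r_1 - r_0)/r_0$, with the point estimate the mean of draw-wise
  changes — consistent with draw-based intervals. (A point-wise variant,
  the change of draw means, is available via `method = "pointwise"`;
  the two agree on constant draws.)
* **Masking**: any (county, race) combination whose mean annual
  all-sex population across the full year range is strictly below 1000
  is masked in every year, never year-by-year. The modeled tables carry
  female person-years; the pipeline multiplies by an `allSexFactor`
  (default 2) to approximate the all-sex population the display rule
  refers to.
* **County-change bookkeeping**: counts and shares of counties with
  (significant) increases, with percentages rounded half-up to one
  decimal for display — the convention that reproduces published
  percentages exactly from their printed numerator/denominator pairs —
  and median/IQR of changes by the same type-7 quantile convention.
  Rounding never feeds back into computation.
* **Rankings**: descending point estimate with ties broken by unit
  identifier, masked rows excluded.

## The synthetic study

The generator (`simConfig()`, `simulateStudy()`) emulates national
vital-statistics tabulations; its defaults are the package's study
conditions and are not tuned per experiment:

* 200 counties with first-year female person-years log-normal
  (`meanlog = log(10000)`, `sdlog = 1.6`) — spanning roughly $10^2$ to
  $10^6$, so a realistic share of county-race combinations falls below
  the masking threshold; populations drift by a small per-county
  multiplicative growth rate (mean 0.5%/year, SD 1%).
* Race shares per county from a Dirichlet with concentration
  (0.5, 0.8, 1.5, 2.0, 10.0) for (AIAN, Asian, Black, Latina, White) —
  a White-majority mix with small, spatially variable minority
  populations.
* Baseline rate $10^{-5}$ per person-year with race offsets (+0.9,
  −0.35, +0.85, −0.05, 0 on the log scale), an age curve peaking at
  40–44 and collapsing outside the reproductive ages, and a shared log
  trend of $\ln 2/17 \approx 0.041$/year — doubling roughly every 17
  years, the magnitude of the observed national rise.
* One standardized county-level covariate ("income", effect −0.15) and
  one county-by-race covariate ("poverty", +0.20) — minimal structure
  for the covariate roles; the exact covariate set of the original
  analysis is not public, so the configuration accepts arbitrary
  covariate tables.
* County effects from a proper CAR on a rook-adjacency lattice
  ($\rho = 0.9$), centered and scaled to SD 0.3 exactly.
* Certificate-race misreporting concentrated in the AIAN population
  (72% of AIAN deaths keep their certificate race, most of the
  remainder recorded White — implying a classification ratio near 1.4,
  the magnitude reported in the linkage literature), mild misreporting
  for Asian and Latina deaths, minimal for Black, and a small inflow
  into every group from White.
* 10% of deaths flagged as garbage-coded. The package redistributes
  them proportionally to cause-specific deaths within each (county,
  age, year) cell, falling back to population shares in cells with no
  specific deaths. The full cause-hierarchical redistribution machinery
  of burden-of-disease pipelines is deliberately out of scope; the
  proportional rule is transparent and conserves totals to $10^{-9}$.
* Seeding: one master seed expands into fixed per-stage child seeds, so
  each stage is individually reproducible.

What the generator does **not** emulate: ICD-coded cause strings,
live-birth denominators (person-years are the denominator throughout),
sex structure beyond a single female population, checkbox-era
ascertainment changes, and spatially structured covariate confounding.
A passing recovery experiment therefore shows the pipeline's internal
correctness — not that real certificate data meet its assumptions.

## What the recovery experiment measures

`evaluateSyntheticRecovery()` runs the full pipeline on the default
conditions (200 counties × 5 populations × 9 age bands × 20 years =
180,000 strata; 1000 draws — a few minutes and ~4 GB on one CPU) and
reports:

* Pearson correlation between true and estimated age-standardized
  rates over all (county, race, year) cells;
* the share of strata whose true rate lies inside the 95% draw
  interval;
* per race, the absolute error of the national population-weighted
  rate against the **realized** self-report rate, before and after
  adjustment. The realized (not expected) rate is the right target
  here: it isolates the misreporting correction from Poisson
  realization noise, which for the smaller populations exceeds the
  misreporting signal; recovery of expected truth is the correlation
  and coverage criterion's job;
* RMSE against truth of modeled versus raw rates for masking-eligible
  county-race combinations (the shrinkage rationale for small-area
  modeling);
* achieved raking margin discrepancies;
* the county-change summary of the synthetic study.

```{r, eval = FALSE}
ev <- evaluateSyntheticRecovery(seed = 1)
ev$correlation; ev$coverage
as.data.frame(ev$raceErrors)
```

The same computation backs `scripts/acceptance.R`, which writes the
metrics as JSON (see the README).

## Known limitations

* The Gaussian-at-the-mode approximation conditions on the optimized
  hyperparameters; hyperparameter uncertainty is not propagated, which
  can make interval coverage slightly below nominal on very sparse
  data.
* Draw means of log-linear rates carry the usual log-normal mean
  inflation $e^{\sigma^2/2}$; for strata with very weak data this
  inflates point estimates relative to the mode — one reason the
  display masking rule exists.
* Ratio adjustment is deterministic; uncertainty in the classification
  ratios themselves is not propagated.
* The proportional garbage-code redistribution and the national
  stage-B benchmark are transparent stand-ins for cause-hierarchical
  redistribution and all-cause envelope raking, which require the
  multi-cause machinery this package does not reproduce.
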