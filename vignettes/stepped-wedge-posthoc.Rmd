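---
title: "Post-hoc analysis of a stepped-wedge trial with a sparse binary endpoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-hoc analysis of a stepped-wedge trial with a sparse binary endpoint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The setting

`swept` implements the analytical toolkit for a stepped-wedge cluster
randomised trial of an unusual shape: seven hospital sites, 24 months of
continuous recruitment, and three phases — a long "validation" phase in
which every site delivers standard care (control), a short randomisation
phase in which sites cross over to the intervention pathway at randomised
steps, and a long "implementation" phase with every site on the
intervention. Two co-primary outcomes are modelled: length of hospital
stay (analysed on the log scale, so effects are geometric mean ratios,
GMR) and a rare binary safety event (overall rate well below 1%, analysed
as an odds ratio, OR).

This design stresses standard stepped-wedge methodology in two ways.
First, contemporaneous ("vertical") comparisons exist only inside the
short randomisation phase, so the mixed model leans heavily on the few
cluster periods around the crossover dates. Second, with a handful of
clusters and a very low event rate, a single site-month with an unusual
event count can move the effect estimate substantially, and sparse-data
bias becomes a live concern. The package exists to make every procedure
in that situation — the model catalogue, covariate adjustment,
data augmentation, raw-data probes and simulation checks — available and
testable without access to the original patient-level data, which were
confined to a national safe haven.

## The models

The efficacy model is a Gaussian linear mixed model for log length of
stay:

$$\log y_{ij} = \mathbf{x}_{ij}^\top\beta + u_j + \varepsilon_{ij},
\qquad u_j \sim N(0, \sigma_u^2),\;
\varepsilon_{ij} \sim N(0, \sigma_e^2),$$

with a random intercept per site $j$ — exactly the compound-symmetry
within-site covariance structure — fitted by REML with the variance ratio
profiled out (`sw_lmm()`). The safety model is the logistic analogue:

$$\mathrm{logit}\,\Pr(y_{ij}=1) = \mathbf{x}_{ij}^\top\beta + u_j,$$

whose marginal likelihood integrates each site's Bernoulli likelihood
over $u_j$. `sw_glmm()` approximates that integral by adaptive
Gauss–Hermite quadrature (AGQ) with mode-centred nodes, or by the
Laplace approximation — the one-node case, used as the default for the
post-hoc refits because it is much faster and, in this near-zero
between-site-variance regime, indistinguishable in practice. The
fixed-effect part of the primary model (code A) is: intercept,
intervention indicator, season as three dummies against a Winter
(Dec–Feb) reference, and presentation day centred on the enrolment
midpoint. Wald intervals on the log scale are used throughout,
exponentiated for reporting.

Eleven model variants (codes A–K, `model_spec()`) modify the population
(calendar-matched before/after; randomisation phase only), the crossover
timing (actual vs as-randomised), the time trend (linear, natural cubic
spline, categorical 3-monthly, or none), exposure-time adjustment
(linear or spline), and the random structure (random intervention effect
or random time slope, both fitted by a two-dimensional Laplace
approximation with unstructured covariance). Four covariate-adjustment
methods (`adjustment_spec()`) bolt onto any model: direct adjustment for
age/sex/deprivation (AFD), direct adjustment for the full 13-variable
history list (AMC), regression adjustment for the logit of a mixed-model
propensity score (APS), and inverse probability of treatment weighting
(IPTW) with $w_i = Z_i/p_i + (1-Z_i)/(1-p_i)$. The propensity model is a
site-random-intercept logistic regression of the condition experienced
on the 13 covariates, re-estimated on the restricted population for the
restricted analyses.

## What the synthetic generator emulates — and what it cannot

`generate_parametric()` draws presentations uniformly over the study
window (the simplest process consistent with continuous recruitment),
covariates from stated marginals (age $N(59, 17^2)$, 45% female, equal
deprivation quintiles, plausible history-flag prevalences), log-normal
length of stay with multiplicative intervention/season/secular effects,
and Bernoulli safety events on the logit scale. Site random intercepts
default to SD 0, reflecting the effectively-zero between-cluster
variability of a rare endpoint across similar emergency departments;
they are configurable upward for stress tests. An optional per-day drift
in the age distribution, combined with an age effect on the outcome,
manufactures the time-varying confounding the adjustment methods are
meant to absorb.

`generate_replica()` instead reproduces the published phase-level count
margins *exactly*: 10,724 / 9,336 / 11,432 presentations and 49 / 37 /
27 safety events across the three phases (31,492 and 113 in total), with
the randomisation phase split into 29 events among 5,248
intervention-condition records versus 8 among 4,088 controls, and
optionally one spiked site-month cluster period carrying exactly 7
events. Within those margins, events are allocated to records by seeded
simple random sampling — a multinomial allocation over cluster periods
proportional to their denominators. The true cluster-period event
calendar was never exportable from the safe haven, so any allocation is
a modelling choice; this is the least-informative one. Consequently the
replica reproduces all count arithmetic and the *qualitative* behaviour
of the model suite, but not the published model-based estimates (OR
1.97, calendar-matched OR 0.48, GMR 0.78), which depend on the
unavailable fine structure of the real data. Passing tests on replica data
therefore validate the machinery, not the trial's clinical conclusions.

Relative site sizes are not published; the generator defaults to equal
weights. Length-of-stay missingness (0.05% in the trial) defaults to 0.

## Data augmentation

The sparse-data device generates a synthetic "prior" cohort placed one
day either side of each site's crossover (the most informative cluster
periods), with per-site event counts drawn once as Binomial(per-side
count, 0.4%) and applied identically to both sides — so the events
before and after the crossover are equal in every site and overall, and
the prior's risk difference is exactly 0 whenever the per-side
denominators are equal. The prior size is calibrated
(`calibrate_prior()`) as the smallest grid value whose realised 95% CI
for the risk difference lies within ±2 percentage points; the criterion
is re-checked on the returned dataset. Pooled fitting
(`fit_augmented()`) drops the global intercept and adds separate
baseline indicators for real and synthetic records — the only full-rank
reading of "no intercept, adjusting for data type" — so the prior
informs only the shared intervention and trend terms. Choices the
source material leaves open, decided here: prior patients are allocated
equally across sites and sides (rounding the total up to a multiple of
14, never silently); the risk-difference interval is a Newcombe score
interval built from per-arm Wilson intervals, a choice the ±2% criterion
is robust to; the calibrated total counts *all* prior patients; prior
covariates sit at population means and cancel into the synthetic-data
baseline.

## Raw-data probes

`tabulate_cluster_periods()` tabulates events and denominators by site ×
calendar month. `set_cluster_period_events()` relabels events inside one
cell (identity when the target equals the current count), which supports
the "reduce the 7-event cell to the median of 1" probe.
`tipping_point()` asks how many events must be removed from one
condition within one phase to drive the model OR across 1; removal
proceeds from the currently fullest cluster period (ties by site order,
then month; the event within a cell is chosen by seeded sampling) —
a deterministic, reproducible reading of "probe the dominant cluster
period", since the original analysis did not state an order. The median
cluster-period count is computed over cells with at least one
presentation, zero-event cells included.

## Numerical choices

* GLMM optimiser: L-BFGS-B over $(\beta, \log\sigma_u)$ with analytic
  gradients of the Laplace objective (envelope theorem at the
  per-cluster modes plus exact derivatives of the log-determinant
  correction); the box's lower bound $\sigma_u = 10^{-4}$ *is* the
  zero-variance boundary, where the fit is reported as $\sigma_u = 0$
  with a `boundary` flag and the fixed effects refitted by plain
  (weighted) IRLS — the exact $\sigma_u \to 0$ limit. Restarts from
  $\sigma_u \in \{0.1, 1\}$ on failure.
* AGQ fits (default 25 nodes; the node count is a package choice) are
  warm-started from the Laplace optimum and polished under the
  quadrature objective with central-difference gradients. A brute-force
  `stats::integrate()` oracle validates the quadrature to $10^{-6}$ in
  the tests; the oracle shares no code with the quadrature path.
* Random-slope models use a 2×2 unstructured covariance in log-Cholesky
  parameterisation, per-cluster 2-D Newton mode search, Laplace only.
* LMM: REML via a profiled scalar variance ratio (golden-section search
  on the log scale), explicitly comparing the interior optimum against
  the $\lambda = 0$ boundary. ML is available; REML is the default, a
  documented choice where the source is silent.
* Weights multiply log-likelihood contributions (frequency-style), so
  IPTW enters both engines identically; an optional cluster-robust
  sandwich covariance is available but off by default, since the
  original variance estimator is unstated.
* Splines: natural cubic bases with 3 interior knots at quantiles
  (configurable); exposure-time splines place knots at quantiles of the
  *positive* exposures because of the mass at zero. Categorical time
  uses eight 91-day bins from the study start, first bin as reference.
  Dummy columns constant in a restricted population (e.g. absent seasons
  in the randomisation phase) are dropped before fitting.
* Propensities are trimmed to $[10^{-6}, 1-10^{-6}]$; optional weight
  truncation at an upper quantile is off by default.
* Boundary conventions: the crossover day itself is intervention; phases
  are half-open $[\mathrm{start}, \mathrm{end})$; the calendar-matched
  window 3 March – 3 September is boundary-inclusive (configurable);
  calendar dates anchor at a configurable origin, 1 June by default.

## Scale of the shipped checks

The test suite exercises the null-calibration study at the trial's own
scale — 500 replicates of n = 31,492 with a 0.4% event rate and seven
sites — and parameter recovery at true OR 2 over 200 replicates; both
report Monte-Carlo standard errors and assert calibration within three
of them. Machinery properties (quadrature, shrinkage, tipping
monotonicity, adjustment-under-drift) run on smaller synthetic cohorts
(thousands of rows, event rates of a few percent) chosen so the whole
suite stays desk-scale while leaving the statistical conclusions
unchanged.

## Known limitations

GEE with small-sample corrections and autoregressive or unstructured
residual models are deliberately out of scope: in this regime (huge
clusters, few sites) they are known to fail to converge, and the
package does not attempt them. The published model-based effect
estimates on the real data are not reproducible from counts alone and
are not targeted. The "approximate risk difference" is computed as an
average marginal effect with a delta-method interval (random effects at
their typical value), a documented stand-in for a construction the
source material does not specify.

## A worked example

```{r, eval = FALSE}
library(swept)
design <- sw_design()
dat <- generate_replica(design,
                        sw_replica_counts(spike = default_spike(design)),
                        seed = 1)
fitA <- run_analysis(dat, design, "A", outcome = "safety")
print(fitA)

cal <- calibrate_prior(design, prior_spec(), seed = 1)
aug <- fit_augmented(dat, cal$prior, design)
print(aug)

tp <- tipping_point(dat, design, seed = 1)
print(tp)
```
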