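# swept

Post-hoc analysis toolkit for stepped-wedge cluster randomised trials
with long before-and-after periods and a sparse binary safety endpoint.

## The problem

In a stepped-wedge trial every cluster starts under control and crosses
over to the intervention at a randomised time point. When the design has
only a few clusters (here: 7 hospital sites), a short randomisation
phase inside a 24-month window, and a binary endpoint occurring in well
under 1% of patients, the pre-specified mixed-model analyses can
disagree sharply — point estimates on opposite sides of 1 with
non-overlapping confidence intervals — because the model leans on a
handful of events in the cluster periods nearest the crossover dates.
`swept` packages the full battery of procedures a trial statistician
needs to dissect such a result:

* a **synthetic cohort generator** — a parametric mode for simulation
  studies, and a *replica* mode that reproduces published phase-level
  count margins exactly (31,492 presentations, 113 events; phase splits
  10724/9336/11432 and 49/37/27; randomisation-phase condition split
  29/5248 vs 8/4088; an optional 7-event cluster-period spike);
* a **mixed-model engine**: random-intercept linear mixed model for log
  length of stay by profiled REML (compound symmetry within site), and
  a logistic mixed model whose marginal likelihood

  log L_j(β, σ_u) = log ∫ ∏_i p_ij(β, u)^{y_ij} (1 − p_ij(β, u))^{1−y_ij} φ(u; 0, σ_u²) du,
  logit p_ij(β, u) = x_ijᵀβ + u,

  is approximated by adaptive Gauss–Hermite quadrature or the Laplace
  method, with weighted fits and 2-D random effects (random intervention
  or random time slope);
* the declarative **catalogue of analyses A–K** (population, timing,
  time-trend, season, exposure-time and random-structure variants) and
  **adjustment methods** (demographics, multiple covariates,
  propensity-score regression adjustment, and IPTW with
  w = Z/p + (1−Z)/(1−p));
* **sparse-data augmentation**: a synthetic null prior anchored one day
  either side of each crossover with an equal-events rule, calibrated so
  its risk-difference 95% CI fits within ±2 percentage points, pooled
  with the data under a no-global-intercept model with per-data-type
  baselines;
* **raw-data probes**: cluster-period (site × month) tabulation, event
  relabelling of single cells, and a tipping-point search for the number
  of events whose removal reverses the odds ratio;
* a **simulation harness** for type-I error, bias and coverage of the
  primary model under the trial's own design.

## A worked example

```r
library(swept)
design <- sw_design()                               # 7 sites, 3 phases, 24 months
dat <- generate_replica(design,
                        sw_replica_counts(spike = default_spike(design)),
                        seed = 1)

fitA <- run_analysis(dat, design, "A", outcome = "safety")  # primary model
print(fitA)
#> Stepped-wedge mixed model fit (Laplace, binomial)
#>   n = 31492  log-likelihood = -741.34091
#>   random-effect SD: site 0.1009
#>   intervention (OR): 3.252 [95% CI 1.399, 7.561]

fitB <- run_analysis(dat, design, "B", outcome = "safety")  # calendar-matched
forest_table(list(fitA, fitB))[, c("label", "estimate", "ci_low", "ci_high", "n_used")]
#>    label estimate    ci_low  ci_high n_used
#> 1 A.none 3.252299 1.3990046 7.560694  31492
#> 2 B.none 0.629506 0.2238465 1.770310   7584
```

On this replica dataset the primary mixed model (OR 3.25) and the
calendar-matched before/after comparison (OR 0.63) sit on opposite sides
of the null — the same qualitative divergence that motivates the
toolkit: the primary model's estimate is driven by the event-rich
cluster periods near the crossovers (including the injected 7-event
spike), while the calendar-matched analysis never sees the randomisation
phase at all. The length-of-stay arm is stable by comparison
(`run_analysis(dat, design, "A", outcome = "los")` gives GMR 0.79).

The augmentation procedure calibrates a null prior and refits:

```r
cal <- calibrate_prior(design, prior_spec(), seed = 1)
cal$n_star                       # 602 imaginary patients
round(cal$rd_ci, 3)              # rd 0.000, 95% CI [-1.792, 1.792] (%)
aug <- fit_augmented(dat, cal$prior, design, method = "Laplace")
aug$combined$effect$estimate     # OR shrinks from 3.25 to 2.33
```

and the average-marginal-effect risk difference for the primary fit is
`approximate_risk_difference(fitA)` → 0.52% (95% CI 0.00%–1.04%).

A YAML-configured end-to-end run (generation → analysis grid →
augmentation → sensitivity → simulation) is available through
`run_pipeline()`; every output CSV is stamped with the config hash and
seed, so reruns are byte-identical.

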