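---
title: "Causal contrasts for competing-risks outcomes with IPTW: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal contrasts for competing-risks outcomes with IPTW: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iptwcr)
```

## The scientific problem

Living-donor kidney transplantation (LDKT) shows better graft survival
than deceased-donor transplantation (DDKT), but living-donor recipients
are also younger, healthier and less deprived, so the crude comparison is
confounded. `iptwcr` estimates the *causal* effect of donor type on graft
failure, treating death with a functioning graft as a competing risk:
the contrast between the graft-failure risk the whole cohort would have
experienced had everyone received a living-donor kidney versus a
deceased-donor kidney (the average treatment effect, ATE).

Hazard ratios are deliberately avoided: early graft failures followed by
a low constant failure rate make proportional hazards implausible, and
hazard ratios lack a causal interpretation under selection over time. The
estimands are instead

* the **risk difference** at horizons $h = 1,\dots,7$ years,
  $F_1^{(0)}(h) - F_1^{(1)}(h)$, where $F_1^{(a)}$ is the marginal
  cumulative incidence of graft failure had everyone received donor type
  $a$ (positive values favour LDKT), and
* the **restricted-mean contrast** over $\tau = 7$ years.

## Estimation pipeline

1. **Eligibility.** ABO-incompatible donor–recipient pairs (missing
   blood group counts as potentially incompatible), records without
   post-transplant outcomes, and LDKT-only centres are excluded
   sequentially; each row counts toward the first rule it violates, so
   per-rule counts and the eligible count always sum to the input count.
   Event times of exactly 0 days are set to 0.5 days so those subjects
   enter the risk set.
2. **Propensity model.** Logistic regression of donor type on the
   baseline confounders (ages, sexes, ethnicity, BMI, blood group, CMV
   status, primary renal disease, deprivation quintile, transplant
   year). Variables that are *consequences* of donor type — cold
   ischaemia time, HLA mismatch level, waiting time — are mediators and
   are refused by default (`allow_mediators` opens the HLA sensitivity
   switch only).
3. **Weights.** Unstabilized ATE weights $w = A/e(X) + (1-A)/(1-e(X))$.
   Stabilization and percentile truncation are available but off by
   default, matching the primary analysis the package reproduces.
   Within-arm estimators are invariant to arm-constant rescaling, so
   stabilization changes nothing in the point estimates here; it is
   offered because it can improve bootstrap behaviour with poor overlap.
4. **Curves.** Per-arm weighted Aalen–Johansen cumulative incidence
   $F_k(t) = \sum_{t_i \le t} S(t_i^-)\, d_{k,i}/n_i$ with weighted event
   and risk-set masses. The identity $S + F_1 + F_2 = 1$ holds exactly
   at every event time. An independent route to the same quantity — the
   Fine–Gray-weighted Kaplan–Meier, in which competing-event subjects
   remain at risk with weight $\hat G(t^-)/\hat G(T_i^-)$ — coincides
   with the Aalen–Johansen CIF *algebraically* when the censoring-KM
   $\hat G$ uses events-before-censorings risk sets, because
   $n_i = n_1\, S(t_i^-)\, \hat G(t_i^-)$ in finite samples. The
   equivalence (to 1e-10) is a standing cross-check in the test suite,
   not an approximation. $\hat G$ uses the IPTW weights by default so
   the pseudo-population interpretation stays coherent; a toggle gives
   the unweighted version.
5. **Contrasts.** Risk differences at the yearly grid by
   right-continuous lookup; the primary restricted-mean contrast is the
   difference in restricted mean time *free of graft failure*,
   $\tau - \mathrm{RMTL}(F_1)$, which respects the competing risk and
   reduces to the ordinary RMST difference when no competing events
   exist. The all-event RMST difference is reported alongside, since
   "years of graft survival" is ambiguous between the two; the
   CIF-based contrast is primary.
6. **Inference.** Nonparametric bootstrap, 250 resamples of subjects
   with replacement, with the propensity model refit inside every
   replicate so design uncertainty propagates. SE = SD of replicate
   estimates; normal (Wald) 95% CIs, as in the analysis reproduced.
   Replicate failures (e.g. separation in a resample) are skipped and
   counted; more than 10% failing aborts. Each replicate draws its seed
   from the master seed by replicate index, so results are independent
   of execution order.
7. **E-values.** From the two adjusted cumulative incidences at each
   horizon: $RR$ = larger/smaller, $E = RR + \sqrt{RR(RR-1)}$. A risk
   difference alone does not determine an e-value, hence the ratio of
   the two CIFs. Both the point e-value and the bootstrap median (the
   form reported in the registry analysis) are returned.
8. **Death as outcome.** `cause = 2` runs the symmetric analysis of
   all-cause death with graft failure competing; it is implemented by
   relabelling event codes, and the test suite checks the symmetry
   exactly.

## The synthetic registry and what it does (not) show

The real registry extract is access-controlled, so the package ships a
generator whose *defaults are the study conditions*: n = 10 915 with
roughly 31.6% living-donor transplants; baseline covariates with
registry-like marginals; a logistic treatment-assignment model and
log-linear cause-specific exponential hazards sharing covariates
(confounding by construction, strongest through recipient age,
ethnicity, deprivation and diabetes); baseline hazards calibrated so
that about 13–15% fail and about 13% die over follow-up; uniform entry
over an 11.5-year window with a 12-year administrative cutoff, giving
censoring times uniform on roughly 0.5–12 years with the analysis
restricted to 7; and MAR missingness concentrated in primary renal
disease, BMI and deprivation, driven by fully observed age and
transplant year. Under these defaults the true 5-year risk difference
is about 6–7 percentage points and the true restricted-mean gain about
0.33 years — the same order as the published registry estimates.

Exponential cause-specific hazards were chosen as the simplest family
with closed-form oracles: with all covariate effects zero,
$F_1(t) = \frac{\lambda_1}{\lambda_1+\lambda_2}(1 - e^{-(\lambda_1+\lambda_2)t})$,
which the estimators must recover within binomial Monte-Carlo error.
The potential-outcomes oracle simulates each subject twice (treatment
forced to 1 and 0, common random numbers, no censoring) and returns the
true marginal contrasts with paired Monte-Carlo standard errors.

What passing these tests does *not* show: real registries have
non-constant hazards (early surgical failures), centre effects,
informative loss to follow-up, measurement error and possibly MNAR
missingness. The generator emulates none of these, so parameter
recovery here validates the estimator machinery, not the registry
conclusions themselves. MAR missingness is deliberate: it makes
multiple imputation theoretically unbiased, giving the MI sensitivity
check a known answer.

## Multiple imputation

Chained equations, m = 10 imputations and 10 sweeps by default
(configurable; the reproduced analysis does not print its values, and
doubling m moves pooled points by well under one Monte-Carlo SE here).
Every conditional model is survival-aware: predictors include
treatment, the other confounders, per-cause event indicators and log
follow-up time. Continuous targets use Bayesian linear-regression draws
(posterior error variance and coefficients, then a noisy prediction);
categorical targets use multinomial-logistic probability draws via
`nnet::multinom`. The multinomial step draws from fitted probabilities
without a coefficient-posterior draw — a mild understatement of
imputation uncertainty, documented here as a known approximation.
Pooling is by Rubin's rules with each imputation's bootstrap variance
as the within-imputation variance; bootstrap-within-imputation is not
nested, a standard cost-saving approximation.

## Numerical choices

* Tie handling: all events and censorings at a time are processed
  events-first; cause-1 and cause-2 events at the same time share
  $S(t^-)$.
* IRLS convergence at score-equation residual < 1e-8 (typically far
  tighter), max 100 iterations, deterministic; separation is detected
  from fitted probabilities hitting 0/1 and reported as an error, and
  rank-deficient designs are refused with the collinear columns named.
* Pooled SD for SMDs is $\sqrt{(s_1^2+s_0^2)/2}$, unweighted before
  weighting and weighted after; multi-level categoricals are assessed
  per level as binary indicators (the convention is not stated in the
  reproduced analysis). Weighted variances use the
  $\sum w - \sum w^2/\sum w$ denominator, which reduces to $n-1$ for
  unit weights. A zero pooled SD with equal means is balance (SMD 0);
  with unequal means it is flagged as signed infinity.
* Dummy coding uses the first declared level as reference, recorded in
  the fit's `design_spec`.
* One master integer seed drives everything; each stage (generation,
  masking, each bootstrap replicate, each imputation chain) uses a
  fixed sub-seed derived from it.

## Problem sizes used in the shipped checks

The test suite exercises estimator identities on 200 random small
instances; closed-form recovery at n = 10^4; parameter recovery,
unadjusted-bias and CI-coverage checks over 100 synthetic cohorts of
n = 5 000 with 250-resample bootstraps; balance over 100 replicates at
n = 10^4; and the MI check at n = 5 000 with m = 10. These sizes give
Monte-Carlo error comfortably below the tolerances being asserted while
keeping a full run at desk scale.

## Known limitations

* The generator's exponential hazards cannot represent the early hazard
  spike of real transplant cohorts; a Weibull shape parameter is the
  natural config extension.
* E-values address unmeasured confounding on the risk-ratio scale only;
  they do not speak to selection or measurement bias.
* The censoring model is administrative only; dependent censoring would
  require IPCW extensions not implemented here.
* Subgroup analyses refit the propensity model within the subgroup
  dataset (all controls plus the qualifying treated rows) and inherit
  all of the above.
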