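# iptwcr

Causal contrasts for competing-risks outcomes via inverse probability of
treatment weighting (IPTW), built for transplant-registry questions of
the form *"what would graft survival have been had every patient
received a living-donor kidney?"*.

Living-donor kidney transplantation (LDKT) shows better graft survival
than deceased-donor transplantation (DDKT), but the two recipient
populations differ systematically, and death with a functioning graft
competes with graft failure. `iptwcr` estimates the average treatment
effect of donor type with:

- a propensity-score logistic model on baseline confounders (mediators
  such as cold ischaemia time, HLA mismatch and waiting time are refused
  by default),
- unstabilized ATE weights `A/e(X) + (1−A)/(1−e(X))` with balance
  (standardized mean difference) and positivity diagnostics,
- per-arm IPTW-weighted **Aalen–Johansen** cumulative incidence
  `F_k(t) = Σ S(t⁻)·d_k/n`, cross-checked against an algebraically
  equivalent **Fine–Gray-weighted Kaplan–Meier** route,
- causal **risk differences** at 1–7 years and a **restricted-mean
  event-free-time contrast** over 7 years (`τ − RMTL(CIF₁)`), never
  hazard ratios,
- a 250-resample bootstrap (propensity model refit in every replicate)
  with normal 95% confidence intervals, and **e-values** for unmeasured
  confounding, `E = RR + √(RR(RR−1))`,
- eligibility filtering with exact exclusion accounting, subgroup and
  sensitivity analyses, and multiple imputation by chained equations
  with Rubin's-rules pooling,
- a synthetic registry generator with a potential-outcomes oracle, so
  every estimator can be validated against known ground truth.

## Worked example

```r
library(iptwcr)

cfg    <- registry_config(n = 10915, seed = 2026, missing_spec = NULL)
cohort <- simulate_registry(cfg)   # synthetic registry-like cohort
confs  <- c("recipient_age", "donor_age", "recipient_bmi",
            "recipient_sex", "ethnicity", "recipient_blood_group",
            "cmv_status", "prd", "imd_quintile", "transplant_year")

fit <- iptw_cmprisk(Surv(time_years, event) ~ treatment, cohort, confs,
                    n_boot = 250, seed = 2026)
summary(fit)
```

```
IPTW competing-risks causal contrasts
  outcome: graft failure (death competing);  n = 10915 (3377 treated, 30.9%)
  bootstrap: 250 resamples (250 effective)
                   estimand   point  boot_se  ci_low ci_high
         risk_difference_1y 0.01713 0.003590 0.01010 0.02417
         risk_difference_2y 0.03438 0.004837 0.02490 0.04386
         risk_difference_3y 0.05376 0.005645 0.04270 0.06482
         risk_difference_4y 0.06051 0.006567 0.04764 0.07338
         risk_difference_5y 0.07870 0.007028 0.06492 0.09247
         risk_difference_6y 0.08072 0.008934 0.06321 0.09823
         risk_difference_7y 0.09002 0.009193 0.07200 0.10804
 event_free_time_difference 0.36615 0.035828 0.29593 0.43637

E-values (risk-ratio scale) by horizon:
 horizon e_value boot_median
       1   3.400       3.354
       ...
       5   3.560       3.574

All modelled confounders balanced after weighting (|SMD| <= 0.1).
Positivity: 0 score(s) outside [0.01, 0.99].
```

Read: after weighting, living-donor recipients have a 7.9 percentage
point (95% CI 6.5–9.2) lower 5-year cumulative incidence of graft
failure and gain 0.37 (95% CI 0.30–0.44) graft-failure-free years over
7 years; an unmeasured confounder would need risk-ratio associations of
about 3.6 with both donor type and graft failure to explain the 5-year
effect away. The generator's potential-outcomes oracle gives the true
5-year risk difference for this configuration:

```r
oracle_true_effects(cfg, oracle_n = 2e5, horizons = 5)$value[1]
#> 0.0677
```

so the weighted estimate is within its confidence interval of the
truth, while the unadjusted contrast (`forced_weights = rep(1, n)`) is
biased away from it — the test suite checks both properties over 100
replicate cohorts.

Other entry points: `run_subgroup_analysis()` (e.g.
`~ donor_age >= 60`), `run_sensitivity()` (`exclude_covid_era`,
`include_hla_in_ps`), `impute_chained()` + `mi_contrast()` for the MI
robustness analysis, `apply_eligibility_filters()` for cohort flow, and
`run_full_analysis()` to execute everything from one `run_config()` and
write CSVs plus a manifest.

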