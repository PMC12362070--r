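fit_args <- function(tab, ...) {
  iptw_cmprisk(Surv(time_years, event) ~ treatment, tab,
               default_confounders, ...)
}

test_that("bootstrap of the sample mean recovers the analytic SE and the
           normal-CI formula", {
  set.seed(88)
  dat <- data.frame(x = rnorm(400))
  bp <- bootstrap_pipeline(dat, function(d) c(mu = mean(d$x)),
                           n_boot = 250, seed = 10)
  expect_lt(abs(bp$boot_se / (1 / 20) - 1), 0.25)
  expect_equal(unname(bp$ci_low), unname(bp$point - 1.96 * bp$boot_se))
  expect_equal(unname(bp$ci_high), unname(bp$point + 1.96 * bp$boot_se))
  expect_equal(bp$n_boot_effective, 250)

  bp2 <- bootstrap_pipeline(dat, function(d) c(mu = mean(d$x)),
                            n_boot = 250, seed = 10)
  expect_identical(bp$boot_se, bp2$boot_se)
  expect_error(bootstrap_pipeline(dat, identity, n_boot = 1), "n_boot")

  # replicate failures above 10% abort (the point estimate succeeds)
  calls <- 0
  flaky <- function(d) {
    calls <<- calls + 1
    if (calls > 1 && runif(1) < 0.5) stop("boom")
    c(m = mean(d$x))
  }
  expect_error(bootstrap_pipeline(dat, flaky, n_boot = 50, seed = 1),
               "unstable")
})

test_that("e-values follow the closed form and its properties", {
  expect_equal(evalue_from_risks(0.2, 0.2), 1)
  expect_equal(evalue_from_risks(0.4, 0.1), 4 + sqrt(12))
  expect_equal(round(4 + sqrt(12), 4), 7.4641)
  # printed 5-year adjusted cumulative incidences, percentage scale
  e5 <- evalue_from_risks(11.63, 5.61)
  expect_equal(e5, 3.5646, tolerance = 1e-3)
  expect_lt(abs(e5 - 3.57), 0.01)
  expect_error(evalue_from_risks(0.3, 0), "positive")
  expect_warning(sw <- evalue_from_risks(0.1, 0.4), "reversed")
  expect_equal(sw, evalue_from_risks(0.4, 0.1))
  # strictly increasing in RR above 1
  rr <- seq(1.01, 6, by = 0.05)
  ev <- rr + sqrt(rr * (rr - 1))
  got <- vapply(rr, function(r) evalue_from_risks(r * 0.1, 0.1),
                numeric(1))
  expect_equal(got, ev)
  expect_true(all(diff(got) > 0))
})

test_that("unit forced weights reproduce the unadjusted AJ contrast
           exactly", {
  cfg <- registry_config(n = 2000, seed = 23, missing_spec = NULL)
  tab <- simulate_registry(cfg)
  fit <- fit_args(tab, n_boot = 0, forced_weights = rep(1, nrow(tab)))
  aj1 <- aalen_johansen(tab$time_years[tab$treatment == 1],
                        tab$event[tab$treatment == 1])
  aj0 <- aalen_johansen(tab$time_years[tab$treatment == 0],
                        tab$event[tab$treatment == 0])
  expect_equal(
    fit$contrasts$point[fit$contrasts$estimand == "risk_difference_5y"],
    eval_curve(aj0$cif1, 5) - eval_curve(aj1$cif1, 5))
})

test_that("null treatment effect yields near-zero adjusted contrasts", {
  hz <- iptwcr:::.default_hazard_coefs()
  hz$cause1["treatment"] <- 0; hz$cause2["treatment"] <- 0
  cfg <- registry_config(n = 1e4, seed = 31, hazard_coefs = hz,
                         missing_spec = NULL)
  tab <- simulate_registry(cfg)
  fit <- fit_args(tab, n_boot = 60, seed = 2)
  rd5 <- fit$contrasts[fit$contrasts$estimand == "risk_difference_5y", ]
  expect_lt(abs(rd5$point), 3 * rd5$boot_se)
})

test_that("a protective cause-1 treatment effect yields positive
           control-minus-treated risk differences", {
  cfg <- registry_config(n = 8000, seed = 13, missing_spec = NULL)
  tab <- simulate_registry(cfg)
  fit <- fit_args(tab, n_boot = 0)
  rd <- fit$contrasts[grepl("^risk_difference", fit$contrasts$estimand), ]
  expect_true(all(rd$point > 0))
  # and the point estimate tracks the potential-outcomes oracle
  truth <- oracle_true_effects(cfg, oracle_n = 1e5, horizons = 5)
  expect_lt(abs(rd$point[rd$horizon == 5] - truth$value[1]), 0.02)
})

test_that("swapping event codes reproduces the cause-2 analysis", {
  cfg <- registry_config(n = 3000, seed = 41, missing_spec = NULL)
  tab <- simulate_registry(cfg)
  fit2 <- fit_args(tab, n_boot = 0, cause = 2)
  swapped <- tab
  swapped$event <- c(0L, 2L, 1L)[tab$event + 1L]
  fit1s <- iptw_cmprisk(Surv(time_years, event) ~ treatment, swapped,
                        default_confounders, n_boot = 0, cause = 1)
  expect_equal(fit2$contrasts$point, fit1s$contrasts$point)
})

test_that("bootstrap inference is deterministic and CI-consistent", {
  cfg <- registry_config(n = 1200, seed = 55, missing_spec = NULL)
  tab <- simulate_registry(cfg)
  f1 <- fit_args(tab, n_boot = 40, seed = 9)
  f2 <- fit_args(tab, n_boot = 40, seed = 9)
  expect_identical(f1$contrasts, f2$contrasts)
  expect_equal(f1$contrasts$ci_low,
               f1$contrasts$point - 1.96 * f1$contrasts$boot_se)
  expect_equal(f1$contrasts$ci_high,
               f1$contrasts$point + 1.96 * f1$contrasts$boot_se)
  expect_equal(f1$n_boot_effective, 40)
})

test_that("subgroup analysis: identity predicate, small subgroups,
           missing columns", {
  cfg <- registry_config(n = 2500, seed = 61, missing_spec = NULL)
  tab <- simulate_registry(cfg)
  base <- fit_args(tab, n_boot = 0)
  all_in <- run_subgroup_analysis(Surv(time_years, event) ~ treatment,
                                  tab, default_confounders,
                                  predicate = ~ donor_age > -Inf,
                                  n_boot = 0)
  expect_equal(all_in$contrasts$point, base$contrasts$point)
  expect_error(run_subgroup_analysis(Surv(time_years, event) ~ treatment,
                                     tab, default_confounders,
                                     predicate = ~ no_such_col == 1,
                                     n_boot = 0),
               "absent")
  expect_error(run_subgroup_analysis(Surv(time_years, event) ~ treatment,
                                     tab, default_confounders,
                                     predicate = ~ donor_age > 1e6,
                                     n_boot = 0),
               "fewer than")
})

test_that("sensitivity variants behave as specified", {
  cfg <- registry_config(n = 2500, seed = 71, missing_spec = NULL)
  tab <- simulate_registry(cfg)
  base <- fit_args(tab, n_boot = 0)

  # no COVID-era rows: identical to base
  pre <- tab; pre$transplant_year <- pmin(pre$transplant_year, 2019)
  base_pre <- fit_args(pre, n_boot = 0)
  sv <- run_sensitivity(Surv(time_years, event) ~ treatment, pre,
                        default_confounders,
                        variant = "exclude_covid_era", n_boot = 0)
  expect_equal(sv$contrasts$point, base_pre$contrasts$point)

  # HLA (independent of treatment and outcome here) barely moves the
  # estimate
  sh <- run_sensitivity(Surv(time_years, event) ~ treatment, tab,
                        default_confounders,
                        variant = "include_hla_in_ps", n_boot = 0)
  rd5 <- function(f)
    f$contrasts$point[f$contrasts$estimand == "risk_difference_5y"]
  expect_lt(abs(rd5(sh) - rd5(base)), 0.02)

  expect_error(run_sensitivity(Surv(time_years, event) ~ treatment, tab,
                               default_confounders, variant = "nope"),
               "arg")
  noyr <- tab; noyr$transplant_year <- NULL
  expect_error(run_sensitivity(Surv(time_years, event) ~ treatment, noyr,
                               default_confounders,
                               variant = "exclude_covid_era"),
               "transplant_year")
})

test_that("fitted object exposes standard accessors", {
  cfg <- registry_config(n = 1500, seed = 81, missing_spec = NULL)
  tab <- simulate_registry(cfg)
  fit <- fit_args(tab, n_boot = 25, seed = 4)
  expect_named(coef(fit))
  ci <- confint(fit, "risk_difference_5y")
  expect_equal(nrow(ci), 1)
  cv <- curves(fit)
  expect_true(all(c("treated", "control") %in% cv$arm))
  expect_output(print(fit), "IPTW competing-risks")
  expect_output(summary(fit), "E-values")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  expect_error(fit_args(tab, horizons = c(1, 9)), "horizons")
})
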