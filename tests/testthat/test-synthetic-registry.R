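test_that("config validation enforces the generator invariants", {
  expect_error(registry_config(n = 1), "integer >= 2")
  spec <- iptwcr:::.default_covariate_spec()
  spec$ethnicity$probs <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(registry_config(covariate_spec = spec), "sum to 1")
  expect_error(registry_config(baseline_hazards = c(cause1 = 0,
                                                    cause2 = 0.1)),
               "strictly positive")
  expect_error(registry_config(censor_admin = list(study_years = 5,
                                                   entry_window = 6)),
               "horizon")
})

test_that("null assignment model yields a balanced coin and valid rows", {
  cfg <- registry_config(n = 1e5, seed = 4,
                         ps_coefs = c(intercept = 0),
                         missing_spec = NULL)
  tab <- simulate_registry(cfg)
  expect_equal(nrow(tab), 1e5)
  # Bernoulli(1/2): 3 SE band
  expect_lt(abs(mean(tab$treatment) - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_true(all(tab$event %in% 0:2))
  expect_true(all(tab$time_years > 0))
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- registry_config(n = 500, seed = 77)
  t1 <- simulate_registry(cfg, apply_missingness = TRUE)
  t2 <- simulate_registry(cfg, apply_missingness = TRUE)
  expect_identical(t1, t2)
})

test_that("null-hazard cohort recovers the closed-form two-cause CIF", {
  # all covariate and treatment log-hazard coefficients zero,
  # lambda1 = lambda2 = 0.1, effectively no censoring
  hz <- iptwcr:::.default_hazard_coefs()
  hz$cause1[] <- 0; hz$cause2[] <- 0
  cfg <- registry_config(
    n = 1e4, seed = 12, hazard_coefs = hz,
    baseline_hazards = c(cause1 = 0.1, cause2 = 0.1),
    censor_admin = list(study_years = 1000, entry_window = 1),
    missing_spec = NULL)
  tab <- simulate_registry(cfg)
  aj <- aalen_johansen(tab$time_years, tab$event)
  truth <- 0.5 * (1 - exp(-0.2 * 5))
  expect_lt(abs(eval_curve(aj$cif1, 5) - truth),
            3 * sqrt(truth * (1 - truth) / 1e4))
})

test_that("forcing treatment to its observed value reproduces the
           observational time distribution", {
  hz <- iptwcr:::.default_hazard_coefs()
  cfg <- registry_config(n = 1e4, seed = 21,
                         censor_admin = list(study_years = 1000,
                                             entry_window = 1),
                         missing_spec = NULL)
  tab <- simulate_registry(cfg)
  # independent redraw of the same observational law
  covs <- iptwcr:::.draw_covariates(cfg, 1e4, 555)
  set.seed(556)
  X <- iptwcr:::.registry_design(covs, cfg, runif(1e4))
  ps <- iptwcr:::expit(iptwcr:::.linpred(X, cfg$ps_coefs))
  a <- rbinom(1e4, 1, ps)
  l1 <- cfg$baseline_hazards[["cause1"]] *
    exp(iptwcr:::.linpred(X, cfg$hazard_coefs$cause1, a))
  l2 <- cfg$baseline_hazards[["cause2"]] *
    exp(iptwcr:::.linpred(X, cfg$hazard_coefs$cause2, a))
  t_new <- pmin(rexp(1e4, l1), rexp(1e4, l2))
  ks <- suppressWarnings(ks.test(tab$time_years, t_new))
  expect_gt(ks$p.value, 0.01)
})

test_that("MAR masking has the implied rates and never touches outcomes", {
  cfg <- registry_config(n = 1e4, seed = 9)
  tab <- simulate_registry(cfg)

  # intercept-only logit of 0 masks about half
  m1 <- inject_missingness(tab, list(recipient_bmi = c(intercept = 0)),
                           seed = 3, config = cfg)
  p <- mean(is.na(m1$recipient_bmi))
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 1e4))

  # default spec: empirical rate within 3 SE of the rate implied by the
  # realized covariates
  md <- inject_missingness(tab, cfg$missing_spec, seed = 4, config = cfg)
  X <- iptwcr:::.registry_design(
    local({ t2 <- tab
            names(t2)[names(t2) == "recipient_blood_group"] <- "blood_group"
            t2 }),
    cfg, pmin((tab$transplant_year - cfg$year0) /
                cfg$censor_admin$entry_window, 1))
  for (nm in names(cfg$missing_spec)) {
    co <- cfg$missing_spec[[nm]]
    eta <- co[["intercept"]]
    for (cn in setdiff(names(co), "intercept"))
      eta <- eta + co[[cn]] * X[, cn]
    pr <- mean(iptwcr:::expit(eta))
    se <- sqrt(pr * (1 - pr) / 1e4)
    expect_lt(abs(mean(is.na(md[[nm]])) - pr), 3 * se)
  }

  # monotone masking in age when the logit has a positive age slope
  m2 <- inject_missingness(tab, list(recipient_bmi = c(
    intercept = -1, recipient_age_z = 1.5)), seed = 5, config = cfg)
  q <- cut(tab$recipient_age, quantile(tab$recipient_age, 0:4 / 4),
           include.lowest = TRUE)
  rates <- tapply(is.na(m2$recipient_bmi), q, mean)
  expect_true(all(diff(rates) > 0))

  # outcome and treatment can never be masked
  expect_error(inject_missingness(tab, list(treatment = c(intercept = 0))),
               "outcome or treatment")
  expect_true(!anyNA(md$time_years) && !anyNA(md$event) &&
                !anyNA(md$treatment))
})

test_that("potential-outcomes oracle matches closed forms and scales", {
  # null treatment effect: all true contrasts are zero up to MC error
  hz <- iptwcr:::.default_hazard_coefs()
  hz$cause1["treatment"] <- 0; hz$cause2["treatment"] <- 0
  cfg0 <- registry_config(seed = 8, hazard_coefs = hz)
  tr0 <- oracle_true_effects(cfg0, oracle_n = 1e5)
  expect_true(all(abs(tr0$value) <= 3 * tr0$mc_se))

  # no covariate effects: two-cause exponential closed form
  hz <- iptwcr:::.default_hazard_coefs()
  hz$cause1[] <- 0; hz$cause2[] <- 0
  hz$cause1["treatment"] <- -0.7
  cfg1 <- registry_config(seed = 8, hazard_coefs = hz,
                          baseline_hazards = c(cause1 = 0.05,
                                               cause2 = 0.05))
  tr1 <- oracle_true_effects(cfg1, oracle_n = 2e5, horizons = 5)
  cif <- function(a, t) {
    r1 <- 0.05 * exp(-0.7 * a); r2 <- 0.05
    r1 / (r1 + r2) * (1 - exp(-(r1 + r2) * t))
  }
  truth <- cif(0, 5) - cif(1, 5)
  got <- tr1$value[tr1$estimand == "risk_difference"]
  expect_lt(abs(got - truth),
            3 * tr1$mc_se[tr1$estimand == "risk_difference"])

  # doubling the Monte-Carlo size halves the MC standard error
  cfg <- registry_config(seed = 8)
  se1 <- oracle_true_effects(cfg, oracle_n = 1e5, horizons = 5)$mc_se[1]
  se2 <- oracle_true_effects(cfg, oracle_n = 2e5, horizons = 5)$mc_se[1]
  expect_lt(abs(se1 / se2 - sqrt(2)), 0.1 * sqrt(2))

  expect_error(oracle_true_effects(cfg, oracle_n = 100), "1e5")
})
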