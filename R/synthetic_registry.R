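## Synthetic transplant-registry generator with known ground truth.
##
## Generative family: cause-specific exponential hazards with log-linear
## covariate effects, a logistic treatment-assignment model on the same
## covariates (confounding by construction), uniform study entry with a
## fixed administrative cutoff (censoring), and MAR missingness driven by
## fully observed covariates.  The closed forms of the exponential family
## give analytic oracles for the estimators; a Monte-Carlo potential-
## outcomes oracle gives the true causal contrasts for any configuration.

.default_covariate_spec <- function() {
  list(
    recipient_age = list(type = "continuous", mean = 50.5, sd = 13.5),
    donor_age     = list(type = "continuous", mean = 47.9, sd = 13.1),
    recipient_bmi = list(type = "continuous", mean = 27.3, sd = 5.2),
    recipient_sex = list(type = "categorical",
                         levels = c("female", "male"), probs = c(0.38, 0.62)),
    ethnicity     = list(type = "categorical",
                         levels = c("white", "asian", "black", "other"),
                         probs = c(0.74, 0.13, 0.08, 0.05)),
    blood_group   = list(type = "categorical",
                         levels = c("O", "A", "B", "AB"),
                         probs = c(0.44, 0.42, 0.10, 0.04)),
    cmv_status    = list(type = "categorical",
                         levels = c("negative", "positive"),
                         probs = c(0.45, 0.55)),
    prd           = list(type = "categorical",
                         levels = c("glomerulonephritis", "diabetes",
                                    "polycystic", "hypertension", "other"),
                         probs = c(0.25, 0.17, 0.15, 0.08, 0.35)),
    imd_quintile  = list(type = "categorical",
                         levels = c("1", "2", "3", "4", "5"),
                         probs = c(0.24, 0.21, 0.20, 0.18, 0.17))
  )
}

## Design columns used by ps_coefs / hazard_coefs / missing_spec.
.design_cols <- c(
  "recipient_age_z", "donor_age_z", "recipient_bmi_z",
  "recipient_sex_male", "ethnicity_asian", "ethnicity_black",
  "ethnicity_other", "blood_group_A", "blood_group_B", "blood_group_AB",
  "cmv_positive", "prd_diabetes", "prd_polycystic", "prd_hypertension",
  "prd_other", "imd_centered", "year_z")

.zero_coefs <- function(extra = character()) {
  stats::setNames(numeric(length(.design_cols) + length(extra)),
                  c(.design_cols, extra))
}

.default_ps_coefs <- function() {
  b <- .zero_coefs("intercept")
  b["intercept"] <- -0.58
  b["recipient_age_z"] <- -0.45
  b["donor_age_z"] <- -0.25
  b["recipient_bmi_z"] <- -0.10
  b["recipient_sex_male"] <- -0.05
  b["ethnicity_asian"] <- -0.45
  b["ethnicity_black"] <- -0.55
  b["ethnicity_other"] <- -0.20
  b["blood_group_A"] <- 0.05
  b["blood_group_B"] <- -0.25
  b["blood_group_AB"] <- -0.15
  b["cmv_positive"] <- -0.15
  b["prd_diabetes"] <- -0.35
  b["prd_polycystic"] <- 0.15
  b["prd_hypertension"] <- -0.10
  b["prd_other"] <- -0.05
  b["imd_centered"] <- -0.17
  b["year_z"] <- 0.05
  b
}

.default_hazard_coefs <- function() {
  b1 <- .zero_coefs("treatment")
  b1["recipient_age_z"] <- 0.10
  b1["donor_age_z"] <- 0.22
  b1["recipient_bmi_z"] <- 0.10
  b1["ethnicity_black"] <- 0.35
  b1["ethnicity_asian"] <- 0.12
  b1["prd_diabetes"] <- 0.28
  b1["prd_polycystic"] <- -0.15
  b1["prd_hypertension"] <- 0.10
  b1["imd_centered"] <- 0.08
  b1["year_z"] <- -0.05
  b1["treatment"] <- -0.68
  b2 <- .zero_coefs("treatment")
  b2["recipient_age_z"] <- 0.80
  b2["recipient_bmi_z"] <- 0.08
  b2["recipient_sex_male"] <- 0.10
  b2["cmv_positive"] <- 0.08
  b2["prd_diabetes"] <- 0.45
  b2["imd_centered"] <- 0.07
  b2["treatment"] <- -0.30
  list(cause1 = b1, cause2 = b2)
}

.default_missing_spec <- function() {
  list(
    prd           = c(intercept = -0.85, recipient_age_z = 0.25,
                      year_z = -0.30),
    recipient_bmi = c(intercept = -1.10, recipient_age_z = 0.20),
    imd_quintile  = c(intercept = -1.40, year_z = 0.40)
  )
}

#' Configuration for the synthetic registry generator
#'
#' Defaults emulate the structure of a UK kidney-transplant registry
#' extract: roughly 31.6 percent living-donor (treated) transplants,
#' confounders that influence both donor type and both cause-specific
#' hazards, about 13 percent graft failures and 13 percent deaths with a
#' functioning graft over follow-up, administrative censoring from uniform
#' study entry over a 12-year window, and MAR missingness concentrated in
#' primary renal disease, BMI and deprivation quintile.
#'
#' @param n subject count (default 10915, the base-analysis size emulated).
#' @param seed integer master seed; every RNG stage derives a fixed
#'   sub-seed from it.
#' @param covariate_spec distributions of baseline covariates (normal for
#'   continuous, category probabilities for categorical).
#' @param ps_coefs named true propensity log-odds coefficients on the
#'   standardized design columns (plus `intercept`).
#' @param hazard_coefs list with elements `cause1` (graft failure) and
#'   `cause2` (death), each a named log-hazard coefficient vector on the
#'   design columns plus a `treatment` coefficient.
#' @param baseline_hazards constant cause-specific baseline rates per year,
#'   `c(cause1 = , cause2 = )`.
#' @param censor_admin list with `study_years` (time from first entry to
#'   administrative cutoff) and `entry_window` (uniform-entry span); the
#'   censoring time is `study_years - entry`, with entry uniform on
#'   `[0, entry_window]`.
#' @param missing_spec per-variable MAR missingness logit coefficients on
#'   fully observed design columns (plus `intercept`), or `NULL` for no
#'   missingness.
#' @param year0 calendar year of first possible entry (cosmetic; sets the
#'   `transplant_year` column).
#' @return An object of class `registry_config`.
#' @export
registry_config <- function(n = 10915, seed = 1,
                            covariate_spec = .default_covariate_spec(),
                            ps_coefs = .default_ps_coefs(),
                            hazard_coefs = .default_hazard_coefs(),
                            baseline_hazards = c(cause1 = 0.031,
                                                 cause2 = 0.019),
                            censor_admin = list(study_years = 12,
                                                entry_window = 11.5),
                            missing_spec = .default_missing_spec(),
                            year0 = 2010) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n))
    stop_iptwcr("n must be an integer >= 2")
  for (nm in names(covariate_spec)) {
    cs <- covariate_spec[[nm]]
    if (cs$type == "categorical") {
      if (abs(sum(cs$probs) - 1) > 1e-12)
        stop_iptwcr("category probabilities for '", nm,
                    "' must sum to 1 (got ", sum(cs$probs), ")")
      if (any(cs$probs < 0 | cs$probs > 1))
        stop_iptwcr("category probabilities for '", nm,
                    "' must lie in [0, 1]")
    }
  }
  if (any(baseline_hazards <= 0))
    stop_iptwcr("baseline hazards must be strictly positive")
  if (censor_admin$study_years <= 0 || censor_admin$entry_window < 0 ||
      censor_admin$entry_window >= censor_admin$study_years)
    stop_iptwcr("censoring horizon must be positive and exceed the entry window")
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         covariate_spec = covariate_spec, ps_coefs = ps_coefs,
         hazard_coefs = hazard_coefs, baseline_hazards = baseline_hazards,
         censor_admin = censor_admin, missing_spec = missing_spec,
         year0 = year0),
    class = "registry_config")
}

## Draw baseline covariates for n subjects (sub-seeded).
.draw_covariates <- function(config, n, seed) {
  set.seed(seed)
  spec <- config$covariate_spec
  out <- list()
  for (nm in names(spec)) {
    cs <- spec[[nm]]
    out[[nm]] <- if (cs$type == "continuous") {
      stats::rnorm(n, cs$mean, cs$sd)
    } else {
      factor(sample(cs$levels, n, replace = TRUE, prob = cs$probs),
             levels = cs$levels)
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

## Standardized design matrix on the fixed column set.  Standardization
## constants are the generator's specification means/SDs, so a design built
## from a subset of rows is identical to the subset of the full design.
.registry_design <- function(covs, config, entry_frac = NULL) {
  spec <- config$covariate_spec
  zc <- function(nm) {
    cs <- spec[[nm]]
    (covs[[nm]] - cs$mean) / cs$sd
  }
  X <- cbind(
    recipient_age_z = zc("recipient_age"),
    donor_age_z = zc("donor_age"),
    recipient_bmi_z = zc("recipient_bmi"),
    recipient_sex_male = as.numeric(covs$recipient_sex == "male"),
    ethnicity_asian = as.numeric(covs$ethnicity == "asian"),
    ethnicity_black = as.numeric(covs$ethnicity == "black"),
    ethnicity_other = as.numeric(covs$ethnicity == "other"),
    blood_group_A = as.numeric(covs$blood_group == "A"),
    blood_group_B = as.numeric(covs$blood_group == "B"),
    blood_group_AB = as.numeric(covs$blood_group == "AB"),
    cmv_positive = as.numeric(covs$cmv_status == "positive"),
    prd_diabetes = as.numeric(covs$prd == "diabetes"),
    prd_polycystic = as.numeric(covs$prd == "polycystic"),
    prd_hypertension = as.numeric(covs$prd == "hypertension"),
    prd_other = as.numeric(covs$prd == "other"),
    imd_centered = as.numeric(as.character(covs$imd_quintile)) - 3,
    year_z = if (is.null(entry_frac)) rep(0, nrow(covs))
             else (entry_frac - 0.5) * 2)
  X
}

.linpred <- function(X, coefs, treatment = NULL) {
  ## names absent from coefs contribute zero, so sparse coefficient
  ## vectors (e.g. intercept-only) are valid
  use <- intersect(colnames(X), names(coefs))
  eta <- as.vector(X[, use, drop = FALSE] %*% coefs[use])
  if (!is.null(coefs["intercept"]) && "intercept" %in% names(coefs))
    eta <- eta + coefs[["intercept"]]
  if (!is.null(treatment) && "treatment" %in% names(coefs))
    eta <- eta + treatment * coefs[["treatment"]]
  eta
}

#' Generate a synthetic registry cohort
#'
#' Draws baseline covariates, assigns living-donor treatment from the true
#' propensity model, draws latent cause-specific exponential event times
#' (cause 1 = graft failure, cause 2 = death with functioning graft),
#' applies administrative censoring from uniform study entry, and optionally
#' masks confounders under the MAR missingness model.  Deterministic for a
#' fixed configuration seed.
#'
#' @param config a [registry_config()].
#' @param apply_missingness mask confounders per `config$missing_spec`
#'   (default `FALSE`: fully observed cohort).
#' @return A `data.frame` with columns `subject_id`, `treatment` (1 =
#'   living donor), `time_years`, `event` (0/1/2), the baseline covariates,
#'   `transplant_year`, `donor_blood_group`, `centre_type`,
#'   `hla_mismatch_level` and `kss_or_altruistic`.  The true propensity
#'   score is attached as attribute `true_ps`.
#' @export
simulate_registry <- function(config, apply_missingness = FALSE) {
  stopifnot(inherits(config, "registry_config"))
  n <- config$n
  covs <- .draw_covariates(config, n, stage_seed(config$seed, "covariates"))

  set.seed(stage_seed(config$seed, "censoring"))
  entry <- stats::runif(n, 0, config$censor_admin$entry_window)
  entry_frac <- entry / max(config$censor_admin$entry_window, 1e-12)
  censor_time <- config$censor_admin$study_years - entry

  X <- .registry_design(covs, config, entry_frac)

  set.seed(stage_seed(config$seed, "treatment"))
  ps <- expit(.linpred(X, config$ps_coefs))
  if (any(ps < 0.01 | ps > 0.99))
    warning("true propensity scores outside [0.01, 0.99] for ",
            sum(ps < 0.01 | ps > 0.99),
            " subjects: positivity is stressed", call. = FALSE)
  a <- stats::rbinom(n, 1, ps)

  set.seed(stage_seed(config$seed, "events"))
  u1 <- stats::runif(n); u2 <- stats::runif(n)
  lam1 <- config$baseline_hazards[["cause1"]] *
    exp(.linpred(X, config$hazard_coefs$cause1, a))
  lam2 <- config$baseline_hazards[["cause2"]] *
    exp(.linpred(X, config$hazard_coefs$cause2, a))
  t1 <- -log(u1) / lam1
  t2 <- -log(u2) / lam2
  t_event <- pmin(t1, t2)
  obs_time <- pmin(t_event, censor_time)
  event <- ifelse(t_event <= censor_time, ifelse(t1 <= t2, 1L, 2L), 0L)

  set.seed(stage_seed(config$seed, "admin"))
  ## Administrative columns for eligibility and subgroup analyses; the
  ## generated cohort is ABO-compatible by construction.
  compat <- list(O = c("O"), A = c("O", "A"), B = c("O", "B"),
                 AB = c("O", "A", "B", "AB"))
  dbg <- vapply(as.character(covs$blood_group), function(r) {
    opts <- compat[[r]]
    sample(opts, 1)
  }, character(1))
  hla <- sample(1:4, n, replace = TRUE, prob = c(0.12, 0.35, 0.33, 0.20))
  kss <- as.integer(a == 1 & stats::runif(n) < 0.18)

  tab <- data.frame(
    subject_id = sprintf("S%06d", seq_len(n)),
    treatment = a,
    time_years = pmax(obs_time, 0.5 / 365.25),
    event = event,
    covs,
    transplant_year = config$year0 + floor(entry),
    donor_blood_group = unname(dbg),
    centre_type = "mixed",
    hla_mismatch_level = hla,
    kss_or_altruistic = kss,
    stringsAsFactors = FALSE)
  names(tab)[names(tab) == "blood_group"] <- "recipient_blood_group"
  attr(tab, "true_ps") <- ps
  if (apply_missingness && !is.null(config$missing_spec))
    tab <- inject_missingness(tab, config$missing_spec,
                              seed = stage_seed(config$seed, "missingness"),
                              config = config)
  tab
}

#' Mask confounders under a MAR missingness model
#'
#' Sets selected covariate entries to `NA` with probability
#' `plogis(intercept + x . coefs)` computed on fully observed covariates.
#' Outcome, time and treatment columns can never be masked.
#'
#' @param table a cohort `data.frame` (as from [simulate_registry()]).
#' @param missing_spec named list: per target variable, a named logit
#'   coefficient vector over `intercept` and design columns.
#' @param seed integer seed.
#' @param config optional [registry_config()] supplying standardization
#'   constants for the design (defaults to the generator defaults).
#' @return The table with masked entries set to `NA`.
#' @export
inject_missingness <- function(table, missing_spec, seed = 1,
                               config = registry_config(n = 2)) {
  protected <- c("subject_id", "treatment", "time_years", "event")
  bad <- intersect(names(missing_spec), protected)
  if (length(bad))
    stop_iptwcr("missingness must not target outcome or treatment columns: ",
                paste(bad, collapse = ", "))
  absent <- setdiff(names(missing_spec), names(table))
  if (length(absent))
    stop_iptwcr("missingness targets absent from table: ",
                paste(absent, collapse = ", "))
  covs <- table
  names(covs)[names(covs) == "recipient_blood_group"] <- "blood_group"
  yr <- if ("transplant_year" %in% names(table)) {
    w <- max(config$censor_admin$entry_window, 1e-12)
    pmin((table$transplant_year - config$year0) / w, 1)
  } else NULL
  X <- .registry_design(covs, config, entry_frac = yr)
  set.seed(seed)
  for (nm in names(missing_spec)) {
    co <- missing_spec[[nm]]
    eta <- rep(co[["intercept"]] %||% 0, nrow(table))
    for (cn in setdiff(names(co), "intercept")) {
      if (!cn %in% colnames(X))
        stop_iptwcr("unknown missingness predictor: ", cn)
      eta <- eta + co[[cn]] * X[, cn]
    }
    mask <- stats::runif(nrow(table)) < expit(eta)
    table[[nm]][mask] <- NA
  }
  table
}

#' Monte-Carlo potential-outcomes oracle for the true causal contrasts
#'
#' Simulates `oracle_n` subjects from the configuration's covariate and
#' hazard models twice -- treatment forced to 1 and to 0, with common
#' random numbers for the latent event times -- without censoring, and
#' returns the true marginal cause-1 risk differences at each horizon and
#' the true restricted-mean-time-lost difference at `tau`, with Monte-Carlo
#' standard errors from the paired differences.
#'
#' @param config a [registry_config()].
#' @param oracle_n Monte-Carlo sample size (>= 1e5).
#' @param horizons risk-difference horizons in years.
#' @param tau restriction horizon for the RMTL contrast.
#' @param cause cause of interest (1 graft failure, 2 death).
#' @return A `data.frame` (class `simulation_truth`) with columns
#'   `estimand`, `horizon`, `value`, `mc_se`; values are control minus
#'   treated risks, so positive = living-donor benefit.
#' @export
oracle_true_effects <- function(config, oracle_n = 2e5, horizons = 1:7,
                                tau = 7, cause = 1) {
  stopifnot(inherits(config, "registry_config"))
  if (oracle_n < 1e5)
    stop_iptwcr("oracle_n must be at least 1e5")
  seed <- stage_seed(config$seed, "oracle")
  covs <- .draw_covariates(config, oracle_n, seed)
  set.seed(derive_seed(seed, 1))
  entry_frac <- stats::runif(oracle_n)
  X <- .registry_design(covs, config, entry_frac)
  u1 <- stats::runif(oracle_n); u2 <- stats::runif(oracle_n)

  draw_po <- function(a) {
    lam1 <- config$baseline_hazards[["cause1"]] *
      exp(.linpred(X, config$hazard_coefs$cause1, a))
    lam2 <- config$baseline_hazards[["cause2"]] *
      exp(.linpred(X, config$hazard_coefs$cause2, a))
    t1 <- -log(u1) / lam1
    t2 <- -log(u2) / lam2
    list(time = pmin(t1, t2), cause = ifelse(t1 <= t2, 1L, 2L))
  }
  po1 <- draw_po(1); po0 <- draw_po(0)

  rows <- lapply(horizons, function(h) {
    i1 <- as.numeric(po1$time <= h & po1$cause == cause)
    i0 <- as.numeric(po0$time <= h & po0$cause == cause)
    d <- i0 - i1                       # control minus treated
    data.frame(estimand = "risk_difference", horizon = h,
               value = mean(d), mc_se = stats::sd(d) / sqrt(oracle_n))
  })
  l1 <- (tau - po1$time) * (po1$time <= tau & po1$cause == cause)
  l0 <- (tau - po0$time) * (po0$time <= tau & po0$cause == cause)
  d <- l0 - l1
  rows <- c(rows, list(data.frame(
    estimand = "rmtl_difference", horizon = tau,
    value = mean(d), mc_se = stats::sd(d) / sqrt(oracle_n))))
  out <- do.call(rbind, rows)
  attr(out, "oracle_n") <- oracle_n
  class(out) <- c("simulation_truth", "data.frame")
  out
}
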