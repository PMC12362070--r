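## The central estimator: IPTW-adjusted competing-risks causal contrasts.

#' E-value for unmeasured confounding from two risks
#'
#' The minimum strength of association, on the risk-ratio scale, that an
#' unmeasured confounder would need with both treatment and outcome to
#' fully explain an observed risk ratio:
#' \deqn{E = RR + \sqrt{RR (RR - 1)}, \quad RR = r_{high} / r_{low}.}
#' Inputs may be proportions or percentages (detected jointly and
#' normalized consistently); if supplied in reversed order they are
#' swapped with a warning so that RR >= 1.
#'
#' @param risk_high,risk_low the two cumulative risks.
#' @return E-value (>= 1; equals 1 when RR = 1).
#' @export
evalue_from_risks <- function(risk_high, risk_low) {
  if (risk_high > 1 || risk_low > 1) {   # percentages
    risk_high <- risk_high / 100
    risk_low <- risk_low / 100
  }
  if (risk_low <= 0) stop_iptwcr("the smaller risk must be positive")
  if (risk_high > 1 || risk_low > 1)
    stop_iptwcr("risks must be proportions in (0,1] or percentages")
  if (risk_high < risk_low) {
    warning("risks supplied in reversed order; swapping", call. = FALSE)
    tmp <- risk_high; risk_high <- risk_low; risk_low <- tmp
  }
  rr <- risk_high / risk_low
  rr + sqrt(rr * (rr - 1))
}

## Point-estimate engine.  Takes raw vectors plus a prebuilt propensity
## design matrix so bootstrap replicates can subset rows without rebuilding
## model frames.  Returns risk differences (control minus treated) at the
## horizons, the two per-arm CIFs at the horizons, and restricted-mean
## contrasts at tau.
.contrast_engine <- function(time, event, a, mm, horizons, tau, cause = 1,
                             forced_weights = NULL, stabilized = FALSE,
                             truncate = NULL, max_iter = 100L) {
  if (is.null(forced_weights)) {
    fit <- stats::glm.fit(mm, a, family = stats::binomial(),
                          control = list(epsilon = 1e-12,
                                         maxit = max_iter))
    e <- fit$fitted.values
    if (any(e <= 0) || any(e >= 1)) stop_iptwcr("degenerate propensity scores")
    w <- a / e + (1 - a) / (1 - e)
    if (stabilized) {
      p1 <- mean(a)
      w <- w * ifelse(a == 1, p1, 1 - p1)
    }
    if (!is.null(truncate)) {
      bounds <- stats::quantile(w, c(truncate, 1 - truncate), names = FALSE)
      w <- pmin(pmax(w, bounds[1]), bounds[2])
    }
  } else {
    w <- forced_weights
  }
  ev <- if (cause == 1) event else c(0L, 2L, 1L)[event + 1L]
  arm_curves <- function(sel) {
    aj <- aalen_johansen(time[sel], ev[sel], w[sel])
    list(cif1 = aj$cif1, surv = aj$survival)
  }
  trt <- arm_curves(a == 1)
  ctl <- arm_curves(a == 0)
  cif_trt <- eval_curve(trt$cif1, horizons)
  cif_ctl <- eval_curve(ctl$cif1, horizons)
  list(
    risk_difference = cif_ctl - cif_trt,       # positive = treated benefit
    cif_treated = cif_trt,
    cif_control = cif_ctl,
    rmtl_difference = rmtl(ctl$cif1, tau) - rmtl(trt$cif1, tau),
    rmst_difference = rmst(trt$surv, tau) - rmst(ctl$surv, tau),
    weights = w)
}

.flatten_contrasts <- function(est, horizons, tau) {
  c(est$risk_difference, est$rmtl_difference, est$rmst_difference,
    est$cif_treated, est$cif_control)
}

#' IPTW competing-risks causal contrasts
#'
#' Fits the full causal pipeline on a cohort: propensity-score logistic
#' regression on the declared confounders, unstabilized ATE inverse
#' probability of treatment weights, per-arm weighted Aalen-Johansen
#' cumulative incidence of the event of interest (competing event handled
#' as such), causal risk differences (control minus treated: positive =
#' treated benefit) at each horizon, a restricted-mean contrast at `tau`,
#' bootstrap standard errors with normal 95 percent confidence intervals,
#' and e-values for unmeasured confounding.
#'
#' The primary restricted-mean contrast is the difference in restricted
#' mean time free of the primary event, `tau - RMTL(CIF_cause)`, which
#' treats the competing event as competing and reduces to the ordinary
#' RMST difference when no competing events occur; the all-event RMST
#' difference is also reported.
#'
#' The bootstrap resamples subjects with replacement and refits the
#' propensity model inside every replicate, propagating design
#' uncertainty.  Replicate failures are skipped and counted; more than 10
#' percent failures is an error.
#'
#' @param formula `Surv(time_years, event) ~ treatment` with event codes
#'   0 (censored), 1 (graft failure), 2 (death with functioning graft).
#' @param data cohort `data.frame`, complete in the confounders.
#' @param confounders character vector of confounder columns for the
#'   propensity model.
#' @param horizons risk-difference evaluation times (years), within
#'   `(0, tau]`.
#' @param tau restricted-mean horizon (years).
#' @param cause event of interest: 1 (default) analyses graft failure with
#'   death competing; 2 analyses all-cause death with graft failure
#'   competing.
#' @param n_boot bootstrap resamples (default 250); 0 skips the bootstrap.
#' @param seed integer master seed for the bootstrap.
#' @param stabilized,truncate weight options passed to [compute_iptw()].
#' @param forced_weights optional fixed weights bypassing the propensity
#'   model (e.g. unit weights for the unadjusted analysis).
#' @param allow_mediators passed to [fit_propensity()].
#' @return An object of class `iptw_cmprisk` with components
#'   `contrasts` (per-estimand point/SE/CI/e-value table), `curves`
#'   (per-arm weighted step curves), `propensity`, `weights`, `balance`,
#'   `positivity`, `n_boot_effective`, `call`.
#' @seealso [summary.iptw_cmprisk()], [plot.iptw_cmprisk()]
#' @export
iptw_cmprisk <- function(formula, data, confounders, horizons = 1:7,
                         tau = 7, cause = 1, n_boot = 250, seed = 1,
                         stabilized = FALSE, truncate = NULL,
                         forced_weights = NULL, allow_mediators = FALSE) {
  if (any(horizons <= 0) || any(horizons > tau))
    stop_iptwcr("horizons must lie in (0, tau]")
  if (!cause %in% 1:2) stop_iptwcr("cause must be 1 or 2")
  vars <- .parse_surv_formula(formula, data)
  time <- vars$time; event <- vars$event; a <- vars$treatment
  if (!all(event %in% 0:2)) stop_iptwcr("event codes must be 0/1/2")
  if (!all(a %in% 0:1)) stop_iptwcr("treatment must be 0/1")

  use_ps <- is.null(forced_weights)
  if (use_ps) {
    ps_fit <- fit_propensity(data, confounders,
                             treatment_col = vars$treatment_name,
                             allow_mediators = allow_mediators)
    wset <- compute_iptw(ps_fit, a, stabilized = stabilized,
                         truncate = truncate)
    w <- wset$weights
    mm <- stats::model.matrix(ps_fit$design_spec$formula, data = data)
  } else {
    ps_fit <- NULL; wset <- NULL
    w <- forced_weights
    mm <- NULL
  }

  est <- .contrast_engine(time, event, a, mm, horizons, tau, cause,
                          forced_weights = if (use_ps) NULL else w,
                          stabilized = stabilized, truncate = truncate)
  ## per-arm curves at the point estimate, for plotting/export
  ev <- if (cause == 1) event else c(0L, 2L, 1L)[event + 1L]
  curves <- list(
    treated = aalen_johansen(time[a == 1], ev[a == 1], w[a == 1]),
    control = aalen_johansen(time[a == 0], ev[a == 0], w[a == 0]))

  estimands <- c(sprintf("risk_difference_%gy", horizons),
                 "event_free_time_difference", "rmst_all_event_difference",
                 sprintf("cif_treated_%gy", horizons),
                 sprintf("cif_control_%gy", horizons))
  point <- .flatten_contrasts(est, horizons, tau)
  names(point) <- estimands

  boot_se <- rep(NA_real_, length(point))
  evalue_median <- rep(NA_real_, length(horizons))
  n_eff <- 0L
  if (n_boot > 0) {
    if (n_boot < 2) stop_iptwcr("n_boot must be >= 2 (or 0 to skip)")
    n <- length(time)
    reps <- matrix(NA_real_, n_boot, length(point))
    ev_reps <- matrix(NA_real_, n_boot, length(horizons))
    for (b in seq_len(n_boot)) {
      set.seed(stage_seed(seed, "bootstrap", b))
      idx <- sample.int(n, n, replace = TRUE)
      r <- tryCatch(
        .contrast_engine(time[idx], event[idx], a[idx],
                         if (use_ps) mm[idx, , drop = FALSE] else NULL,
                         horizons, tau, cause,
                         forced_weights = if (use_ps) NULL else w[idx],
                         stabilized = stabilized, truncate = truncate),
        error = function(e) NULL)
      if (!is.null(r)) {
        reps[b, ] <- .flatten_contrasts(r, horizons, tau)
        lo <- pmin(r$cif_treated, r$cif_control)
        hi <- pmax(r$cif_treated, r$cif_control)
        ev_reps[b, ] <- ifelse(lo > 0, hi / lo + sqrt(pmax(
          hi / lo * (hi / lo - 1), 0)), NA)
      }
    }
    ok <- stats::complete.cases(reps)
    n_eff <- sum(ok)
    if (n_eff < 0.9 * n_boot)
      stop_iptwcr("bootstrap unstable: ", n_boot - n_eff, " of ", n_boot,
                  " replicates failed")
    boot_se <- apply(reps[ok, , drop = FALSE], 2, stats::sd)
    evalue_median <- apply(ev_reps[ok, , drop = FALSE], 2, stats::median,
                           na.rm = TRUE)
  }

  ## point e-values from the adjusted per-arm CIFs at each horizon
  ev_point <- vapply(seq_along(horizons), function(i) {
    lo <- min(est$cif_treated[i], est$cif_control[i])
    hi <- max(est$cif_treated[i], est$cif_control[i])
    if (lo <= 0) return(NA_real_)
    evalue_from_risks(hi, lo)
  }, numeric(1))

  contrasts <- data.frame(
    estimand = estimands,
    horizon = c(horizons, tau, tau, horizons, horizons),
    point = unname(point),
    boot_se = boot_se,
    ci_low = unname(point) - 1.96 * boot_se,
    ci_high = unname(point) + 1.96 * boot_se,
    e_value = NA_real_,
    e_value_boot_median = NA_real_)
  is_rd <- seq_along(horizons)
  contrasts$e_value[is_rd] <- ev_point
  contrasts$e_value_boot_median[is_rd] <- evalue_median

  structure(list(
    call = match.call(),
    contrasts = contrasts,
    curves = curves,
    horizons = horizons, tau = tau, cause = cause,
    propensity = ps_fit,
    weights = wset %||% list(weights = w, estimand = "forced"),
    balance = if (use_ps) balance_table(data, confounders, w,
                                        vars$treatment_name) else NULL,
    positivity = if (use_ps) positivity_diagnostics(ps_fit, a) else NULL,
    n = length(time), n_treated = sum(a),
    n_boot = n_boot, n_boot_effective = n_eff, seed = seed),
    class = "iptw_cmprisk")
}

## Minimal Surv-style formula parser: LHS Surv(time, event) (the survival
## package need not be attached), RHS a single treatment variable.
.parse_surv_formula <- function(formula, data) {
  lhs <- formula[[2]]
  if (!is.call(lhs) || !identical(as.character(lhs[[1]]), "Surv"))
    stop_iptwcr("formula must be Surv(time, event) ~ treatment")
  time <- eval(lhs[[2]], data, environment(formula))
  event <- eval(lhs[[3]], data, environment(formula))
  rhs <- all.vars(formula[[3]])
  if (length(rhs) != 1)
    stop_iptwcr("right-hand side must be a single treatment variable")
  list(time = time, event = as.integer(event),
       treatment = data[[rhs]], treatment_name = rhs)
}

#' Bootstrap a user-supplied estimator
#'
#' Generic row-resampling bootstrap: resamples subjects with replacement,
#' applies `estimator` (a function of the resampled data returning a
#' numeric vector) to each replicate, and returns the replicate standard
#' deviations as standard errors with normal 95 percent confidence
#' intervals about the full-data point estimate.  Per-replicate seeds are
#' derived from the master seed by replicate index, so results do not
#' depend on execution order; failed replicates are skipped and counted,
#' with more than 10 percent failures an error.
#'
#' @param data `data.frame` of subjects.
#' @param estimator `function(data) -> named numeric vector`.
#' @param n_boot number of resamples (default 250).
#' @param seed integer master seed.
#' @return List with `point`, `boot_se`, `ci_low`, `ci_high`,
#'   `n_boot_effective`, `replicates` (matrix).
#' @export
bootstrap_pipeline <- function(data, estimator, n_boot = 250, seed = 1) {
  if (n_boot < 2) stop_iptwcr("n_boot must be >= 2")
  point <- estimator(data)
  n <- nrow(data)
  reps <- matrix(NA_real_, n_boot, length(point),
                 dimnames = list(NULL, names(point)))
  for (b in seq_len(n_boot)) {
    set.seed(stage_seed(seed, "bootstrap", b))
    idx <- sample.int(n, n, replace = TRUE)
    r <- tryCatch(estimator(data[idx, , drop = FALSE]),
                  error = function(e) NULL)
    if (!is.null(r)) reps[b, ] <- r
  }
  ok <- stats::complete.cases(reps)
  if (sum(ok) < 0.9 * n_boot)
    stop_iptwcr("bootstrap unstable: ", n_boot - sum(ok), " of ", n_boot,
                " replicates failed")
  se <- apply(reps[ok, , drop = FALSE], 2, stats::sd)
  list(point = point, boot_se = se,
       ci_low = point - 1.96 * se, ci_high = point + 1.96 * se,
       n_boot_effective = sum(ok), replicates = reps[ok, , drop = FALSE])
}
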