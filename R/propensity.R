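## Propensity model, ATE weights, balance and positivity diagnostics.

## Known treatment-consequence variables that would mediate the effect of
## donor type on outcome; they must not enter the propensity model.
MEDIATOR_BLOCKLIST <- c("cold_ischaemia_time", "hla_mismatch_level",
                        "waiting_time")

#' Fit the propensity model
#'
#' Maximum-likelihood logistic regression of treatment on the declared
#' confounders (iteratively reweighted least squares via [stats::glm()]),
#' with categorical covariates reference-level dummy-coded (reference =
#' first declared level).  Rows with missing confounders are rejected:
#' this is the complete-case path; use [impute_chained()] for the MI path.
#' Known mediators of donor type (cold ischaemia time, HLA mismatch level,
#' waiting time) are refused unless explicitly overridden for sensitivity
#' analysis.
#'
#' @param table cohort `data.frame`.
#' @param confounders character vector of confounder column names.
#' @param treatment_col treatment column (0/1).
#' @param allow_mediators permit blocklisted mediator columns (the
#'   HLA-in-propensity-score sensitivity switch).
#' @param tol convergence tolerance on the score equations (default 1e-8).
#' @param max_iter maximum IRLS iterations (default 100).
#' @return An object of class `propensity_fit`: named `coefficients`,
#'   fitted `scores` in (0,1), `converged`, `iterations`, and the
#'   `design_spec` (terms and reference levels) used.
#' @export
fit_propensity <- function(table, confounders, treatment_col = "treatment",
                           allow_mediators = FALSE, tol = 1e-8,
                           max_iter = 100L) {
  absent <- setdiff(confounders, names(table))
  if (length(absent))
    stop_iptwcr("confounders absent from table: ",
                paste(absent, collapse = ", "))
  med <- intersect(confounders, MEDIATOR_BLOCKLIST)
  if (length(med) && !allow_mediators)
    stop_iptwcr("mediator(s) of donor type in the confounder set: ",
                paste(med, collapse = ", "),
                " (set allow_mediators = TRUE only for sensitivity analysis)")
  cc <- stats::complete.cases(table[, c(treatment_col, confounders),
                                    drop = FALSE])
  if (!all(cc))
    stop_iptwcr(sum(!cc), " row(s) have missing confounders; ",
                "supply complete cases or impute first")
  ff <- if (length(confounders))
    stats::reformulate(confounders, response = treatment_col)
  else stats::as.formula(paste(treatment_col, "~ 1"))
  mm <- stats::model.matrix(ff, data = table)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    drop_cols <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop_iptwcr("rank-deficient design; collinear column(s): ",
                paste(drop_cols, collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm.fit(mm, table[[treatment_col]],
                   family = stats::binomial(),
                   control = list(epsilon = 1e-12, maxit = max_iter)))
  scores <- fit$fitted.values
  ## score equations: X'(A - e) = 0 at the MLE
  score_resid <- max(abs(crossprod(mm, table[[treatment_col]] - scores)))
  if (any(scores < 1e-8) || any(scores > 1 - 1e-8))
    stop_iptwcr("(quasi-)perfect separation detected: fitted scores reach ",
                "0/1; the propensity model is not identifiable")
  structure(list(
    coefficients = fit$coefficients,
    scores = scores,
    converged = fit$converged && score_resid < tol * nrow(mm),
    iterations = fit$iter,
    score_residual = score_resid,
    design_spec = list(formula = ff, columns = colnames(mm),
                       reference_levels = lapply(
                         Filter(is.factor, table[confounders]),
                         function(f) levels(f)[1]))),
    class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat(sprintf("Propensity model: %d coefficient(s), %s in %d iteration(s)\n",
              length(x$coefficients),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  score range [%.4f, %.4f]\n", min(x$scores), max(x$scores)))
  invisible(x)
}

#' Inverse probability of treatment weights (ATE)
#'
#' `w = A/e + (1-A)/(1-e)`: treated subjects weighted by the reciprocal of
#' their propensity score, controls by the reciprocal of its complement,
#' creating a pseudo-population in which measured confounders are balanced
#' and contrasts target the average treatment effect.
#'
#' @param fit a [fit_propensity()] object, or a numeric vector of scores.
#' @param treatment 0/1 treatment vector aligned to the scores.
#' @param stabilized multiply by the marginal treatment prevalence
#'   (default `FALSE`: unstabilized ATE weights).
#' @param truncate optional percentile `p` in (0, 0.5): weights capped at
#'   the empirical `[p, 1-p]` quantiles, count capped recorded.
#' @return An object of class `weight_set`: `weights`, `estimand`,
#'   `stabilized`, `truncation` metadata.
#' @export
compute_iptw <- function(fit, treatment, stabilized = FALSE,
                         truncate = NULL) {
  e <- if (inherits(fit, "propensity_fit")) fit$scores else fit
  if (length(e) != length(treatment))
    stop_iptwcr("scores and treatment must be aligned")
  if (any(e <= 0 | e >= 1))
    stop_iptwcr("propensity scores must lie strictly inside (0,1)")
  w <- treatment / e + (1 - treatment) / (1 - e)
  if (stabilized) {
    p1 <- mean(treatment)
    w <- w * ifelse(treatment == 1, p1, 1 - p1)
  }
  truncation <- NULL
  if (!is.null(truncate)) {
    if (truncate <= 0 || truncate >= 0.5)
      stop_iptwcr("truncate must be a percentile in (0, 0.5)")
    bounds <- stats::quantile(w, c(truncate, 1 - truncate), names = FALSE)
    n_capped <- sum(w < bounds[1] | w > bounds[2])
    w <- pmin(pmax(w, bounds[1]), bounds[2])
    truncation <- list(percentile = truncate, bounds = bounds,
                       n_capped = n_capped)
  }
  structure(list(weights = w, estimand = "ATE", stabilized = stabilized,
                 truncation = truncation),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("%s%s IPTW weights: n = %d, range [%.3f, %.3f], sum %.1f\n",
              if (x$stabilized) "stabilized " else "",
              x$estimand, length(x$weights), min(x$weights),
              max(x$weights), sum(x$weights)))
  if (!is.null(x$truncation))
    cat(sprintf("  truncated at [%.3f, %.3f] (%d capped)\n",
                x$truncation$bounds[1], x$truncation$bounds[2],
                x$truncation$n_capped))
  invisible(x)
}

#' Standardized mean difference
#'
#' Between-arm mean difference divided by the pooled standard deviation
#' \eqn{\sqrt{(s_1^2 + s_0^2)/2}}, signed (arm 1 minus arm 0).  With
#' weights, weighted means and weighted variances are used.  A zero pooled
#' SD with equal means gives 0; with unequal means, signed infinity.
#'
#' @param x continuous covariate or binary level indicator.
#' @param treatment 0/1 arm indicator.
#' @param weights optional positive weights.
#' @return Signed SMD.
#' @export
standardized_mean_difference <- function(x, treatment, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(x))
  i1 <- treatment == 1; i0 <- treatment == 0
  if (!any(i1) || !any(i0)) stop_iptwcr("both arms must be non-empty")
  m1 <- wmean(x[i1], weights[i1]); m0 <- wmean(x[i0], weights[i0])
  v1 <- wvar(x[i1], weights[i1]); v0 <- wvar(x[i0], weights[i0])
  pooled <- sqrt((v1 + v0) / 2)
  if (pooled == 0) {
    if (m1 == m0) return(0)
    return(sign(m1 - m0) * Inf)
  }
  (m1 - m0) / pooled
}

#' Covariate balance before and after weighting
#'
#' SMDs for every confounder (one row per level for categoricals, treated
#' as binary indicators) before weighting (unit weights) and after
#' (supplied weights), flagging |SMD| > 0.1 after weighting as imbalance.
#'
#' @param table cohort `data.frame`.
#' @param confounders character vector of confounder columns.
#' @param weights a [compute_iptw()] object or numeric weights.
#' @param treatment_col treatment column.
#' @return A `data.frame` `variable`, `level`, `smd_before`, `smd_after`,
#'   `imbalanced` (class `balance_table`).
#' @export
balance_table <- function(table, confounders, weights,
                          treatment_col = "treatment") {
  if (inherits(weights, "weight_set")) weights <- weights$weights
  a <- table[[treatment_col]]
  rows <- list()
  for (nm in confounders) {
    x <- table[[nm]]
    if (is.numeric(x)) {
      items <- list(list(level = NA_character_, x = x))
    } else {
      f <- factor(x)
      items <- lapply(levels(f), function(l)
        list(level = l, x = as.numeric(f == l)))
    }
    for (it in items) {
      sb <- standardized_mean_difference(it$x, a)
      sa <- standardized_mean_difference(it$x, a, weights)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, level = it$level, smd_before = sb, smd_after = sa,
        imbalanced = abs(sa) > 0.1)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("balance_table", "data.frame")
  out
}

#' Positivity diagnostics
#'
#' Summaries of propensity-score overlap between arms: per-arm score range
#' and quantiles, and the count of scores outside [0.01, 0.99].
#'
#' @param fit a [fit_propensity()] object (or numeric scores).
#' @param treatment 0/1 vector aligned to the scores.
#' @param bounds extreme-score bounds (default `c(0.01, 0.99)`).
#' @return A list (class `positivity_report`).
#' @export
positivity_diagnostics <- function(fit, treatment,
                                   bounds = c(0.01, 0.99)) {
  e <- if (inherits(fit, "propensity_fit")) fit$scores else fit
  qs <- c(0, 0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99, 1)
  per_arm <- lapply(split(e, treatment), function(s)
    list(min = min(s), max = max(s),
         quantiles = stats::quantile(s, qs, names = TRUE)))
  structure(list(
    n = length(e),
    n_extreme = sum(e < bounds[1] | e > bounds[2]),
    bounds = bounds,
    per_arm = per_arm),
    class = "positivity_report")
}

#' @export
print.positivity_report <- function(x, ...) {
  cat(sprintf("Positivity: %d of %d score(s) outside [%.2f, %.2f]\n",
              x$n_extreme, x$n, x$bounds[1], x$bounds[2]))
  for (a in names(x$per_arm))
    cat(sprintf("  arm %s: scores in [%.4f, %.4f]\n", a,
                x$per_arm[[a]]$min, x$per_arm[[a]]$max))
  invisible(x)
}
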