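## Multiple imputation by chained equations and Rubin's-rules pooling.
##
## Survival-aware imputation: every conditional model's predictors include
## treatment, the other confounders, per-cause event indicators and log
## follow-up time.  Continuous targets are imputed by Bayesian linear
## regression draws (posterior draw of the error variance and
## coefficients, then a noisy prediction); categorical targets by
## multinomial logistic draws (fitted class probabilities sampled per
## missing entry).

#' Multiple imputation of missing confounders by chained equations
#'
#' @param table cohort `data.frame`; missingness allowed only in the
#'   declared confounders -- `subject_id`, treatment, time and event must
#'   be fully observed.
#' @param confounders character vector of confounder columns (imputation
#'   targets and predictors).
#' @param m number of completed tables (default 10).
#' @param max_iter chained-equation sweeps per table (default 10).
#' @param seed integer master seed; chain `i` uses a fixed sub-seed.
#' @param treatment_col,time_col,event_col column names.
#' @return An object of class `imputation_set`: `m`, `tables` (list of
#'   completed data frames), `method_per_variable`, `seed`.
#' @export
impute_chained <- function(table, confounders, m = 10, max_iter = 10,
                           seed = 1, treatment_col = "treatment",
                           time_col = "time_years", event_col = "event") {
  outcome_cols <- c(treatment_col, time_col, event_col)
  for (nm in outcome_cols)
    if (anyNA(table[[nm]]))
      stop_iptwcr("missingness in outcome/treatment column '", nm,
                  "' is not imputable here")
  targets <- confounders[vapply(confounders, function(nm)
    anyNA(table[[nm]]), logical(1))]
  for (nm in targets)
    if (all(is.na(table[[nm]])))
      stop_iptwcr("variable '", nm, "' is 100% missing; cannot impute")
  methods <- vapply(targets, function(nm)
    if (is.numeric(table[[nm]])) "bayes_lm" else "multinomial", character(1))

  if (!length(targets)) {
    return(structure(list(m = m, tables = replicate(m, table,
                                                    simplify = FALSE),
                          method_per_variable = methods, seed = seed),
                     class = "imputation_set"))
  }

  ## fixed survival-aware predictor frame (fully observed part)
  base_pred <- data.frame(
    .trt = table[[treatment_col]],
    .ev1 = as.numeric(table[[event_col]] == 1),
    .ev2 = as.numeric(table[[event_col]] == 2),
    .logt = log(table[[time_col]]))

  tables <- vector("list", m)
  for (i in seq_len(m)) {
    set.seed(stage_seed(seed, "imputation", i))
    comp <- table
    ## initialize missing entries by sampling observed values
    for (nm in targets) {
      miss <- is.na(comp[[nm]])
      comp[[nm]][miss] <- sample(comp[[nm]][!miss], sum(miss),
                                 replace = TRUE)
    }
    for (iter in seq_len(max_iter)) {
      for (nm in targets) {
        miss <- is.na(table[[nm]])
        others <- setdiff(confounders, nm)
        pred <- cbind(base_pred, comp[, others, drop = FALSE])
        X <- stats::model.matrix(~ ., data = pred)
        if (methods[[nm]] == "bayes_lm") {
          comp[[nm]][miss] <- .draw_bayes_lm(table[[nm]], X, miss)
        } else {
          comp[[nm]][miss] <- .draw_multinomial(comp[[nm]], X, miss)
        }
      }
    }
    tables[[i]] <- comp
  }
  structure(list(m = m, tables = tables, method_per_variable = methods,
                 seed = seed),
            class = "imputation_set")
}

## Bayesian linear regression draw: sigma^2 from the scaled inverse
## chi-square posterior, beta from its normal posterior, then a noisy
## prediction for each missing row.
.draw_bayes_lm <- function(y, X, miss) {
  Xo <- X[!miss, , drop = FALSE]
  yo <- y[!miss]
  qr_x <- qr(Xo)
  keep <- qr_x$pivot[seq_len(qr_x$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, yo)
  df <- length(yo) - ncol(Xo)
  sse <- sum(fit$residuals^2)
  sigma2 <- sse / stats::rchisq(1, max(df, 1))
  XtX_inv <- chol2inv(chol(crossprod(Xo) +
                             diag(1e-8, ncol(Xo))))
  ## A = U'U with U upper-triangular, so U'z ~ N(0, A)
  beta <- fit$coefficients +
    drop(crossprod(chol(sigma2 * XtX_inv), stats::rnorm(ncol(Xo))))
  Xm <- X[miss, keep, drop = FALSE]
  drop(Xm %*% beta) + sqrt(sigma2) * stats::rnorm(sum(miss))
}

## Multinomial (or binomial) logistic draw from fitted class probabilities.
.draw_multinomial <- function(y_current, X, miss) {
  f <- factor(y_current)
  obs_f <- f[!miss]
  if (nlevels(droplevels(obs_f)) < 2)
    return(rep(levels(obs_f)[1], sum(miss)))
  fit <- nnet::multinom(obs_f ~ . - 1,
                        data = data.frame(X[!miss, , drop = FALSE],
                                          check.names = TRUE),
                        trace = FALSE, MaxNWts = 5000)
  p <- stats::predict(fit, newdata = data.frame(X[miss, , drop = FALSE],
                                                check.names = TRUE),
                      type = "probs")
  if (is.null(dim(p))) p <- cbind(1 - p, p)  # binomial case
  lv <- fit$lev
  drawn <- apply(p, 1, function(pr) sample(lv, 1, prob = pr))
  factor(drawn, levels = levels(f))
}

#' Rubin's-rules pooling
#'
#' Combines per-imputation point estimates and variances:
#' pooled point = mean of points; total variance = within + (1 + 1/m)
#' between; normal 95 percent CI from the total variance.
#'
#' @param points numeric vector of per-imputation point estimates.
#' @param variances per-imputation squared standard errors.
#' @return An object of class `pooled_estimate` with `point`,
#'   `within_var`, `between_var`, `total_var`, `se`, `ci_low`, `ci_high`,
#'   `m`.
#' @export
pool_estimates <- function(points, variances) {
  m <- length(points)
  if (m < 2) stop_iptwcr("pooling requires m >= 2 imputations")
  if (length(variances) != m)
    stop_iptwcr("points and variances must have equal length")
  point <- mean(points)
  within <- mean(variances)
  between <- stats::var(points)
  total <- within + (1 + 1 / m) * between
  structure(list(point = point, within_var = within, between_var = between,
                 total_var = total, se = sqrt(total),
                 ci_low = point - 1.96 * sqrt(total),
                 ci_high = point + 1.96 * sqrt(total), m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "Pooled estimate over %d imputations: %.4f (SE %.4f, 95%% CI %.4f to %.4f)\n",
    x$m, x$point, x$se, x$ci_low, x$ci_high))
  cat(sprintf("  within-variance %.3g, between-variance %.3g\n",
              x$within_var, x$between_var))
  invisible(x)
}

#' MI sensitivity analysis for the IPTW contrast
#'
#' Runs the full IPTW competing-risks pipeline on each completed table of
#' an imputation set and pools the contrast estimates by Rubin's rules,
#' using each imputation's bootstrap variance as the within-imputation
#' variance (bootstrap-within-imputation is not nested).
#'
#' @param imp an [impute_chained()] result.
#' @param formula,confounders,... passed to [iptw_cmprisk()].
#' @param estimand which contrast row to pool (default the 5-year risk
#'   difference).
#' @return A [pool_estimates()] object with the per-imputation fits
#'   attached as attribute `fits`.
#' @export
mi_contrast <- function(imp, formula, confounders,
                        estimand = "risk_difference_5y", ...) {
  stopifnot(inherits(imp, "imputation_set"))
  fits <- lapply(imp$tables, function(tab)
    iptw_cmprisk(formula, tab, confounders, ...))
  pick <- function(f, col) {
    r <- f$contrasts[f$contrasts$estimand == estimand, ]
    if (!nrow(r)) stop_iptwcr("unknown estimand: ", estimand)
    r[[col]]
  }
  points <- vapply(fits, pick, numeric(1), col = "point")
  vars <- vapply(fits, pick, numeric(1), col = "boot_se")^2
  out <- pool_estimates(points, vars)
  attr(out, "fits") <- fits
  out
}
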