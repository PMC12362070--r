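## S3 methods for fitted iptw_cmprisk objects.

#' @export
print.iptw_cmprisk <- function(x, digits = 4, ...) {
  cause_lbl <- if (x$cause == 1) "graft failure (death competing)"
               else "all-cause death (graft failure competing)"
  cat("IPTW competing-risks causal contrasts\n")
  cat(sprintf("  outcome: %s;  n = %d (%d treated, %.1f%%)\n", cause_lbl,
              x$n, x$n_treated, 100 * x$n_treated / x$n))
  main <- x$contrasts[grepl("^risk_difference|^event_free",
                            x$contrasts$estimand), ]
  cat(sprintf("  bootstrap: %d resamples (%d effective)\n",
              x$n_boot, x$n_boot_effective))
  print(main[, c("estimand", "point", "boot_se", "ci_low", "ci_high")],
        digits = digits, row.names = FALSE)
  invisible(x)
}

#' Summary of a fitted IPTW competing-risks analysis
#'
#' @param object an [iptw_cmprisk()] fit.
#' @param ... unused.
#' @return The object, invisibly; prints the contrast table, e-values,
#'   weight diagnostics and any covariates still imbalanced after
#'   weighting.
#' @export
summary.iptw_cmprisk <- function(object, ...) {
  print(object)
  rd <- object$contrasts[grepl("^risk_difference", object$contrasts$estimand), ]
  if (any(!is.na(rd$e_value))) {
    cat("\nE-values (risk-ratio scale) by horizon:\n")
    print(data.frame(horizon = rd$horizon, e_value = rd$e_value,
                     boot_median = rd$e_value_boot_median),
          digits = 4, row.names = FALSE)
  }
  if (!is.null(object$balance)) {
    bad <- object$balance[object$balance$imbalanced, ]
    if (nrow(bad)) {
      cat("\nCovariates with |SMD| > 0.1 after weighting:\n")
      print(bad, digits = 3, row.names = FALSE)
    } else {
      cat("\nAll modelled confounders balanced after weighting ",
          "(|SMD| <= 0.1).\n", sep = "")
    }
  }
  if (!is.null(object$positivity))
    cat(sprintf("\nPositivity: %d score(s) outside [%.2f, %.2f].\n",
                object$positivity$n_extreme, object$positivity$bounds[1],
                object$positivity$bounds[2]))
  invisible(object)
}

#' @export
coef.iptw_cmprisk <- function(object, ...) {
  stats::setNames(object$contrasts$point, object$contrasts$estimand)
}

#' @export
confint.iptw_cmprisk <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$contrasts$point - z * object$contrasts$boot_se,
              object$contrasts$point + z * object$contrasts$boot_se)
  rownames(ci) <- object$contrasts$estimand
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Plot adjusted cumulative incidence by arm
#'
#' Step plot of the weighted Aalen-Johansen cumulative incidence of the
#' event of interest for each treatment arm.
#'
#' @param x an [iptw_cmprisk()] fit.
#' @param xlim,ylim,main,xlab,ylab usual graphics parameters.
#' @param ... passed to [graphics::plot()].
#' @export
plot.iptw_cmprisk <- function(x, xlim = c(0, x$tau), ylim = NULL,
                              main = "Adjusted cumulative incidence",
                              xlab = "Years since transplant",
                              ylab = "Cumulative incidence", ...) {
  c1 <- x$curves$control$cif1; c2 <- x$curves$treated$cif1
  if (is.null(ylim))
    ylim <- c(0, max(eval_curve(c1, x$tau), eval_curve(c2, x$tau)) * 1.2)
  graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = xlab, ylab = ylab,
                 main = main, ...)
  graphics::lines(stats::stepfun(c1$time, c(0, c1$estimate)), do.points = FALSE,
                  col = "firebrick")
  graphics::lines(stats::stepfun(c2$time, c(0, c2$estimate)), do.points = FALSE,
                  col = "royalblue")
  graphics::legend("topleft", legend = c("control (DDKT)", "treated (LDKT)"),
                   col = c("firebrick", "royalblue"), lty = 1, bty = "n")
  invisible(x)
}

#' Extract fitted step curves
#'
#' @param object an [iptw_cmprisk()] fit.
#' @return A `data.frame` of both arms' CIF and survival curves in long
#'   form (time, estimate, at_risk, events, kind, cause, arm).
#' @export
curves <- function(object) UseMethod("curves")

#' @export
curves.iptw_cmprisk <- function(object) {
  one_arm <- function(aj, arm) {
    out <- rbind(as.data.frame(aj$cif1), as.data.frame(aj$cif2),
                 as.data.frame(aj$survival))
    out$arm <- arm
    out
  }
  rbind(one_arm(object$curves$treated, "treated"),
        one_arm(object$curves$control, "control"))
}

#' Subgroup analysis against the full control arm
#'
#' Re-runs the complete pipeline on the dataset formed by all control
#' (deceased-donor) rows plus the treated (living-donor) rows satisfying
#' `predicate`, refitting the propensity model on that subset.  Mirrors
#' registry subgroup analyses such as older living donors (>= 60 years),
#' HLA mismatch level 4, or kidney-sharing-scheme / altruistic donation.
#'
#' @param formula,data,confounders,... as in [iptw_cmprisk()].
#' @param predicate one-sided formula or expression on the data columns,
#'   evaluated over treated rows (e.g. `~ donor_age >= 60`).
#' @param min_treated minimum treated rows required (default 50).
#' @return An [iptw_cmprisk()] fit on the subgroup dataset.
#' @export
run_subgroup_analysis <- function(formula, data, confounders, predicate,
                                  min_treated = 50, ...) {
  expr <- if (inherits(predicate, "formula")) predicate[[2]] else predicate
  vars <- all.vars(expr)
  absent <- setdiff(vars, names(data))
  if (length(absent))
    stop_iptwcr("predicate uses columns absent from the table: ",
                paste(absent, collapse = ", "))
  tr_name <- all.vars(formula[[3]])[1]
  keep_trt <- eval(expr, data, parent.frame())
  sel <- data[[tr_name]] == 0 | (data[[tr_name]] == 1 & keep_trt)
  sub <- data[sel, , drop = FALSE]
  if (sum(sub[[tr_name]] == 1) < min_treated)
    stop_iptwcr("subgroup has fewer than ", min_treated,
                " treated rows; estimates would be unstable")
  iptw_cmprisk(formula, sub, confounders, ...)
}

#' Pre-specified sensitivity analyses
#'
#' `exclude_covid_era` drops transplants from 2020 onward and re-runs the
#' pipeline; `include_hla_in_ps` adds HLA mismatch level to the propensity
#' model (overriding the mediator blocklist) to probe confounding by
#' immunological match quality.
#'
#' @param formula,data,confounders,... as in [iptw_cmprisk()].
#' @param variant `"exclude_covid_era"` or `"include_hla_in_ps"`.
#' @return An [iptw_cmprisk()] fit under the variant.
#' @export
run_sensitivity <- function(formula, data, confounders,
                            variant = c("exclude_covid_era",
                                        "include_hla_in_ps"), ...) {
  variant <- match.arg(variant)
  if (variant == "exclude_covid_era") {
    if (!"transplant_year" %in% names(data))
      stop_iptwcr("variant requires a 'transplant_year' column")
    iptw_cmprisk(formula, data[data$transplant_year < 2020, , drop = FALSE],
                 confounders, ...)
  } else {
    if (!"hla_mismatch_level" %in% names(data))
      stop_iptwcr("variant requires an 'hla_mismatch_level' column")
    iptw_cmprisk(formula, data,
                 unique(c(confounders, "hla_mismatch_level")),
                 allow_mediators = TRUE, ...)
  }
}
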