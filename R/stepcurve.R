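#' Right-continuous step curve
#'
#' Container for a survival curve or cumulative incidence function: a
#' right-continuous step function over strictly increasing event times,
#' carrying the weighted risk-set size just before each time and the
#' weighted event count at each time.
#'
#' @param time strictly increasing positive event times (years).
#' @param estimate curve value at each time (right-continuous).
#' @param at_risk weighted risk-set size just before each time.
#' @param events weighted event count at each time.
#' @param kind `"survival"` (starts at 1, non-increasing) or `"cif"`
#'   (starts at 0, non-decreasing).
#' @param cause optional event cause (1 = primary event, 2 = competing
#'   event) for CIF curves.
#' @return An object of class `step_curve`.
#' @export
step_curve <- function(time, estimate, at_risk = rep(NA_real_, length(time)),
                       events = rep(NA_real_, length(time)),
                       kind = c("survival", "cif"), cause = NULL) {
  kind <- match.arg(kind)
  if (length(time) && is.unsorted(time, strictly = TRUE))
    stop_iptwcr("step curve times must be strictly increasing")
  if (any(estimate < -1e-12) || any(estimate > 1 + 1e-12))
    stop_iptwcr("step curve values must lie in [0, 1]")
  if (kind == "survival" && length(estimate) > 1 &&
      any(diff(estimate) > 1e-12))
    stop_iptwcr("survival curve must be non-increasing")
  if (kind == "cif" && length(estimate) > 1 && any(diff(estimate) < -1e-12))
    stop_iptwcr("cumulative incidence curve must be non-decreasing")
  structure(
    list(time = as.numeric(time), estimate = pmin(pmax(estimate, 0), 1),
         at_risk = as.numeric(at_risk), events = as.numeric(events),
         kind = kind, cause = cause),
    class = "step_curve")
}

#' Evaluate a step curve
#'
#' Right-continuous lookup: the curve value at the largest jump time not
#' exceeding `t`, or the kind-specific origin value (1 for survival, 0 for
#' a CIF) before the first jump.
#'
#' @param curve a [step_curve()].
#' @param t numeric vector of evaluation times.
#' @return numeric vector of curve values.
#' @export
eval_curve <- function(curve, t) {
  origin <- if (curve$kind == "survival") 1 else 0
  if (!length(curve$time)) return(rep(origin, length(t)))
  idx <- findInterval(t, curve$time)
  c(origin, curve$estimate)[idx + 1L]
}

#' @export
print.step_curve <- function(x, ...) {
  lbl <- if (x$kind == "survival") "survival curve"
         else sprintf("cumulative incidence (cause %s)",
                      x$cause %||% "?")
  cat(sprintf("Weighted %s: %d step(s)\n", lbl, length(x$time)))
  if (length(x$time)) {
    rng <- range(x$time)
    cat(sprintf("  time range [%.4g, %.4g], final value %.4f\n",
                rng[1], rng[2], x$estimate[length(x$estimate)]))
  }
  invisible(x)
}

#' @export
as.data.frame.step_curve <- function(x, ...) {
  data.frame(time = x$time, estimate = x$estimate, at_risk = x$at_risk,
             events = x$events, kind = x$kind,
             cause = if (is.null(x$cause)) NA_integer_ else x$cause)
}

## Exact integral of the step function on [0, tau].
.integrate_step <- function(curve, tau) {
  origin <- if (curve$kind == "survival") 1 else 0
  tt <- c(0, curve$time)
  vv <- c(origin, curve$estimate)
  keep <- tt < tau
  tt <- tt[keep]; vv <- vv[keep]
  sum(diff(c(tt, tau)) * vv)
}

#' Restricted mean survival time
#'
#' Area under a survival step curve up to horizon `tau`: the mean event-free
#' time over the first `tau` years.  The curve value between the last jump
#' and `tau` is the value at the last jump (right-continuity).
#'
#' @param curve a `step_curve` of kind `"survival"`.
#' @param tau positive restriction horizon (years).
#' @return RMST in years.
#' @export
rmst <- function(curve, tau) {
  if (!inherits(curve, "step_curve") || curve$kind != "survival")
    stop_iptwcr("rmst() requires a survival step curve")
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0)
    stop_iptwcr("tau must be a positive scalar")
  .integrate_step(curve, tau)
}

#' Restricted mean time lost
#'
#' Area under a cumulative incidence step curve up to `tau`: the mean time
#' lost to the curve's event cause over the first `tau` years.  Satisfies
#' `rmtl(cif1) + rmtl(cif2) + rmst(overall survival) == tau`.
#'
#' @param curve a `step_curve` of kind `"cif"`.
#' @param tau positive restriction horizon (years).
#' @return RMTL in years.
#' @export
rmtl <- function(curve, tau) {
  if (!inherits(curve, "step_curve") || curve$kind != "cif")
    stop_iptwcr("rmtl() requires a cumulative incidence step curve")
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0)
    stop_iptwcr("tau must be a positive scalar")
  .integrate_step(curve, tau)
}
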