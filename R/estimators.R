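## Weighted nonparametric estimators for competing risks.
##
## All estimators share one tie convention: every event and censoring at the
## same time is processed together, events before censorings, so censored
## subjects at time t still count in the risk set for events at t.  Weighted
## counts replace integer counts throughout; multiplying all weights by a
## positive constant leaves every curve unchanged.

## Aggregate weighted counts at the unique observed times.
## Returns, per unique time: weighted at-risk just before (n), weighted
## cause-1/cause-2 event mass (d1, d2) and censoring mass (dc).
.risk_table <- function(time, event, weights) {
  ut <- sort(unique(time))
  f <- match(time, ut)
  agg <- function(x) {
    out <- numeric(length(ut))
    s <- rowsum(x, f)
    out[as.integer(rownames(s))] <- s
    out
  }
  d1 <- agg(weights * (event == 1))
  d2 <- agg(weights * (event == 2))
  dc <- agg(weights * (event == 0))
  leaving <- d1 + d2 + dc
  n <- sum(weights) - c(0, cumsum(leaving))[seq_along(ut)]
  list(time = ut, n = n, d1 = d1, d2 = d2, dc = dc)
}

.check_surv_args <- function(time, event, weights, codes) {
  if (length(time) != length(event) || length(time) != length(weights))
    stop_iptwcr("time, event and weights must have equal length")
  if (any(!is.finite(time)) || any(time <= 0))
    stop_iptwcr("all event times must be positive and finite")
  if (!all(event %in% codes))
    stop_iptwcr("event codes must be in {", paste(codes, collapse = ","), "}")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop_iptwcr("all weights must be positive and finite")
}

#' Weighted Kaplan-Meier estimator
#'
#' Product-limit estimator of the survival function with subject weights
#' (for example inverse probability of treatment weights):
#' \deqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}
#' with weighted event mass \eqn{d_i} and weighted at-risk mass \eqn{n_i}
#' just before each event time.
#'
#' @param time positive follow-up times (years).
#' @param status 0 = censored, 1 = event.
#' @param weights positive subject weights; default 1 (unweighted).
#' @return A [step_curve()] of kind `"survival"` stepping at event times.
#' @export
weighted_km <- function(time, status, weights = rep(1, length(time))) {
  .check_surv_args(time, status, weights, 0:1)
  if (all(status == 0) && all(time <= 0))
    stop_iptwcr("no subject enters the risk set")
  rt <- .risk_table(time, status, weights)
  d <- rt$d1
  surv <- cumprod(1 - d / rt$n)
  keep <- d > 0
  step_curve(rt$time[keep], surv[keep], at_risk = rt$n[keep],
             events = d[keep], kind = "survival")
}

#' Weighted Aalen-Johansen estimator
#'
#' Nonparametric cumulative incidence under two competing causes with
#' subject weights.  The cause-specific CIFs are
#' \deqn{F_k(t) = \sum_{t_i \le t} S(t_i^-) \, d_{k,i} / n_i}
#' where \eqn{S} is the weighted all-cause Kaplan-Meier survival.  At every
#' event time \eqn{S + F_1 + F_2 = 1} exactly.
#'
#' @param time positive follow-up times (years).
#' @param event 0 = censored, 1 = primary event (graft failure),
#'   2 = competing event (death with functioning graft).
#' @param weights positive subject weights; default 1.
#' @return List with components `cif1`, `cif2` (kind `"cif"`) and
#'   `survival` (all-cause survival), each a [step_curve()] stepping at the
#'   any-cause event times.
#' @export
aalen_johansen <- function(time, event, weights = rep(1, length(time))) {
  .check_surv_args(time, event, weights, 0:2)
  rt <- .risk_table(time, event, weights)
  dall <- rt$d1 + rt$d2
  surv <- cumprod(1 - dall / rt$n)
  surv_minus <- c(1, surv[-length(surv)])
  cif1 <- cumsum(surv_minus * rt$d1 / rt$n)
  cif2 <- cumsum(surv_minus * rt$d2 / rt$n)
  keep <- dall > 0
  list(
    cif1 = step_curve(rt$time[keep], cif1[keep], at_risk = rt$n[keep],
                      events = rt$d1[keep], kind = "cif", cause = 1L),
    cif2 = step_curve(rt$time[keep], cif2[keep], at_risk = rt$n[keep],
                      events = rt$d2[keep], kind = "cif", cause = 2L),
    survival = step_curve(rt$time[keep], surv[keep], at_risk = rt$n[keep],
                          events = dall[keep], kind = "survival"))
}

#' Fine-Gray-weighted Kaplan-Meier cumulative risk
#'
#' Subdistribution estimate of the cause-1 cumulative risk: subjects who
#' fail from the competing cause remain in the cause-1 risk set after their
#' event with the time-varying weight
#' \eqn{w_i \, \hat G(t^-) / \hat G(T_i^-)}, where \eqn{\hat G} is the
#' (optionally IPTW-weighted) Kaplan-Meier estimator of the censoring
#' distribution.  The returned curve is one minus the subdistribution
#' Kaplan-Meier; with the shared tie convention it coincides with the
#' Aalen-Johansen cause-1 CIF at every event time (a finite-sample
#' identity, not an approximation).
#'
#' @param time positive follow-up times (years).
#' @param event 0 = censored, 1 = primary event, 2 = competing event.
#' @param weights positive subject weights (IPTW); default 1.
#' @param weighted_censoring use the same subject weights in the censoring
#'   distribution estimator (default `TRUE`, keeping the pseudo-population
#'   interpretation coherent); `FALSE` uses unit weights for \eqn{\hat G}.
#' @return A [step_curve()] of kind `"cif"`, cause 1.
#' @export
fine_gray_weighted_km <- function(time, event,
                                  weights = rep(1, length(time)),
                                  weighted_censoring = TRUE) {
  .check_surv_args(time, event, weights, 0:2)
  rt <- .risk_table(time, event, weights)
  if (weighted_censoring) {
    dc <- rt$dc
    ev_mass <- rt$d1 + rt$d2
    n_cens <- rt$n
  } else {
    rt_u <- .risk_table(time, event, rep(1, length(time)))
    dc <- rt_u$dc
    ev_mass <- rt_u$d1 + rt_u$d2
    n_cens <- rt_u$n
  }
  ## Censoring survival G with events processed before censorings: the
  ## censoring risk set at t excludes subjects failing (any cause) at t.
  g_rs <- n_cens - ev_mass
  g_step <- ifelse(g_rs > 0, 1 - dc / g_rs, 1)
  G <- cumprod(g_step)
  G_minus <- c(1, G[-length(G)])      # G(t_i^-)

  ## Cause-2 mass re-entering the risk set: each competing-event subject
  ## with event at t_j contributes w_j * G(t^-)/G(t_j^-) for t > t_j.
  ratio2 <- ifelse(G_minus > 0, rt$d2 / G_minus, 0)
  carried <- c(0, cumsum(ratio2))[seq_along(ratio2)]  # sum over t_j < t_i
  n_star <- rt$n + G_minus * carried

  step <- ifelse(n_star > 0, 1 - rt$d1 / n_star, 1)
  surv_sub <- cumprod(step)
  keep <- (rt$d1 + rt$d2) > 0
  step_curve(rt$time[keep], 1 - surv_sub[keep], at_risk = n_star[keep],
             events = rt$d1[keep], kind = "cif", cause = 1L)
}
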