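## Internal helpers shared across modules.

expit <- function(x) 1 / (1 + exp(-x))

## Deterministic sub-seed derivation: one master integer seed governs every
## RNG stage (generation, masking, bootstrap replicate, imputation chain).
## Offsets are fixed per stage so stages are independently reproducible and
## results do not depend on execution order.  Result always in [1, 2^31-2].
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 2147483647) + as.numeric(offset) * 48271
  as.integer(s %% 2147483646) + 1L
}

.stage_offsets <- c(
  covariates = 101L, treatment = 202L, events = 303L, censoring = 404L,
  admin = 505L, missingness = 606L, oracle = 707L, bootstrap = 1000000L,
  imputation = 2000000L
)

stage_seed <- function(seed, stage, index = 0L) {
  off <- .stage_offsets[[stage]]
  derive_seed(seed, off + as.numeric(index))
}

## Weighted first and second moments.  Variance uses the reliability-type
## denominator sum(w) - sum(w^2)/sum(w), which reduces to the usual n-1
## sample variance for unit weights.
wmean <- function(x, w) sum(w * x) / sum(w)

wvar <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  denom <- sw - sum(w^2) / sw
  if (denom <= 0) return(NA_real_)
  sum(w * (x - m)^2) / denom
}

## Weighted quantile by inverting the weighted ECDF (type-1 step inverse).
wquantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_iptwcr <- function(...) stop(..., call. = FALSE)
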