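test_that("intercept-only model has the closed-form MLE", {
  tab <- data.frame(treatment = c(rep(1, 3), rep(0, 7)))
  fit <- fit_propensity(tab, character(0))
  expect_equal(unname(fit$coefficients[1]), log(3 / 7), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("logistic fit agrees with a general-purpose likelihood
           maximizer to 1e-6", {
  set.seed(3)
  n <- 200
  tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                    x3 = factor(sample(c("a", "b"), n, replace = TRUE)))
  eta <- -0.4 + 0.8 * tab$x1 - 0.5 * tab$x2 + 0.6 * (tab$x3 == "b")
  tab$treatment <- rbinom(n, 1, plogis(eta))
  fit <- fit_propensity(tab, c("x1", "x2", "x3"))

  X <- model.matrix(~ x1 + x2 + x3, tab)
  nll <- function(b) {
    p <- plogis(drop(X %*% b))
    -sum(tab$treatment * log(p) + (1 - tab$treatment) * log1p(-p))
  }
  opt <- optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_lt(max(abs(fit$coefficients - opt$par)), 1e-6)
})

test_that("null treatment assignment gives slopes within 3 SE of zero", {
  set.seed(14)
  n <- 2e4
  tab <- data.frame(x1 = rnorm(n), x2 = runif(n),
                    treatment = rbinom(n, 1, 0.4))
  fit <- fit_propensity(tab, c("x1", "x2"))
  X <- model.matrix(~ x1 + x2, tab)
  e <- fit$scores
  se <- sqrt(diag(solve(crossprod(X * sqrt(e * (1 - e))))))
  expect_true(all(abs(fit$coefficients[-1]) < 3 * se[-1]))
})

test_that("propensity fit rejects pathological designs and mediators", {
  tab <- data.frame(x = c(rep(0, 5), rep(1, 5)),
                    treatment = c(rep(0, 5), rep(1, 5)))
  expect_error(fit_propensity(tab, "x"), "separation")

  tab2 <- data.frame(x = rnorm(20))
  tab2$y <- 2 * tab2$x
  tab2$treatment <- rbinom(20, 1, 0.5)
  expect_error(fit_propensity(tab2, c("x", "y")), "collinear")

  tab3 <- data.frame(hla_mismatch_level = rnorm(20),
                     treatment = rbinom(20, 1, 0.5))
  expect_error(fit_propensity(tab3, "hla_mismatch_level"), "mediator")
  expect_s3_class(fit_propensity(tab3, "hla_mismatch_level",
                                 allow_mediators = TRUE),
                  "propensity_fit")

  tab4 <- data.frame(x = c(NA, rnorm(9)), treatment = rbinom(10, 1, 0.5))
  expect_error(fit_propensity(tab4, "x"), "missing confounders")
})

test_that("ATE weights follow the inverse-probability formulas", {
  w <- compute_iptw(c(0.5, 0.5), c(1, 0))
  expect_equal(w$weights, c(2, 2))
  w2 <- compute_iptw(c(0.25, 0.25), c(1, 0))
  expect_equal(w2$weights, c(4, 4 / 3))
  expect_error(compute_iptw(c(1, 0.5), c(1, 0)), "inside")

  # stabilization multiplies by the marginal prevalence
  w3 <- compute_iptw(c(0.25, 0.25), c(1, 0), stabilized = TRUE)
  expect_equal(w3$weights, c(4 * 0.5, 4 / 3 * 0.5))

  # truncation caps and counts
  w4 <- compute_iptw(c(0.02, rep(0.5, 98), 0.98),
                     c(1, rep(0, 99)), truncate = 0.05)
  expect_equal(w4$truncation$n_capped, 2)
  expect_true(all(w4$weights >= w4$truncation$bounds[1] &
                    w4$weights <= w4$truncation$bounds[2]))
})

test_that("IPTW identity: weighted arm totals approximate n", {
  cfg <- registry_config(n = 1e4, seed = 6, missing_spec = NULL)
  tab <- simulate_registry(cfg)
  fit <- fit_propensity(tab, default_confounders)
  w <- compute_iptw(fit, tab$treatment)$weights
  n <- nrow(tab)
  expect_lt(abs(sum(w[tab$treatment == 1]) / n - 1), 0.1)
  expect_lt(abs(sum(w[tab$treatment == 0]) / n - 1), 0.1)
})

test_that("standardized mean differences match hand arithmetic", {
  expect_equal(standardized_mean_difference(
    rep(c(1, 2), 4), rep(c(1, 0), each = 4)), 0)
  # means 0.5 vs 0.3, SDs 0.1: SMD = 2
  x1 <- c(0.4, 0.5, 0.6); x0 <- c(0.2, 0.3, 0.4)
  expect_equal(standardized_mean_difference(
    c(x1, x0), rep(c(1, 0), each = 3)), 2)
  # binary level p1 = 0.6, p0 = 0.5 -> 0.1/sqrt((0.24+0.25)/2)
  x1 <- rep(c(1, 0), c(6, 4)); x0 <- rep(c(1, 0), c(5, 5))
  got <- standardized_mean_difference(c(x1, x0), rep(c(1, 0), c(10, 10)))
  v1 <- var(x1); v0 <- var(x0)
  expect_equal(got, 0.1 / sqrt((v1 + v0) / 2))
  expect_equal(round(0.1 / sqrt((0.24 + 0.25) / 2), 4), 0.2020,
               tolerance = 1e-4)
  # zero pooled SD with unequal means: signed infinity
  expect_equal(standardized_mean_difference(
    rep(c(1, 0), each = 3), rep(c(1, 0), each = 3)), Inf)
  expect_error(standardized_mean_difference(1:3, rep(1, 3)), "both arms")
})

test_that("weighting balances modelled confounders but not omitted ones", {
  # unit weights: before == after
  cfg <- registry_config(n = 2000, seed = 3, missing_spec = NULL)
  tab <- simulate_registry(cfg)
  bt0 <- balance_table(tab, default_confounders, rep(1, nrow(tab)))
  expect_equal(bt0$smd_before, bt0$smd_after)

  # confounded cohort: weighting brings every modelled SMD under 0.1
  cfg <- registry_config(n = 1e4, seed = 19, missing_spec = NULL)
  tab <- simulate_registry(cfg)
  fit <- fit_propensity(tab, default_confounders)
  w <- compute_iptw(fit, tab$treatment)$weights
  bt <- balance_table(tab, default_confounders, w)
  expect_true(any(abs(bt$smd_before) > 0.1))   # confounding was real
  expect_true(all(abs(bt$smd_after) < 0.1))

  # a confounder omitted from the model need not be balanced
  set.seed(42)
  n <- 1e4
  sim <- data.frame(u = rnorm(n), z = rnorm(n))
  sim$treatment <- rbinom(n, 1, plogis(-0.5 + 1.2 * sim$u + 0.3 * sim$z))
  fit2 <- fit_propensity(sim, "z")
  w2 <- compute_iptw(fit2, sim$treatment)$weights
  bt2 <- balance_table(sim, c("z", "u"), w2)
  expect_lt(abs(bt2$smd_after[bt2$variable == "z"]), 0.1)
  expect_gt(abs(bt2$smd_after[bt2$variable == "u"]), 0.1)
})

test_that("positivity diagnostics count extreme scores", {
  rep1 <- positivity_diagnostics(c(0.2, 0.5, 0.8), c(0, 1, 1))
  expect_equal(rep1$n_extreme, 0)
  rep2 <- positivity_diagnostics(c(0.2, 0.995), c(0, 1))
  expect_equal(rep2$n_extreme, 1)
  expect_identical(rep2, positivity_diagnostics(c(0.2, 0.995), c(0, 1)))
})
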