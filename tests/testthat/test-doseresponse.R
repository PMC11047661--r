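test_that("saturated two-point data reproduces the closed-form logit line", {
  # grouped Bernoulli data at two doses: the MLE passes through the
  # empirical logits, so coefficients follow in closed form
  C1 <- 0; C2 <- 2e6
  f1 <- 0.3; f2 <- 0.8
  d <- tibble::tibble(
    concentration_nM = c(rep(C1, 10), rep(C2, 10)),
    outcome = c(rep(1L, 3), rep(0L, 7), rep(1L, 8), rep(0L, 2)))
  fit <- fit_logistic(d)
  beta1_cf <- (qlogis(f2) - qlogis(f1)) / (C2 - C1)
  expect_equal(fit$beta0, qlogis(f1), tolerance = 1e-6)
  expect_equal(fit$beta1, beta1_cf, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_false(fit$separation_flag)
  expect_identical(fit$n_obs, 20L)
})

test_that("degenerate designs are rejected with informative errors", {
  d1 <- tibble::tibble(concentration_nM = rep(100, 10),
                       outcome = rep(c(0L, 1L), 5))
  expect_error(fit_logistic(d1), "distinct concentrations")
  d2 <- tibble::tibble(concentration_nM = c(1, 10, 100, 1000),
                       outcome = rep(0L, 4))
  expect_error(fit_logistic(d2), "separation")
  d3 <- tibble::tibble(concentration_nM = c(1, 10, 100, 1000),
                       outcome = rep(1L, 4))
  expect_error(fit_logistic(d3), "separation")
})

test_that("IRLS optimum matches a dense log-likelihood grid search", {
  d <- simulate_binary_dose_response(
    sim_dose_config(-1.1, 1e-6, c(0, 1e5, 5e5, 1e6, 2e6), 40, seed = 12))
  expect_lte(nrow(d), 200)
  fit <- fit_logistic(d)
  b0g <- seq(-2.5, 0.5, by = 0.01)
  b1g <- seq(-1e-6, 3e-6, by = 1e-8)
  gs <- grid_search_logistic(d$concentration_nM, d$outcome, b0g, b1g)
  expect_lt(abs(fit$beta0 - gs$beta0), 0.011)
  expect_lt(abs(fit$beta1 - gs$beta1), 1.1e-8)
  # and the IRLS solution is at least as likely as the best grid point
  expect_gte(loglik_logistic(fit$beta0, fit$beta1, d$concentration_nM,
                             d$outcome), gs$loglik - 1e-9)
})

test_that("parameter recovery across the configured (beta0, beta1) design grid", {
  concs <- c(100, 1e3, 1e4, 1e5, 1e6, 1e7)
  cases <- expand.grid(beta0 = c(-2, -1, 0), beta1 = c(0, 1e-6, 1e-5))
  for (k in seq_len(nrow(cases))) {
    b0 <- cases$beta0[k]; b1 <- cases$beta1[k]
    d <- simulate_binary_dose_response(
      sim_dose_config(b0, b1, concs, 500, seed = 1000 + k))
    fit <- fit_logistic(d)
    td <- tidy(fit)
    expect_lt(abs(td$estimate[1] - b0), 3 * td$std.error[1])
    expect_lt(abs(td$estimate[2] - b1), 3 * td$std.error[2])
  }
})

test_that("predicted probabilities follow the logistic expression", {
  expect_equal(predict(logistic_model(0, 0), c(0, 10, 1e7)), rep(0.5, 3))
  sls <- logistic_model(-1.1057, 1e-6)
  expect_gt(predict(sls, 1.73e7), 0.99)
  expect_equal(round(predict(sls, 0), 4), 0.2487)
  # strictly inside (0, 1) even at extreme linear predictors
  expect_gt(predict(logistic_model(-1000, 0), 0), 0)
  expect_lt(predict(logistic_model(1000, 0), 0), 1)
  # strictly increasing iff slope > 0; constant iff slope = 0
  grid <- 10^seq(1, 7, by = 0.5)
  expect_true(all(diff(predict(sls, grid)) > 0))
  expect_true(all(diff(predict(logistic_model(-0.949, 0), grid)) == 0))
  expect_error(predict(sls, -5), ">= 0")
})

test_that("IC50 is -beta0/beta1 and undefined for non-positive slopes", {
  sls <- logistic_model(-1.1057, 1e-6)
  expect_equal(ic50(sls), 1.1057e6)
  expect_equal(signif(ic50(sls), 1), 1e6)
  expect_equal(predict(sls, ic50(sls)), 0.5, tolerance = 1e-12)
  expect_identical(ic50(logistic_model(0, 2e-6)), 0)
  expect_error(ic50(logistic_model(-0.9490, 0)), "undefined")
  expect_error(ic50(logistic_model(-1, -1e-7)), "undefined")
})

test_that("Wald confidence bands bracket the estimate and tighten with n", {
  d <- simulate_binary_dose_response(
    sim_dose_config(-1.1057, 1e-6, c(1e2, 1e4, 1e6, 5e6), 200, seed = 3))
  fit <- fit_logistic(d)
  grid <- 10^seq(2, 7, length.out = 30)
  band <- confidence_band(fit, grid)
  expect_true(all(band$lower <= band$p & band$p <= band$upper))
  expect_equal(band$p, predict(fit, grid), tolerance = 1e-12)

  widths <- vapply(c(100, 1000, 10000), function(n) {
    dd <- simulate_binary_dose_response(
      sim_dose_config(-1.1057, 1e-6, c(1e2, 1e4, 1e6, 5e6), n, seed = 4))
    b <- confidence_band(fit_logistic(dd), 5e5)
    b$upper - b$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  bad <- logistic_model(0, 1e-6)
  bad$converged <- FALSE
  expect_error(confidence_band(bad, grid), "converged")
})

test_that("Wald band coverage of the true curve is near nominal", {
  # Monte-Carlo coverage at mid-range concentration under the cytotoxic
  # reference model
  true <- logistic_model(-1.1057, 1e-6)
  C0 <- 5e5
  p_true <- predict(true, C0)
  concs <- c(1e2, 1e3, 1e4, 1e5, 1e6, 1e7)
  hits <- vapply(1:500, function(k) {
    d <- simulate_binary_dose_response(
      sim_dose_config(-1.1057, 1e-6, concs, 500, seed = 20000 + k))
    b <- confidence_band(fit_logistic(d), C0)
    b$lower <= p_true && p_true <= b$upper
  }, logical(1))
  expect_gte(mean(hits), 0.91)
  expect_lte(mean(hits), 0.99)
})

test_that("the union probability obeys its algebraic properties", {
  expect_equal(combine_probabilities(0.2791, 0.8), 0.85582, tolerance = 1e-4)
  expect_identical(combine_probabilities(0.37, 0), 0.37)
  expect_identical(combine_probabilities(1, 1), 1)
  set.seed(6)
  pA <- runif(200); pB <- runif(200)
  u <- combine_probabilities(pA, pB)
  expect_equal(u, combine_probabilities(pB, pA))                   # symmetry
  expect_true(all(u >= pmax(pA, pB) - 1e-12))                      # bounds
  expect_true(all(u <= pmin(1, pA + pB) + 1e-12))
  # monotone in each argument
  eps <- 0.01
  expect_true(all(combine_probabilities(pmin(pA + eps, 1), pB) >= u - 1e-12))
  expect_error(combine_probabilities(1.2, 0.5), "\\[0, 1\\]")
  expect_error(combine_probabilities(0.5, -0.1), "\\[0, 1\\]")
})

test_that("custom intersection rules are validated against Frechet bounds", {
  # comonotone upper bound: P(A&B) = min(pA, pB) -> union = max(pA, pB)
  u <- combine_probabilities(0.3, 0.6, intersection = function(a, b) pmin(a, b))
  expect_equal(u, 0.6)
  # lower Frechet bound -> union = min(1, pA + pB)
  u2 <- combine_probabilities(0.7, 0.6,
                              intersection = function(a, b) pmax(0, a + b - 1))
  expect_equal(u2, 1)
  expect_error(
    combine_probabilities(0.3, 0.6, intersection = function(a, b) a + b),
    "Frechet")
})

test_that("the irritation profile combines fitted and constant components", {
  sls <- logistic_model(-1.1057, 1e-6)
  grid <- 10^seq(2, 7, by = 0.25)
  prof <- irritation_profile(sls, 0.5, grid)
  expect_s3_class(prof, "irritation_profile")
  expect_identical(attr(prof, "intersection_rule"), "independence")
  # union dominates each component
  expect_true(all(prof$p_combined >= prof$p_apoptosis - 1e-12))
  expect_true(all(prof$p_combined >= prof$p_trpv1 - 1e-12))
  # the sub-cytotoxic plateau sits near 0.63
  expect_equal(prof$p_combined[prof$concentration_nM == 1e5],
               combine_probabilities(predict(sls, 1e5), 0.5),
               tolerance = 1e-12)
  # both components ~0 -> union ~0
  prof0 <- irritation_profile(logistic_model(-30, 0), 1e-9, grid)
  expect_true(all(prof0$p_combined < 1e-8))
  expect_error(irritation_profile(sls, 1.2, grid), "scalar probability")
})

test_that("tidy and glance expose the fit in broom conventions", {
  d <- simulate_binary_dose_response(
    sim_dose_config(-1, 1e-6, c(1e2, 1e5, 1e6), 100, seed = 14))
  fit <- fit_logistic(d)
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "concentration_nM"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_identical(gl$n_obs, 300L)
  expect_true(gl$converged)
  expect_lt(gl$logLik, 0)
})
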