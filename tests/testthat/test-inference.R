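test_that("likelihood-ratio and information-criterion arithmetic is exact", {
  ## deviance ladders of the manifest and latent random-scale comparisons
  expect_equal(lrt(6081, 5537, 2)$statistic, 544)
  expect_equal(lrt(33678, 33034, 2)$statistic, 644)
  eq <- lrt(5000, 5000, 2)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  expect_warning(neg <- lrt(100, 105, 1), "negative")
  expect_true(neg$negative)

  expect_equal(information_criteria(6081, 3)$aic, 6087)
  expect_equal(information_criteria(5537, 5)$aic, 5547)
  expect_equal(information_criteria(5245, 10)$aic, 5265)
  expect_equal(information_criteria(123.4, 0)$aic, 123.4)
  expect_equal(information_criteria(100, 4, 50)$bic, 100 + 4 * log(50))
})

test_that("Wald linear tests match the quadratic form", {
  expect_equal(wald_linear(c(1, -1), c(2, 2), diag(2))$statistic, 0)
  expect_equal(wald_linear(1, 2, matrix(4))$statistic, 1.0)
  set.seed(12)
  for (k in 1:10) {
    d <- sample(2:5, 1)
    th <- rnorm(d); cc <- rnorm(d)
    A <- matrix(rnorm(d * d), d); V <- crossprod(A) + diag(d) * 0.1
    w <- wald_linear(cc, th, V)
    expect_equal(w$statistic,
                 sum(cc * th)^2 / drop(t(cc) %*% V %*% cc), tolerance = 1e-12)
    expect_equal(w$p, pchisq(w$statistic, 1, lower.tail = FALSE))
  }
  expect_error(wald_linear(c(1, 0), c(1, 1), matrix(0, 2, 2)), "positive")
})

test_that("free-parameter counting reproduces the model ladder bookkeeping", {
  df <- data.frame(subject = rep(1:3, each = 4), occasion = rep(1:4, 3),
                   y = rnorm(12), stressors = rpois(12, 1))
  d <- person_center(diary_data(df, outcome = "y"), "stressors")
  count <- function(spec) lvmelsm:::param_layout(spec)$n
  ## homoscedastic random-intercept model: beta0, alpha0, tau0
  expect_equal(count(melsm_spec(within = within_spec(random_scale = FALSE))), 3L)
  ## adding the random scale effect and its covariance: 5
  expect_equal(count(melsm_spec()), 5L)
  ## full stressor model: beta0, beta1, beta2, alpha0, alpha1,
  ## tau0, tau1, tau2, phi_a, rho
  expect_equal(count(stressor_spec()), 10L)
  ## invariant 5-item/8-day latent model: 13 measurement + 5 structural
  expect_equal(count(melsm_spec(measurement = measurement_spec(5, 8))), 18L)
})

test_that("staged starting values have the documented stage-1 closed form", {
  tm <- toy_manifest()
  sim <- simulate_melsm(tm$spec, tm$truth, n_subjects = 80, n_occasions = 6,
                        seed = 202)
  st <- staged_start(sim$data, tm$spec, refine = FALSE)
  expect_equal(unname(st$beta), mean(sim$data$y), tolerance = 1e-10)
  y <- sim$data$y; s <- sim$data$subject
  within_var <- sum(tapply(y, s, function(v) sum((v - mean(v))^2))) /
    (length(y) - length(unique(s)))
  expect_equal(unname(st$tau[1]), log(within_var), tolerance = 1e-10)
  ## covariate effects in the variance models start at 0
  sim2 <- simulate_melsm(stressor_spec(), list(
    beta = c(3, -0.1, -0.3), alpha = matrix(c(-0.6, 0), 1),
    tau = c(-1.8, 0.2, 0.5), phi_a = 0.8, rho_ua = -0.3), n_subjects = 60,
    n_occasions = 6, stressors = TRUE, seed = 203)
  st2 <- staged_start(sim2$data, stressor_spec(), refine = FALSE)
  expect_equal(unname(st2$alpha[1, 2]), 0)
  expect_equal(unname(st2$tau[2:3]), c(0, 0))
})

test_that("fitting improves on the staged start and is a fixed point at the optimum", {
  tm <- toy_manifest()
  sim <- simulate_melsm(tm$spec, tm$truth, n_subjects = 60, n_occasions = 5,
                        seed = 77)
  st <- staged_start(sim$data, tm$spec)
  ll_start <- marginal_loglik(st, sim$data, tm$spec)
  fit <- fit_melsm(sim$data, tm$spec, start = st, se = FALSE)
  expect_true(fit$converged)
  expect_gte(fit$loglik, ll_start)
  ## refitting from the solution does not move the log-likelihood
  refit <- fit_melsm(sim$data, tm$spec, start = fit$params, se = FALSE)
  expect_equal(refit$loglik, fit$loglik, tolerance = 1e-8)
  ## nesting monotonicity: freeing the scale effect cannot fit worse
  spec0 <- melsm_spec(within = within_spec(random_scale = FALSE))
  fit0 <- fit_melsm(sim$data, spec0, se = FALSE)
  expect_gte(fit$loglik, fit0$loglik - 1e-6)
  ## AIC/BIC identities hold on the constructed objects
  expect_equal(fit$aic, fit$deviance + 2 * fit$n_params)
  expect_equal(fit$bic, fit$deviance + fit$n_params * log(fit$N))
})

test_that("standard errors shrink roughly as 1/sqrt(N)", {
  tm <- toy_manifest()
  se_at <- function(n, seed) {
    sim <- simulate_melsm(tm$spec, tm$truth, n_subjects = n, n_occasions = 5,
                          seed = seed)
    fit_melsm(sim$data, tm$spec)$se
  }
  se1 <- se_at(60, 301)
  se2 <- se_at(240, 302)
  ratio <- se2 / se1
  expect_true(all(is.finite(ratio)))
  expect_true(all(ratio > 0.25 & ratio < 0.85))
})

test_that("model-comparison tables carry sequential tests", {
  tm <- toy_manifest()
  sim <- simulate_melsm(tm$spec, tm$truth, n_subjects = 80, n_occasions = 6,
                        seed = 41)
  f0 <- fit_melsm(sim$data,
                  melsm_spec(within = within_spec(random_scale = FALSE)),
                  se = FALSE)
  f1 <- fit_melsm(sim$data, melsm_spec(), se = FALSE)
  tab <- compare_melsm(homoscedastic = f0, random_scale = f1)
  expect_equal(tab$df[2], 2L)
  expect_equal(tab$lrt[2], f0$deviance - f1$deviance)
  ## data were generated with a strong scale effect: the test should reject
  expect_lt(tab$p[2], 0.01)
})
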