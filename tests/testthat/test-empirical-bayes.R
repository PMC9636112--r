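## minimal fit-like object so EB can be evaluated at known parameters
fake_fit <- function(truth, spec, data, n_quad = 30L)
  structure(list(params = truth, spec = spec, data = data,
                 n_quad = n_quad, converged = TRUE), class = "melsm_fit")

test_that("EB location estimates reduce to the classical BLUP without a scale effect", {
  spec0 <- melsm_spec(within = within_spec(random_scale = FALSE))
  truth0 <- list(beta = c("(Intercept)" = 2), alpha = matrix(-0.7, 1, 1),
                 tau = c("(Intercept)" = -1.2), random_scale = FALSE)
  sim <- simulate_melsm(spec0, truth0, n_subjects = 40, n_occasions = 5,
                        seed = 61)
  eb <- eb_estimates(fake_fit(truth0, spec0, sim$data))
  phi_u2 <- exp(-0.7); sig2 <- exp(-1.2)
  blup <- vapply(split(sim$data$y, sim$data$subject),
                 oracle_blup, numeric(1), beta0 = 2, phi_u2 = phi_u2,
                 sig2 = sig2)
  expect_equal(unname(eb$subjects[["upsilon_hat.(Intercept)"]]),
               unname(blup[as.character(eb$subjects$subject)]),
               tolerance = 1e-8)
  ## without data-dependence, a_hat is identically zero
  expect_equal(eb$subjects$a_hat, rep(0, 40))
})

test_that("EB posterior means match a dense grid posterior on a toy subject", {
  tl <- toy_latent(2, 2)
  sim <- simulate_melsm(tl$spec, tl$truth, n_subjects = 3, n_occasions = 2,
                        seed = 62)
  eb <- eb_estimates(fake_fit(tl$truth, tl$spec, sim$data, n_quad = 60L))
  des <- build_designs(sim$data, tl$spec)
  for (i in 1:3) {
    gp <- oracle_grid_posterior(tl$truth, tl$spec, des[[i]],
                                half_width = 7, n_grid = 161)
    expect_equal(eb$subjects[["upsilon_hat.(Intercept)"]][i], gp$upsilon,
                 tolerance = 1e-3)
    expect_equal(eb$subjects$a_hat[i], gp$a, tolerance = 1e-3)
  }
})

test_that("EB summaries shrink, recover the true effects, and center near zero", {
  tm <- toy_manifest()
  sim <- simulate_melsm(tm$spec, tm$truth, n_subjects = 200, n_occasions = 8,
                        seed = 63)
  fit <- fit_melsm(sim$data, tm$spec, se = FALSE)
  eb <- eb_estimates(fit)
  ## posterior SDs are smaller than the prior SDs for every subject
  prior_sd_u <- sqrt(exp(fit$estimates["alpha.(Intercept)"]))
  expect_true(all(eb$subjects[["upsilon_sd.(Intercept)"]] < prior_sd_u))
  expect_true(all(eb$subjects$a_sd < fit$estimates["phi_a"]))
  ## posterior means track the simulated effects
  expect_gt(cor(eb$subjects[["upsilon_hat.(Intercept)"]],
                sim$effects$upsilon.1), 0.8)
  expect_gt(cor(eb$subjects$a_hat, sim$effects$a), 0.4)
  ## self-consistency at the ML solution
  expect_lt(abs(mean(eb$subjects$a_hat)), 0.08)
  ## residuals: one row per observed cell, centered near zero
  expect_equal(nrow(eb$residuals), nrow(sim$data))
  expect_lt(abs(mean(eb$residuals$residual)), 0.05)
})

test_that("scale-effect recovery improves with more occasions", {
  tm <- toy_manifest()
  truth <- tm$truth; truth$phi_a <- 1.0
  cors <- vapply(c(4L, 16L), function(Tn) {
    sim <- simulate_melsm(tm$spec, truth, n_subjects = 150, n_occasions = Tn,
                          seed = 64)
    eb <- eb_estimates(fake_fit(truth, tm$spec, sim$data))
    cor(eb$subjects$a_hat, sim$effects$a)
  }, numeric(1))
  expect_true(all(cors > 0))
  expect_gt(cors[2], cors[1])
})

test_that("subjects with no observed responses fall back to their prior", {
  tm <- toy_manifest()
  sim <- simulate_melsm(tm$spec, tm$truth, n_subjects = 5, n_occasions = 3,
                        seed = 65)
  df <- as.data.frame(sim$data)
  df$y[df$subject == 2] <- NA
  dat <- diary_data(df, outcome = "y")
  eb <- eb_estimates(fake_fit(tm$truth, tm$spec, dat))
  i <- which(eb$subjects$subject == 2)
  expect_equal(eb$subjects[["upsilon_hat.(Intercept)"]][i], 0,
               tolerance = 1e-10)
  expect_equal(eb$subjects$a_hat[i], 0, tolerance = 1e-10)
  ## prior SDs are returned for such a subject
  expect_equal(eb$subjects$a_sd[i], tm$truth$phi_a, tolerance = 1e-6)
})
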