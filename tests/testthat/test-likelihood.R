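test_that("quadrature rule has the Gauss-Hermite structure", {
  r <- gh_rule(15)
  expect_equal(sum(r$weights), sqrt(pi), tolerance = 1e-12)
  expect_equal(r$nodes, -rev(r$nodes), tolerance = 1e-12)
  expect_equal(gh_rule(1)$nodes, 0)
})

test_that("without a scale effect the likelihood equals the closed-form LMM value", {
  spec0 <- melsm_spec(within = within_spec(random_scale = FALSE))
  truth0 <- list(beta = c("(Intercept)" = 3), alpha = matrix(-1.2, 1, 1),
                 tau = c("(Intercept)" = -2), random_scale = FALSE)
  sim <- simulate_melsm(spec0, truth0, n_subjects = 8, n_occasions = 5,
                        seed = 21)
  ll <- marginal_loglik_manifest(truth0, sim$data, spec0, gh_rule(1))
  expect_equal(ll, oracle_lmm_loglik(truth0, sim$data, spec0),
               tolerance = 1e-10)
  ## a latent spec is rejected by the manifest entry point
  tl <- toy_latent()
  expect_error(marginal_loglik_manifest(tl$truth, sim$data, tl$spec),
               "measurement")
})

test_that("reduced 1-D marginal equals the unreduced integral over (upsilon, a)", {
  ## manifest instance
  tm <- toy_manifest()
  simm <- simulate_melsm(tm$spec, tm$truth, n_subjects = 5, n_occasions = 3,
                         seed = 13)
  ll_red <- marginal_loglik(tm$truth, simm$data, tm$spec, gh_rule(80))
  ll_brute <- oracle_brute_loglik(tm$truth, simm$data, tm$spec, K = 80)
  expect_lt(abs(ll_red - ll_brute), 1e-8)

  ## latent instance (N = 3, T = 2, M = 2), including a missing item cell
  tl <- toy_latent(2, 2)
  siml <- simulate_melsm(tl$spec, tl$truth, n_subjects = 3, n_occasions = 2,
                         seed = 14)
  df <- as.data.frame(siml$data)
  df$item2[2] <- NA
  datl <- diary_data(df, items = c("item1", "item2"))
  ll_red_l <- marginal_loglik(tl$truth, datl, tl$spec, gh_rule(80))
  ll_brute_l <- oracle_brute_loglik(tl$truth, datl, tl$spec, K = 80)
  expect_lt(abs(ll_red_l - ll_brute_l), 1e-8)
})

test_that("latent model with identity measurement collapses to the manifest model", {
  tm <- toy_manifest()
  sim <- simulate_melsm(tm$spec, tm$truth, n_subjects = 6, n_occasions = 3,
                        seed = 33)
  df <- as.data.frame(sim$data)
  df$item1 <- df$y
  dat1 <- diary_data(df, items = "item1")
  ms <- measurement_spec(1, 3)
  spec1 <- melsm_spec(measurement = ms)
  truth1 <- tm$truth
  ## single anchor item: loading 1, intercept 0; tiny uniqueness stands in
  ## for the manifest model's absent measurement error
  truth1$measurement <- list(tau = 0, lambda = 1, psi = 1e-10)
  ll_lat <- marginal_loglik(truth1, dat1, spec1, gh_rule(30))
  ll_man <- marginal_loglik(tm$truth, sim$data, tm$spec, gh_rule(30))
  expect_equal(ll_lat, ll_man, tolerance = 1e-6)
})

test_that("single standard-normal observation gives -log(2*pi)/2", {
  dat <- diary_data(data.frame(subject = 1, occasion = 1, y = 0),
                    outcome = "y")
  spec <- melsm_spec(within = within_spec(random_scale = FALSE))
  truth <- list(beta = c("(Intercept)" = 0), alpha = matrix(-Inf, 1, 1),
                tau = c("(Intercept)" = 0), random_scale = FALSE)
  truth$alpha <- matrix(log(1e-300), 1, 1)   # variance numerically zero
  ll <- marginal_loglik(truth, dat, spec, gh_rule(1))
  expect_equal(ll, -0.5 * log(2 * pi), tolerance = 1e-10)
})

test_that("conditional response moments match a simulation oracle", {
  tl <- toy_latent(2, 2)
  sim <- simulate_melsm(tl$spec, tl$truth, n_subjects = 1, n_occasions = 2,
                        seed = 55)
  d <- build_designs(sim$data, tl$spec)[[1]]
  a0 <- 0.7
  cm <- conditional_moments(tl$truth, tl$spec, d, a = a0)
  ## simulate y | a directly from the model equations
  set.seed(991)
  ndraw <- 2e5
  phi_u2 <- exp(tl$truth$alpha[1, 1]); phi_a <- tl$truth$phi_a
  rho <- tl$truth$rho_ua
  cv <- rho * sqrt(phi_u2) * phi_a
  mu_ua <- cv / phi_a^2 * a0
  v_ua <- phi_u2 - cv^2 / phi_a^2
  ups <- rnorm(ndraw, mu_ua, sqrt(v_ua))
  lam <- c(1, tl$truth$measurement$lambda[2])
  tau_m <- c(0, tl$truth$measurement$tau[2])
  sig2 <- exp(tl$truth$tau[[1]] + a0)
  Y <- matrix(NA, ndraw, 4)
  for (t in 1:2) {
    eta <- tl$truth$beta[[1]] + ups + rnorm(ndraw, 0, sqrt(sig2))
    for (m in 1:2)
      Y[, (t - 1) * 2 + m] <- tau_m[m] + lam[m] * eta +
        rnorm(ndraw, 0, sqrt(tl$truth$measurement$psi[m]))
  }
  expect_equal(as.vector(cm$mu), colMeans(Y), tolerance = 0.02)
  expect_equal(cm$Sigma, cov(Y), tolerance = 0.05, ignore_attr = TRUE)
  ## exchangeable special case: compound symmetry inside the latent block
  truth_cs <- tl$truth; truth_cs$rho_ua <- 0
  cm_cs <- conditional_moments(truth_cs, tl$spec, d, a = 0)
  expect_equal(cm_cs$Sigma[1, 3], cm_cs$Sigma[3, 1])
  expect_equal(cm_cs$Sigma[1, 3], phi_u2 * lam[1]^2, tolerance = 1e-10)
})

test_that("log-likelihood is invariant to orderings and additive over subjects", {
  tm <- toy_manifest()
  sim <- simulate_melsm(tm$spec, tm$truth, n_subjects = 6, n_occasions = 4,
                        seed = 77)
  df <- as.data.frame(sim$data)
  ll <- marginal_loglik(tm$truth, sim$data, tm$spec)
  ## permute rows of the file
  df2 <- df[rev(seq_len(nrow(df))), ]
  ll2 <- marginal_loglik(tm$truth, diary_data(df2, outcome = "y"), tm$spec)
  expect_equal(ll, ll2, tolerance = 1e-10)
  ## dropping a subject removes exactly its contribution
  per <- marginal_loglik(tm$truth, sim$data, tm$spec, per_subject = TRUE)
  expect_equal(sum(per), ll, tolerance = 1e-10)
  keep <- df$subject != 3
  ll_wo <- marginal_loglik(tm$truth, diary_data(df[keep, ], outcome = "y"),
                           tm$spec)
  expect_equal(ll - per[["3"]], ll_wo, tolerance = 1e-10)
})

test_that("quadrature refinement stabilizes monotonically", {
  tl <- toy_latent(2, 2)
  sim <- simulate_melsm(tl$spec, tl$truth, n_subjects = 10, n_occasions = 2,
                        seed = 88)
  ll <- sapply(c(5, 10, 20, 40), function(k)
    marginal_loglik(tl$truth, sim$data, tl$spec, gh_rule(k)))
  gaps <- abs(diff(ll))
  expect_true(all(diff(gaps) < 0))
  expect_lt(abs(ll[4] - ll[3]), 1e-8)
})

test_that("deviance is -2 log-likelihood", {
  expect_equal(deviance_from_loglik(-2768.5), 5537)
  expect_equal(deviance_from_loglik(0), 0)
})
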