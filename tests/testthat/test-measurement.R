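test_that("loading matrix has the block structure of the longitudinal factor model", {
  ## all loadings 1, 5 items x 2 occasions: 10 x 2 block indicator matrix
  ms <- measurement_spec(5, 2)
  L <- build_lambda(ms, rep(1, 5), occasions = 1:2)
  expect_equal(dim(L), c(10L, 2L))
  expect_true(all(L %in% c(0, 1)))
  expect_equal(L[1:5, 1], rep(1, 5))
  expect_equal(L[6:10, 2], rep(1, 5))
  ## every row has exactly one nonzero entry
  expect_true(all(rowSums(L != 0) == 1))

  ## 5 items x 8 days with the estimated loading profile
  lam <- c(1, 1.15, 1.13, 1.15, 1.32)
  ms8 <- measurement_spec(5, 8)
  L8 <- build_lambda(ms8, lam, occasions = 1:8)
  expect_equal(dim(L8), c(40L, 8L))
  expect_equal(L8[37, 8], 1.15)          # row 2 of block 8 holds lambda_2
  expect_equal(L8[1, 1], 1)              # anchor loading fixed at 1
  expect_true(all(rowSums(L8 != 0) == 1))

  ## masking one item drops its row and leaves the rest unchanged
  obs <- matrix(TRUE, 5, 8); obs[3, 1] <- FALSE
  Lm <- build_lambda(ms8, lam, occasions = 1:8, obs = obs)
  expect_equal(nrow(Lm), 39L)
  expect_equal(Lm, L8[-3, ])

  ## an occasion without the anchor item is unidentified
  obs2 <- matrix(TRUE, 5, 8); obs2[1, 4] <- FALSE
  expect_error(build_lambda(ms8, lam, occasions = 1:8, obs = obs2), "anchor")
})

test_that("constraint maps count free parameters the way invariance testing needs", {
  ## fully invariant 5-item/8-day model: 4 + 4 + 5 = 13 measurement parameters
  expect_equal(n_free_measurement(measurement_spec(5, 8)), 13L)
  ## unconstrained uniquenesses by day: 5 x 8 = 40 slots
  ms_u <- measurement_spec(5, 8, uniquenesses = "cell")
  expect_equal(length(measurement_labels(ms_u)$uniquenesses), 40L)
  ## configural model
  expect_equal(n_free_measurement(
    measurement_spec(5, 8, intercepts = "cell", loadings = "cell",
                     uniquenesses = "cell")), 104L)
})

test_that("pack/unpack measurement is a round-trip and enforces constraints", {
  ms <- measurement_spec(5, 3)
  tau <- c(0, -0.5, -0.6, -0.55, -1.4)
  lam <- c(1, 1.15, 1.13, 1.15, 1.32)
  psi <- c(0.2, 0.22, 0.35, 0.21, 0.52)
  free <- pack_measurement(ms, tau, lam, psi)
  expect_length(free, 13L)
  tabs <- unpack_measurement(free, ms)
  expect_equal(tabs$tau, matrix(tau, 5, 3))
  expect_equal(tabs$lambda, matrix(lam, 5, 3))
  expect_equal(tabs$psi, matrix(psi, 5, 3))
  ## random free vector round-trips exactly through unpack -> pack
  set.seed(31)
  v <- stats::setNames(rnorm(13), names(free))
  tabs2 <- unpack_measurement(v, ms)
  expect_equal(pack_measurement(ms, tabs2$tau, tabs2$lambda, tabs2$psi), v)
  ## cells sharing a label must agree
  bad_tau <- matrix(tau, 5, 3); bad_tau[2, 3] <- 9
  expect_error(pack_measurement(ms, bad_tau, lam, psi), "unequal")
  ## a map with an empty cell is not a partition
  m <- constraint_map(5, 3); m[2, 2] <- ""
  expect_error(measurement_spec(5, 3, intercepts = m), "partition")
})

test_that("invariance ladder reproduces the nested-test degrees of freedom", {
  tl <- toy_latent(5, 8)
  sim <- simulate_melsm(tl$spec, tl$truth, n_subjects = 12, n_occasions = 8,
                        seed = 404)
  tab <- invariance_sequence(sim$data,
                             free_intercepts_equal = rbind(c(4, 8)),
                             free_intercepts_both = rbind(c(4, 1), c(4, 8),
                                                          c(5, 8)),
                             fit_fn = NULL)
  df <- stats::setNames(tab$df, tab$model)
  expect_equal(df[["equal_loadings"]], 28L)
  expect_equal(df[["equal_intercepts"]], 27L)
  expect_equal(df[["equal_loadings_intercepts"]], 53L)
  expect_equal(df[["equal_uniquenesses"]], 35L)
})

test_that("invariance fits return deviances, BICs and valid LRTs", {
  tl <- toy_latent(3, 3)
  sim <- simulate_melsm(tl$spec, tl$truth, n_subjects = 60, n_occasions = 3,
                        seed = 99)
  tab <- invariance_sequence(sim$data)
  expect_true(all(is.finite(tab$deviance)))
  expect_true(all(is.finite(tab$bic)))
  ## data were generated invariant, so equality constraints should not be
  ## overwhelmingly rejected, and restricted models cannot fit better
  nested <- !is.na(tab$lrt)
  expect_true(all(tab$lrt[nested] > -1e-4))
  ## 3 items x 3 occasions: 4, 4, 8 free parameters released vs configural,
  ## and 6 uniquenesses released in the final step
  expect_equal(tab$df[nested], c(4L, 4L, 8L, 6L))
  ## identical specs compared give a zero statistic
  same <- lrt(tab$deviance[1], tab$deviance[1], 0)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})
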