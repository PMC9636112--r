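# Independent oracles used to cross-check the likelihood engine.  These are
# deliberately written the "dense textbook" way (full covariance, Cholesky),
# sharing no code path with the package's low-rank evaluation.

## dense multivariate normal log-density
dmvnorm_chol <- function(y, mu, Sigma) {
  cS <- chol(Sigma)
  u <- backsolve(cS, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(cS))) + sum(u^2))
}

## per-subject conditional moments given the full random-effect vector
## (upsilon, a), assembled densely from the designs
oracle_cond_moments <- function(truth, spec, d, ups, a) {
  mu_eta <- as.vector(d$Gamma %*% truth$beta + d$Z %*% ups)
  sig2 <- exp(as.vector(d$V %*% truth$tau) + a)
  if (is.null(spec$measurement))
    return(list(mu = mu_eta, Sigma = diag(sig2, d$n)))
  ms <- spec$measurement
  obs <- t(!is.na(d$y))
  lam_tab <- if (is.matrix(truth$measurement$lambda)) truth$measurement$lambda
             else matrix(truth$measurement$lambda, ms$n_items, ms$n_occasions)
  tau_tab <- if (is.matrix(truth$measurement$tau)) truth$measurement$tau
             else matrix(truth$measurement$tau, ms$n_items, ms$n_occasions)
  psi_tab <- if (is.matrix(truth$measurement$psi)) truth$measurement$psi
             else matrix(truth$measurement$psi, ms$n_items, ms$n_occasions)
  lam_tab[ms$anchor, ] <- 1; tau_tab[ms$anchor, ] <- 0
  mu <- c(); psis <- c(); Lrows <- NULL
  for (t in seq_len(d$n)) {
    occ <- d$occasions[t]
    for (m in which(obs[, t])) {
      mu <- c(mu, tau_tab[m, occ] + lam_tab[m, occ] * mu_eta[t])
      psis <- c(psis, psi_tab[m, occ])
      row <- numeric(d$n); row[t] <- lam_tab[m, occ]
      Lrows <- rbind(Lrows, row)
    }
  }
  list(mu = mu, Sigma = Lrows %*% diag(sig2, d$n) %*% t(Lrows) +
         diag(psis, length(psis)))
}

## joint covariance of (upsilon, a) from a natural truth list (p* = 1)
oracle_phi_c <- function(truth) {
  phi_u <- exp(truth$alpha[1, 1])
  phi_a <- truth$phi_a %||% 0
  rho <- truth$rho_ua %||% 0
  cv <- rho * sqrt(phi_u) * phi_a
  matrix(c(phi_u, cv, cv, phi_a^2), 2, 2)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## unreduced marginal log-likelihood: tensor Gauss-Hermite over the full
## random-effect vector (upsilon, a), one subject at a time
oracle_brute_loglik <- function(truth, data, spec, K = 60) {
  des <- build_designs(data, spec)
  g <- pracma::gaussHermite(K)
  Phi_c <- oracle_phi_c(truth)
  ev <- eigen(Phi_c, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2)
  nodes <- as.matrix(expand.grid(g$x, g$x))
  logw <- log(expand.grid(g$w, g$w)[, 1]) + log(expand.grid(g$w, g$w)[, 2]) -
    log(pi)
  tot <- 0
  for (d in des) {
    ce <- sqrt(2) * nodes %*% t(L)            # draws of (upsilon, a)
    ldens <- vapply(seq_len(nrow(ce)), function(r) {
      cm <- oracle_cond_moments(truth, spec, d, ce[r, 1], ce[r, 2])
      y <- if (is.null(spec$measurement)) d$y else {
        obs <- t(!is.na(d$y)); as.vector(t(d$y))[as.vector(obs)]
      }
      dmvnorm_chol(y, cm$mu, cm$Sigma)
    }, numeric(1))
    m <- max(ldens + logw)
    tot <- tot + m + log(sum(exp(ldens + logw - m)))
  }
  tot
}

## closed-form marginal log-likelihood when phi_a^2 = 0 (linear mixed model):
## Sigma_i = Z Phi_u Z' + diag(sigma^2), dense
oracle_lmm_loglik <- function(truth, data, spec) {
  des <- build_designs(data, spec)
  sum(vapply(des, function(d) {
    phi_u <- exp(sum(truth$alpha[1, ] * d$B))
    sig2 <- exp(as.vector(d$V %*% truth$tau))
    S <- phi_u * tcrossprod(d$Z) + diag(sig2, d$n)
    dmvnorm_chol(d$y, as.vector(d$Gamma %*% truth$beta), S)
  }, numeric(1)))
}

## classical BLUP of a random intercept, balanced model without a scale effect
oracle_blup <- function(y_i, beta0, phi_u2, sig2) {
  n <- length(y_i)
  shrink <- phi_u2 / (phi_u2 + sig2 / n)
  shrink * (mean(y_i) - beta0)
}

## dense 2-D grid posterior over (upsilon, a) for one subject
oracle_grid_posterior <- function(truth, spec, d, half_width = 6, n_grid = 201) {
  Phi_c <- oracle_phi_c(truth)
  su <- sqrt(Phi_c[1, 1]); sa <- sqrt(Phi_c[2, 2])
  ug <- seq(-half_width * su, half_width * su, length.out = n_grid)
  ag <- seq(-half_width * sa, half_width * sa, length.out = n_grid)
  y <- if (is.null(spec$measurement)) d$y else {
    obs <- t(!is.na(d$y)); as.vector(t(d$y))[as.vector(obs)]
  }
  lp <- outer(seq_along(ug), seq_along(ag), Vectorize(function(i, j) {
    cm <- oracle_cond_moments(truth, spec, d, ug[i], ag[j])
    dmvnorm_chol(y, cm$mu, cm$Sigma) +
      dmvnorm_chol(c(ug[i], ag[j]), c(0, 0), Phi_c)
  }))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  list(upsilon = sum(rowSums(w) * ug), a = sum(colSums(w) * ag))
}
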