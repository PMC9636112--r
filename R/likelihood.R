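#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for integrals of the form
#' \code{int exp(-t^2) f(t) dt} (physicists' convention: the weights sum to
#' \code{sqrt(pi)}, the nodes are symmetric about zero).  With the
#' substitution \code{a = sqrt(2) * phi_a * t} the rule integrates a
#' function against the \code{N(0, phi_a^2)} density, so it is
#' parameter-independent and can be computed once per fit.
#'
#' @param n number of quadrature points (default 10).
#' @return A list with \code{n}, \code{nodes} and \code{weights}.
#' @export
gh_rule <- function(n = 10L) {
  stopifnot(n >= 1L)
  if (n == 1L) return(list(n = 1L, nodes = 0, weights = sqrt(pi)))
  g <- pracma::gaussHermite(n)
  list(n = as.integer(n), nodes = g$x, weights = g$w)
}

## log-density of columns of Resid under N(0, diag(D) + U S U'),
## vectorized over columns; S is PSD (eigenvalues clipped at zero).
## Woodbury/low-rank form: no dense covariance is ever factorized.
ld_lowrank <- function(Resid, D, U, S) {
  n <- nrow(Resid)
  Wi <- 1 / D
  q1 <- colSums(Resid * Resid * Wi)
  ldetD <- sum(log(D))
  k <- if (is.null(U)) 0L else ncol(U)
  if (k) {
    es <- eigen((S + t(S)) / 2, symmetric = TRUE)
    keep <- es$values > 1e-12 * max(abs(es$values), 1e-300)
    if (any(es$values < -1e-8 * max(abs(es$values)))) return(rep(NaN, ncol(Resid)))
    if (any(keep)) {
      V <- U %*% (es$vectors[, keep, drop = FALSE] *
                    rep(sqrt(es$values[keep]), each = nrow(es$vectors)))
      M <- diag(sum(keep)) + crossprod(V, V * Wi)
      cM <- chol(M)
      Bm <- crossprod(V, Resid * Wi)
      u <- backsolve(cM, Bm, transpose = TRUE)
      q1 <- q1 - colSums(u * u)
      ldetD <- ldetD + 2 * sum(log(diag(cM)))
    }
  }
  -0.5 * (n * log2pi + ldetD + q1)
}

## Build the evaluation engine: per-subject designs, with subjects sharing
## identical designs and observation patterns grouped so that the
## per-quadrature-point covariance factorization is done once per group.
prepare_engine <- function(data, spec) {
  designs <- build_designs(data, spec)
  latent <- is_latent(spec)
  M <- if (latent) spec$measurement$n_items else 0L

  per <- lapply(designs, function(d) {
    if (latent) {
      obs <- t(!is.na(d$y))            # M x T_i, occasion-major columns
      item_idx <- integer(0); occ_idx <- integer(0); yv <- numeric(0)
      for (t in seq_len(d$n)) {
        mobs <- which(obs[, t])
        item_idx <- c(item_idx, mobs)
        occ_idx <- c(occ_idx, rep(d$occasions[t], length(mobs)))
        yv <- c(yv, d$y[t, mobs])
      }
      d$obs <- obs; d$item_idx <- item_idx; d$occ_idx <- occ_idx
      d$yvec <- yv; d$nobs <- length(yv)
    } else {
      if (anyNA(d$y)) {
        keep <- !is.na(d$y)
        d$Gamma <- d$Gamma[keep, , drop = FALSE]
        d$Z <- d$Z[keep, , drop = FALSE]
        d$V <- d$V[keep, , drop = FALSE]
        d$occasions <- d$occasions[keep]
        d$y <- d$y[keep]; d$n <- sum(keep)
      }
      d$yvec <- d$y; d$nobs <- d$n
    }
    d$sig <- paste(c(d$n, signif(c(d$Gamma, d$Z, d$V, d$B), 12), d$occasions,
                     if (latent) c(d$item_idx, d$occ_idx)), collapse = ",")
    d
  })

  sigs <- vapply(per, `[[`, "", "sig")
  groups <- lapply(split(seq_along(per), factor(sigs, levels = unique(sigs))),
    function(ii) {
      d <- per[[ii[1]]]
      list(idx = ii, subjects = sapply(per[ii], `[[`, "subject"),
           n = d$n, occasions = d$occasions, Gamma = d$Gamma, Z = d$Z,
           V = d$V, B = d$B, obs = d$obs, item_idx = d$item_idx,
           occ_idx = d$occ_idx, nobs = d$nobs,
           Y = matrix(vapply(per[ii], `[[`, numeric(d$nobs), "yvec"),
                      nrow = d$nobs, ncol = length(ii)))
    })
  list(spec = spec, layout = param_layout(spec), latent = latent,
       groups = groups, N = length(per),
       subjects = vapply(per, function(d) as.character(d$subject), ""))
}

## per-subject marginal log-likelihood contributions for unconstrained theta
loglik_engine <- function(theta, engine, rule) {
  p <- unpack_params(theta, engine$layout)
  spec <- engine$spec
  rs <- spec$within$random_scale
  if (rs) {
    nodes <- sqrt(2) * p$phi_a * rule$nodes
    logw <- log(rule$weights) - 0.5 * log(pi)
  } else {
    nodes <- 0; logw <- 0
  }
  nq <- length(nodes)
  ll <- numeric(engine$N)
  mtab <- if (engine$latent) p$measurement else NULL

  for (g in engine$groups) {
    rem <- re_moments(p, g$B)
    Phi_cond <- if (rs)
      rem$Phi - tcrossprod(rem$phi_ua) / p$phi_a^2 else rem$Phi
    slope <- if (rs) rem$phi_ua / p$phi_a^2 else numeric(engine$layout$pstar)
    eta_mean <- as.vector(g$Gamma %*% p$beta)
    logs2 <- as.vector(g$V %*% p$tau)
    if (engine$latent) {
      lam_cell <- mtab$lambda[cbind(g$item_idx, g$occ_idx)]
      lam_cell[g$item_idx == spec$measurement$anchor] <- 1
      Lam <- matrix(0, g$nobs, g$n)
      Lam[cbind(seq_len(g$nobs), match(g$occ_idx, g$occasions))] <- lam_cell
      tau_y <- mtab$tau[cbind(g$item_idx, g$occ_idx)]
      psi_y <- mtab$psi[cbind(g$item_idx, g$occ_idx)]
    }
    ld <- matrix(NA_real_, nq, ncol(g$Y))
    for (k in seq_len(nq)) {
      a <- nodes[k]
      m_a <- slope * a
      sig2 <- exp(logs2 + a)
      if (engine$latent) {
        S_eta <- g$Z %*% Phi_cond %*% t(g$Z) + diag(sig2, g$n)
        mu <- tau_y + as.vector(Lam %*% (eta_mean + g$Z %*% m_a))
        ld[k, ] <- ld_lowrank(g$Y - mu, psi_y, Lam, S_eta) + logw[k]
      } else {
        mu <- eta_mean + as.vector(g$Z %*% m_a)
        ld[k, ] <- ld_lowrank(g$Y - mu, sig2, g$Z, Phi_cond) + logw[k]
      }
    }
    ll[g$idx] <- if (nq == 1L) ld[1, ] else logsumexp(ld)
  }
  ll
}

#' Marginal log-likelihood of a location scale model
#'
#' Evaluates the marginal log-likelihood at a natural-scale parameter set
#' by integrating the conditional normal density of each subject's
#' responses over the random scale effect with Gauss-Hermite quadrature.
#' The location random effects are eliminated analytically: conditional on
#' \code{a_i} the model is linear in \code{upsilon_i}, so only the
#' one-dimensional integral over \code{a_i} remains.  Node densities are
#' combined in log space (log-sum-exp), so the result is finite whenever
#' any node density is.  When there is no random scale effect the
#' likelihood is closed-form and evaluated exactly at a single point.
#'
#' @param params natural-scale parameter list with elements \code{beta},
#'   \code{alpha}, \code{tau}, and (with a random scale effect)
#'   \code{phi_a} (SD) and \code{rho_ua}; for multiple random effects also
#'   \code{R_upsilon}; in latent mode a \code{measurement} list with
#'   \code{tau}, \code{lambda}, \code{psi} tables.
#' @param data a [diary_data] object.
#' @param spec a [melsm_spec].
#' @param rule a [gh_rule()] quadrature rule.
#' @param per_subject return the vector of per-subject contributions
#'   instead of their sum?
#' @return The log-likelihood (or the per-subject vector).
#' @export
marginal_loglik <- function(params, data, spec, rule = gh_rule(10L),
                            per_subject = FALSE) {
  engine <- prepare_engine(data, spec)
  theta <- pack_params(params, engine$layout)
  ll <- loglik_engine(theta, engine, rule)
  if (per_subject) stats::setNames(ll, engine$subjects) else sum(ll)
}

#' @rdname marginal_loglik
#' @details \code{marginal_loglik_manifest} is the manifest-outcome case:
#'   it requires a spec without a measurement model (identity loading, no
#'   uniquenesses, zero measurement intercepts) and is otherwise identical.
#' @export
marginal_loglik_manifest <- function(params, data, spec, rule = gh_rule(10L),
                                     per_subject = FALSE) {
  if (is_latent(spec))
    stop("spec has a measurement model; use marginal_loglik()")
  marginal_loglik(params, data, spec, rule, per_subject)
}

#' Conditional moments of a subject's responses given the scale effect
#'
#' Mean and covariance of the observed response vector for one subject,
#' conditional on the random scale effect \code{a}: the location random
#' effects are integrated out using their conditional-normal law given
#' \code{a}.  In latent mode the latent-level moments are mapped through
#' the loading matrix and the uniquenesses are added.
#'
#' @param params natural-scale parameter list (see [marginal_loglik()]).
#' @param spec a [melsm_spec].
#' @param subject one element of [build_designs()] output.
#' @param a scale-effect value.
#' @return List with \code{mu} and \code{Sigma} for the subject's observed
#'   responses (missing cells dropped).
#' @export
conditional_moments <- function(params, spec, subject, a = 0) {
  layout <- param_layout(spec)
  p <- unpack_params(pack_params(params, layout), layout)
  rs <- spec$within$random_scale
  rem <- re_moments(p, subject$B)
  Phi_cond <- if (rs) rem$Phi - tcrossprod(rem$phi_ua) / p$phi_a^2 else rem$Phi
  m_a <- if (rs) rem$phi_ua * a / p$phi_a^2 else numeric(layout$pstar)
  mu_eta <- as.vector(subject$Gamma %*% p$beta + subject$Z %*% m_a)
  sig2 <- exp(as.vector(subject$V %*% p$tau) + a)
  S_eta <- subject$Z %*% Phi_cond %*% t(subject$Z) + diag(sig2, subject$n)
  if (!is_latent(spec)) {
    if (anyNA(subject$y)) {
      keep <- !is.na(subject$y)
      return(list(mu = mu_eta[keep], Sigma = S_eta[keep, keep, drop = FALSE]))
    }
    return(list(mu = mu_eta, Sigma = S_eta))
  }
  ms <- spec$measurement
  obs <- t(!is.na(subject$y))
  Lam <- build_lambda(ms, p$measurement$lambda, subject$occasions, obs)
  cells <- cbind(rep(seq_len(ms$n_items), subject$n)[as.vector(obs)],
                 rep(subject$occasions, each = ms$n_items)[as.vector(obs)])
  mu <- p$measurement$tau[cells] + as.vector(Lam %*% mu_eta)
  Sigma <- Lam %*% S_eta %*% t(Lam) + diag(p$measurement$psi[cells],
                                           nrow(cells))
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("conditional response covariance is not positive definite; invalid parameters")
  list(mu = mu, Sigma = Sigma)
}

#' Deviance from a log-likelihood
#'
#' The deviance convention used throughout: \code{-2} times the maximized
#' log-likelihood, additive over independent subjects.
#'
#' @param loglik log-likelihood value.
#' @return \code{-2 * loglik}.
#' @export
deviance_from_loglik <- function(loglik) -2 * loglik
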