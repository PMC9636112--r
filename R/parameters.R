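## Packed parameter layout
##
## All model parameters live in one unconstrained vector theta for
## optimization:
##   beta        fixed location effects (occasion-varying then subject-level)
##   alpha       between-variance coefficients, one row per random effect
##               (log-variance scale, so already unconstrained)
##   z_rho_u     atanh correlations among multiple random location effects
##   tau         within-variance coefficients (log-variance scale)
##   log_phi_a   log SD of the random scale effect        (if random_scale)
##   z_rho_ua    atanh correlations of upsilon with a     (if random_scale)
##   m_tau / m_lambda / m_logpsi   free measurement parameters (if latent)
## The log/atanh transforms keep the implied joint random-effects
## covariance positive definite and the uniquenesses positive throughout
## optimization.

param_layout <- function(spec) {
  loc <- spec$location; bv <- spec$between; wv <- spec$within
  nm <- function(terms) ifelse(terms == "1", "(Intercept)", terms)
  beta_names <- paste0("beta.", nm(c(loc$x_terms, loc$w_terms)))
  pstar <- length(loc$random)
  b_terms <- c("(Intercept)", bv$terms)
  alpha_names <- if (pstar == 1L) paste0("alpha.", b_terms)
    else as.vector(t(outer(nm(loc$random), b_terms,
                           function(r, tmn) paste0("alpha.", r, ".", tmn))))
  nrho_u <- pstar * (pstar - 1L) / 2L
  rho_u_names <- if (nrho_u) paste0("z_rho_u.", seq_len(nrho_u)) else character()
  tau_names <- paste0("tau.", c("(Intercept)", nm(wv$x_terms), nm(wv$w_terms)))
  scale_names <- if (wv$random_scale)
    c("log_phi_a", paste0("z_rho_ua.", nm(loc$random))) else character()
  meas_names <- character()
  if (is_latent(spec)) {
    lab <- measurement_labels(spec$measurement)
    meas_names <- c(paste0("m_tau.", lab$intercepts, recycle0 = TRUE),
                    paste0("m_lambda.", lab$loadings, recycle0 = TRUE),
                    paste0("m_logpsi.", lab$uniquenesses, recycle0 = TRUE))
  }
  layout <- list(spec = spec, pstar = pstar, nb = length(b_terms),
                 names = list(beta = beta_names, alpha = alpha_names,
                              z_rho_u = rho_u_names, tau = tau_names,
                              scale = scale_names, meas = meas_names))
  layout$all_names <- unlist(layout$names, use.names = FALSE)
  layout$n <- length(layout$all_names)
  layout
}

## split theta by block
theta_blocks <- function(theta, layout) {
  stopifnot(length(theta) == layout$n)
  ends <- cumsum(lengths(layout$names))
  starts <- ends - lengths(layout$names) + 1L
  out <- Map(function(s, e) if (e >= s) theta[s:e] else numeric(0),
             starts, ends)
  names(out) <- names(layout$names)
  out
}

## unconstrained theta -> natural-scale parameter list
unpack_params <- function(theta, layout) {
  b <- theta_blocks(theta, layout)
  spec <- layout$spec
  pstar <- layout$pstar
  out <- list(
    beta = stats::setNames(b$beta, sub("^beta\\.", "", layout$names$beta)),
    alpha = matrix(b$alpha, nrow = pstar, ncol = layout$nb, byrow = TRUE),
    R_upsilon = corr_from_atanh(b$z_rho_u, pstar),
    tau = stats::setNames(b$tau, sub("^tau\\.", "", layout$names$tau)),
    phi_a = 0, rho_ua = numeric(pstar), random_scale = spec$within$random_scale)
  if (spec$within$random_scale) {
    out$phi_a <- exp(b$scale[1])
    out$rho_ua <- tanh(b$scale[-1])
  }
  if (is_latent(spec)) {
    lab <- measurement_labels(spec$measurement)
    k1 <- length(lab$intercepts); k2 <- length(lab$loadings)
    k3 <- length(lab$uniquenesses)
    free <- c(stats::setNames(b$meas[seq_len(k1)], paste0("tau.", lab$intercepts, recycle0 = TRUE)),
              stats::setNames(b$meas[k1 + seq_len(k2)], paste0("lambda.", lab$loadings, recycle0 = TRUE)),
              stats::setNames(exp(b$meas[k1 + k2 + seq_len(k3)]),
                              paste0("psi.", lab$uniquenesses, recycle0 = TRUE)))
    out$measurement <- unpack_measurement(free, spec$measurement)
  }
  out
}

## natural-scale parameter list -> unconstrained theta
pack_params <- function(natural, layout) {
  spec <- layout$spec
  pstar <- layout$pstar
  alpha <- natural$alpha
  if (!is.matrix(alpha)) alpha <- matrix(alpha, nrow = pstar, byrow = TRUE)
  stopifnot(ncol(alpha) == layout$nb)
  z_rho_u <- if (pstar > 1L) atanh(natural$R_upsilon[lower.tri(natural$R_upsilon)])
             else numeric()
  theta <- c(natural$beta, as.vector(t(alpha)), z_rho_u, natural$tau)
  if (spec$within$random_scale) {
    phi_a <- natural$phi_a
    if (is.null(phi_a) || phi_a <= 0) stop("phi_a must be positive")
    rho <- natural$rho_ua %||% numeric(pstar)
    theta <- c(theta, log(phi_a), atanh(rho))
  }
  if (is_latent(spec)) {
    m <- natural$measurement
    free <- pack_measurement(spec$measurement, m$tau, m$lambda, m$psi)
    lab <- measurement_labels(spec$measurement)
    k12 <- length(lab$intercepts) + length(lab$loadings)
    iu <- k12 + seq_len(length(lab$uniquenesses))
    free[iu] <- log(free[iu])
    theta <- c(theta, unname(free))
  }
  stats::setNames(theta, layout$all_names)
}

## natural-scale reporting vector (the quantities tables print: variances as
## log-scale coefficients, phi_a as an SD, correlations, psi on the
## variance scale)
natural_vector <- function(theta, layout) {
  p <- unpack_params(theta, layout)
  spec <- layout$spec
  out <- c(stats::setNames(p$beta, layout$names$beta),
           stats::setNames(as.vector(t(p$alpha)), layout$names$alpha))
  if (layout$pstar > 1L)
    out <- c(out, stats::setNames(p$R_upsilon[lower.tri(p$R_upsilon)],
                                  sub("^z_", "", layout$names$z_rho_u)))
  out <- c(out, stats::setNames(p$tau, layout$names$tau))
  if (spec$within$random_scale)
    out <- c(out, phi_a = unname(p$phi_a),
             stats::setNames(p$rho_ua, sub("^z_", "", layout$names$scale[-1])))
  if (is_latent(spec)) {
    m <- p$measurement
    free <- pack_measurement(spec$measurement, m$tau, m$lambda, m$psi)
    out <- c(out, free)
  }
  out
}

## subject-level random-effect moments implied by the parameters:
## SDs exp(alpha' B / 2) per effect, Phi_upsilon = D R D, and the
## cross-covariances rho_ua * sd_j * phi_a
re_moments <- function(p, Bvec) {
  eta <- as.vector(p$alpha %*% Bvec)
  sdv <- exp(eta / 2)
  Phi <- diag(sdv, length(sdv)) %*% p$R_upsilon %*% diag(sdv, length(sdv))
  Phi <- (Phi + t(Phi)) / 2
  phi_ua <- p$rho_ua * sdv * p$phi_a
  list(sd = sdv, Phi = Phi, phi_ua = phi_ua)
}
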