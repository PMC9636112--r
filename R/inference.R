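#' Staged starting values
#'
#' Builds starting values the way the models are fit in practice: a
#' fixed-effects (closed-form least squares) stage supplies the location
#' coefficients and a moment decomposition of the residuals supplies the
#' between- and within-variance intercepts; covariate effects in both
#' variance models start at 0.  With \code{refine = TRUE} and a random
#' scale effect in the spec, a second-stage ML fit of the model without
#' the random scale refines those values before the scale-effect SD is
#' freed (started at a small positive value, its correlations with the
#' location effects at 0).  In latent mode the measurement block starts at
#' a one-factor analysis solution rescaled to the anchor item.
#'
#' @param data a [diary_data] object.
#' @param spec a [melsm_spec].
#' @param refine run the intermediate no-random-scale ML fit?
#' @param n_quad quadrature points for the refinement fit.
#' @return Natural-scale parameter list usable as \code{start} in
#'   [fit_melsm()].
#' @export
staged_start <- function(data, spec, refine = TRUE, n_quad = 10L) {
  designs <- build_designs(data, spec)
  layout <- param_layout(spec)
  pstar <- layout$pstar
  latent <- is_latent(spec)
  ms <- spec$measurement

  meas <- NULL
  if (latent) {
    Ymat <- do.call(rbind, lapply(designs, `[[`, "y"))
    meas <- measurement_start(Ymat, ms)
    ## anchor item as pseudo-outcome for the structural stage
    yv_list <- lapply(designs, function(d) d$y[, ms$anchor])
    extra_var <- mean(meas$psi[ms$anchor, ])
  } else {
    yv_list <- lapply(designs, `[[`, "y")
    extra_var <- 0
  }

  G <- do.call(rbind, lapply(designs, `[[`, "Gamma"))
  yv <- unlist(yv_list)
  subj <- rep(seq_along(designs), vapply(yv_list, length, 1L))
  keep <- !is.na(yv)
  beta <- stats::lm.fit(G[keep, , drop = FALSE], yv[keep])$coefficients
  beta[is.na(beta)] <- 0
  r <- yv[keep] - as.vector(G[keep, , drop = FALSE] %*% beta)
  sk <- subj[keep]
  rbar <- tapply(r, sk, mean)
  n_i <- tabulate(sk)[unique(sk)]
  ok <- n_i > 1L
  s2w <- if (any(ok)) sum((r - rbar[as.character(sk)])^2) /
           max(1, sum(n_i) - length(n_i)) else stats::var(r)
  s2w <- max(s2w, 1e-4)
  s2w_eta <- max(s2w - extra_var, 0.25 * s2w)
  varb <- max(stats::var(as.vector(rbar)) - s2w * mean(1 / n_i), 0.05 * s2w_eta)

  alpha <- matrix(0, pstar, layout$nb)
  alpha[, 1] <- log(varb) + c(0, rep(log(0.25), pstar - 1L))
  tau <- numeric(length(layout$names$tau))
  tau[1] <- log(s2w_eta)
  start <- list(beta = stats::setNames(as.numeric(beta),
                                       sub("^beta\\.", "", layout$names$beta)),
                alpha = alpha, R_upsilon = diag(pstar),
                tau = stats::setNames(tau, sub("^tau\\.", "", layout$names$tau)),
                random_scale = spec$within$random_scale)
  if (latent) start$measurement <- meas

  if (spec$within$random_scale) {
    if (refine) {
      spec0 <- spec
      spec0$within$random_scale <- FALSE
      start0 <- start; start0$random_scale <- FALSE
      fit0 <- fit_melsm(data, spec0, start = start0, n_quad = n_quad,
                        se = FALSE)
      start <- fit0$params
      start$random_scale <- TRUE
    }
    start$phi_a <- 0.5
    start$rho_ua <- numeric(pstar)
  }
  start
}

## one-factor start for the measurement block, rescaled so the anchor item
## has loading 1 and intercept 0
measurement_start <- function(Ymat, ms) {
  M <- ms$n_items
  Yc <- Ymat[stats::complete.cases(Ymat), , drop = FALSE]
  mu <- colMeans(Yc)
  sds <- apply(Yc, 2, stats::sd)
  lam_raw <- rep(NA_real_, M)
  psi <- rep(NA_real_, M)
  fa <- tryCatch(stats::factanal(Yc, factors = 1), error = function(e) NULL)
  if (!is.null(fa)) {
    lam_raw <- as.vector(fa$loadings) * sds
    psi <- fa$uniquenesses * sds^2
  } else {
    S <- stats::cov(Yc)
    lam_raw <- S[, ms$anchor] / sqrt(max(S[ms$anchor, ms$anchor], 1e-8))
    psi <- pmax(diag(S) - lam_raw^2, 0.1 * diag(S))
  }
  lam <- lam_raw / lam_raw[ms$anchor]
  tau_m <- mu - lam * mu[ms$anchor]
  psi <- pmax(psi, 1e-3)
  list(tau = matrix(tau_m, M, ms$n_occasions),
       lambda = matrix(lam, M, ms$n_occasions),
       psi = matrix(psi, M, ms$n_occasions))
}

#' Fit a mixed-effects location scale model by marginal maximum likelihood
#'
#' Maximizes the marginal log-likelihood (see [marginal_loglik()]) over the
#' unconstrained parameterization: variance-model coefficients enter on the
#' log scale, the scale-effect SD as its logarithm and correlations through
#' atanh, so the implied joint random-effects covariance stays positive
#' definite throughout.  Optimization uses a quasi-Newton method
#' (\code{nlminb}) with numerically differentiated gradients; standard
#' errors come from the inverse of the central-difference observed
#' information, mapped to the natural scale by the delta method.
#'
#' @param data a [diary_data] object.
#' @param spec a [melsm_spec].
#' @param start natural-scale parameter list (as from [staged_start()], the
#'   default), or an unconstrained parameter vector of full length.
#' @param n_quad Gauss-Hermite quadrature points (default 10).
#' @param se compute standard errors? (The Hessian costs a few hundred
#'   likelihood evaluations; disable for simulation loops.)
#' @param control list: \code{iter.max}, \code{eval.max}, \code{rel.tol},
#'   \code{grad_tol} (gradient max-norm tolerance, scaled by the
#'   log-likelihood magnitude).
#' @return A \code{melsm_fit} object: natural-scale estimates and standard
#'   errors, log-likelihood, deviance, AIC (\code{deviance + 2k}) and BIC
#'   (\code{deviance + k log N}, N = subjects), convergence metadata, and
#'   the data/spec needed for downstream prediction.
#' @export
fit_melsm <- function(data, spec, start = NULL, n_quad = 10L, se = TRUE,
                      control = list()) {
  engine <- prepare_engine(data, spec)
  layout <- engine$layout
  rule <- gh_rule(n_quad)
  if (is.null(start)) start <- staged_start(data, spec, n_quad = n_quad)
  theta0 <- if (is.numeric(start) && length(start) == layout$n) start
            else pack_params(start, layout)

  negll <- function(th) {
    v <- sum(loglik_engine(th, engine, rule))
    if (!is.finite(v)) return(1e10)
    -v
  }
  ctl <- list(iter.max = control$iter.max %||% 500L,
              eval.max = control$eval.max %||% 4000L,
              rel.tol = control$rel.tol %||% 1e-10)
  opt <- stats::nlminb(theta0, negll, control = ctl)
  theta <- opt$par
  ll <- -negll(theta)
  grad <- num_grad(negll, theta)
  grad_norm <- max(abs(grad))
  grad_tol <- (control$grad_tol %||% 1e-4) * max(1, abs(ll))
  converged <- opt$convergence == 0L && is.finite(ll) && grad_norm < grad_tol

  est <- natural_vector(theta, layout)
  k <- layout$n
  dev <- -2 * ll
  ic <- information_criteria(dev, k, engine$N)

  se_nat <- rep(NA_real_, length(est))
  vcov_nat <- matrix(NA_real_, length(est), length(est))
  vcov_theta <- NULL
  if (se) {
    H <- num_hessian(negll, theta)
    vcov_theta <- tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
    if (!is.null(vcov_theta)) {
      J <- num_jacobian(function(th) natural_vector(th, layout), theta)
      vcov_nat <- J %*% vcov_theta %*% t(J)
      d <- diag(vcov_nat)
      se_nat <- ifelse(d > 0, sqrt(pmax(d, 0)), NA_real_)
    }
  }
  names(se_nat) <- names(est)
  dimnames(vcov_nat) <- list(names(est), names(est))

  out <- structure(list(
    estimates = est, se = se_nat, vcov = vcov_nat,
    params = unpack_params(theta, layout), theta = theta,
    vcov_theta = vcov_theta,
    loglik = ll, deviance = dev, aic = ic$aic, bic = ic$bic,
    n_params = k, N = engine$N, converged = converged,
    grad_norm = grad_norm, n_quad = as.integer(n_quad),
    message = opt$message, spec = spec, layout = layout, data = data),
    class = "melsm_fit")
  stopifnot(isTRUE(all.equal(out$aic, out$deviance + 2 * k)),
            isTRUE(all.equal(out$bic, out$deviance + k * log(engine$N))))
  out
}

#' Likelihood-ratio test between nested fits
#'
#' Chi-square test based on the deviance difference between a reduced and a
#' full model, with the naive chi-square reference distribution (no
#' boundary correction for variance components).
#'
#' @param deviance_reduced,deviance_full deviances of the nested models.
#' @param df difference in free-parameter counts.
#' @return List with \code{statistic}, \code{df}, \code{p}, and a
#'   \code{negative} flag set (with a warning) when the statistic is
#'   negative, which signals non-nesting or non-convergence.
#' @export
lrt <- function(deviance_reduced, deviance_full, df) {
  stat <- deviance_reduced - deviance_full
  negative <- stat < 0
  if (negative)
    warning("negative LRT statistic: models may not be nested or a fit did not converge")
  p <- if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE)
       else as.numeric(stat <= 0)
  list(statistic = stat, df = df, p = p, negative = negative)
}

#' Information criteria from a deviance
#'
#' @param deviance \code{-2 log L}.
#' @param n_params number of free parameters k.
#' @param n_subjects number of independent subjects N.
#' @return List with \code{aic = deviance + 2k} and
#'   \code{bic = deviance + k log(N)}.
#' @export
information_criteria <- function(deviance, n_params, n_subjects = NA) {
  list(aic = deviance + 2 * n_params,
       bic = deviance + n_params * log(n_subjects))
}

#' Wald test of a linear hypothesis
#'
#' Tests \code{c' theta = 0} via the chi-square statistic
#' \code{(c' theta)^2 / (c' V c)} with 1 degree of freedom, e.g. equality
#' of a within- and a between-subject effect with
#' \code{c = (1, -1)} on those two coefficients.
#'
#' @param contrast coefficient vector c.
#' @param estimates estimate vector.
#' @param vcov covariance matrix of the estimates.
#' @return List with \code{statistic}, \code{df = 1}, \code{p}.
#' @export
wald_linear <- function(contrast, estimates, vcov) {
  stopifnot(length(contrast) == length(estimates),
            all(dim(vcov) == length(contrast)))
  denom <- as.numeric(t(contrast) %*% vcov %*% contrast)
  if (denom <= 0) stop("contrast variance is not positive")
  stat <- as.numeric(crossprod(contrast, estimates))^2 / denom
  list(statistic = stat, df = 1L, p = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' Compare a ladder of fitted models
#'
#' Deviance/AIC/BIC table over a sequence of fits, with sequential
#' likelihood-ratio tests of each model against the previous one
#' (degrees of freedom = difference in free-parameter counts).
#'
#' @param ... named \code{melsm_fit} objects, ordered from most restricted
#'   to least.
#' @return A data frame with one row per model.
#' @export
compare_melsm <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !inherits(fits[[1]], "melsm_fit"))
    fits <- fits[[1]]
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "melsm_fit")))
  labs <- names(fits) %||% paste0("M", seq_along(fits))
  out <- data.frame(model = labs,
                    n_params = vapply(fits, `[[`, 0L, "n_params"),
                    deviance = vapply(fits, `[[`, 0, "deviance"),
                    aic = vapply(fits, `[[`, 0, "aic"),
                    bic = vapply(fits, `[[`, 0, "bic"),
                    lrt = NA_real_, df = NA_integer_, p = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (length(fits) > 1L) for (i in 2:length(fits)) {
    df <- out$n_params[i] - out$n_params[i - 1]
    tst <- lrt(out$deviance[i - 1], out$deviance[i], df)
    out$lrt[i] <- tst$statistic; out$df[i] <- df; out$p[i] <- tst$p
  }
  out
}

#' @export
logLik.melsm_fit <- function(object, ...)
  structure(object$loglik, df = object$n_params, nobs = object$N,
            class = "logLik")

#' @export
coef.melsm_fit <- function(object, ...) object$estimates

#' @export
vcov.melsm_fit <- function(object, ...) object$vcov

#' @export
print.melsm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Mixed-effects location scale model (%s mode)\n",
              if (is_latent(x$spec)) "latent" else "manifest"))
  cat(sprintf("  subjects: %d   free parameters: %d   quadrature points: %d\n",
              x$N, x$n_params, x$n_quad))
  cat(sprintf("  logLik %.3f   deviance %.2f   AIC %.2f   BIC %.2f\n",
              x$loglik, x$deviance, x$aic, x$bic))
  if (!x$converged) cat("  WARNING: optimizer did not satisfy convergence criteria\n")
  tab <- data.frame(estimate = round(x$estimates, digits),
                    se = round(x$se, digits))
  print(tab, ...)
  invisible(x)
}

#' @export
summary.melsm_fit <- function(object, ...) object
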