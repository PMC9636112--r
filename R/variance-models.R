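#' Between-subject variance under the log-linear model
#'
#' Evaluates \code{exp(alpha0 + alpha1 w1 + ...)}: the variance of a random
#' location effect as a log-linear function of subject-level covariates.
#' The first element of \code{alpha} is the intercept \code{alpha0};
#' exponentiated, it is the random-effect variance for a subject with
#' covariates at zero.
#'
#' @param alpha coefficient vector (intercept first).
#' @param w subject-level covariate values (length \code{length(alpha)-1}).
#' @return The (strictly positive) variance.
#' @export
between_variance <- function(alpha, w = numeric()) {
  if (length(w) != length(alpha) - 1L)
    stop("length mismatch: alpha has ", length(alpha),
         " coefficients but w has ", length(w), " covariates")
  exp(sum(alpha * c(1, w)))
}

#' Within-subject residual variance under the log-linear model
#'
#' Evaluates \code{exp(tau0 + tau_x' x + tau_w' w + a)}: the occasion-level
#' residual variance given covariates and the subject's random scale effect
#' \code{a}.  At \code{x = w = 0, a = 0} this is \code{exp(tau0)}, the
#' common residual variance.
#'
#' @param tau coefficient vector \code{(tau0, tau_x, tau_w)}.
#' @param x occasion-varying covariate values.
#' @param w subject-level covariate values.
#' @param a random scale effect (default 0).
#' @return The (strictly positive) residual variance.
#' @export
within_variance <- function(tau, x = numeric(), w = numeric(), a = 0) {
  if (length(x) + length(w) != length(tau) - 1L)
    stop("length mismatch: tau has ", length(tau),
         " coefficients but x, w supply ", length(x) + length(w))
  exp(sum(tau * c(1, x, w)) + a)
}

#' Typical-subject within-subject variance
#'
#' The within-subject variance \code{exp(tau0 + a)} is log-normal over
#' subjects when \code{a ~ N(0, phi_a^2)}; its marginal mean is
#' \code{exp(tau0 + phi_a^2 / 2)}, the residual state variance for the
#' typical individual.  By Jensen's inequality this is at least the
#' variance at \code{a = 0}, with equality only when \code{phi_a^2 = 0}.
#'
#' @param tau0 within-variance intercept (log scale).
#' @param phi_a_sq variance of the random scale effect (must be >= 0).
#' @return \code{exp(tau0 + phi_a_sq / 2)}.
#' @export
typical_subject_within_variance <- function(tau0, phi_a_sq) {
  if (phi_a_sq < 0) stop("phi_a_sq must be nonnegative")
  exp(tau0 + phi_a_sq / 2)
}

#' Joint distribution of the stacked random effects
#'
#' Bundles the moments of \code{c_i = (upsilon_i', a_i)'}: the location
#' random effects \code{upsilon_i} with covariance \code{Phi_upsilon}, the
#' scale effect \code{a_i} with variance \code{phi_a_sq}, and their
#' covariances \code{phi_upsilon_a}.
#'
#' @param Phi_upsilon p* x p* covariance matrix of the location effects.
#' @param phi_upsilon_a length-p* covariance vector between the location
#'   effects and the scale effect.
#' @param phi_a_sq variance of the scale effect.
#' @param mu_c optional mean of the stacked effects (default zero).
#' @return A \code{re_joint} object.
#' @export
re_joint <- function(Phi_upsilon, phi_upsilon_a = numeric(nrow(Phi_upsilon)),
                     phi_a_sq = 0, mu_c = NULL) {
  Phi_upsilon <- as.matrix(Phi_upsilon)
  p <- nrow(Phi_upsilon)
  stopifnot(ncol(Phi_upsilon) == p, length(phi_upsilon_a) == p)
  if (phi_a_sq < 0) stop("phi_a_sq must be nonnegative")
  if (is.null(mu_c)) mu_c <- numeric(p + 1L)
  structure(list(Phi_upsilon = Phi_upsilon,
                 phi_upsilon_a = as.numeric(phi_upsilon_a),
                 phi_a_sq = phi_a_sq, mu_c = mu_c),
            class = "re_joint")
}

#' Assemble the joint random-effects covariance matrix
#'
#' Stacks \code{Phi_upsilon}, \code{phi_upsilon_a} and \code{phi_a_sq} into
#' the (p*+1) x (p*+1) covariance of \code{c_i = (upsilon_i', a_i)'} and
#' verifies positive definiteness by Cholesky factorization.
#'
#' @param joint a [re_joint] object.
#' @return The symmetric positive-definite covariance matrix.
#' @export
assemble_phi_c <- function(joint) {
  stopifnot(inherits(joint, "re_joint"))
  Phi <- rbind(cbind(joint$Phi_upsilon, joint$phi_upsilon_a),
               c(joint$phi_upsilon_a, joint$phi_a_sq))
  ev <- eigen(Phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("assembled random-effects covariance is not positive definite (smallest eigenvalue %.3e)",
                 min(ev)))
  Phi
}

#' Conditional distribution of the location effects given the scale effect
#'
#' Because \code{(upsilon_i, a_i)} is jointly normal, \code{upsilon_i}
#' given \code{a_i = a} is normal with mean
#' \code{mu + (phi_upsilon_a / phi_a^2) a} and covariance
#' \code{Phi_upsilon - phi_upsilon_a phi_upsilon_a' / phi_a^2}.  The
#' covariance does not depend on \code{a}; the mean is linear in it.  This
#' is the identity that lets the marginal likelihood collapse to a
#' one-dimensional integral over \code{a}.
#'
#' @param joint a [re_joint] object with \code{phi_a_sq > 0} (or zero with
#'   zero cross-covariances, in which case the marginal law is returned).
#' @param a value of the scale effect.
#' @return A list with \code{mean} (length p*) and \code{cov}
#'   (p* x p*, positive semidefinite; tiny negative eigenvalues are
#'   clipped to zero).
#' @export
conditional_re_given_a <- function(joint, a) {
  stopifnot(inherits(joint, "re_joint"))
  p <- nrow(joint$Phi_upsilon)
  mu_ups <- joint$mu_c[seq_len(p)]
  if (joint$phi_a_sq <= 0) {
    if (any(joint$phi_upsilon_a != 0))
      stop("phi_a_sq = 0 with nonzero phi_upsilon_a: degenerate conditioning")
    return(list(mean = mu_ups, cov = joint$Phi_upsilon))
  }
  slope <- joint$phi_upsilon_a / joint$phi_a_sq
  cv <- joint$Phi_upsilon - tcrossprod(joint$phi_upsilon_a) / joint$phi_a_sq
  cv <- (cv + t(cv)) / 2
  es <- eigen(cv, symmetric = TRUE)
  if (min(es$values) < -1e-10)
    stop("conditional covariance has a negative eigenvalue: invalid joint distribution")
  es$values <- pmax(es$values, 0)
  cv <- es$vectors %*% (es$values * t(es$vectors))
  list(mean = mu_ups + slope * a, cov = (cv + t(cv)) / 2)
}
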