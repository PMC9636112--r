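#' Empirical Bayes estimates of subject location and scale effects
#'
#' Posterior summaries of each subject's location random effects
#' \code{upsilon_i} and scale effect \code{a_i} given the data and the ML
#' estimates, computed on the same Gauss-Hermite grid as estimation.  The
#' posterior over \code{a_i} is the prior quadrature weight times the
#' subject's conditional density, renormalized; given \code{a},
#' \code{upsilon_i} has a conditional-normal posterior, and the reported
#' values are posterior means mixed over the grid (means, not modes).
#' Conditional residuals are the observed responses minus the fitted means
#' at the posterior means of both effects.  Subjects with no observed
#' responses receive their prior means (zero) and prior SDs.
#'
#' @param fit a converged [fit_melsm()] result.
#' @param data dataset to predict for (defaults to the fitted data; every
#'   requested subject must be present).
#' @param rule quadrature rule (defaults to the rule size used in fitting).
#' @return An \code{eb_estimates} object: \code{$subjects}, a data frame of
#'   per-subject posterior means and SDs (\code{upsilon_hat.*},
#'   \code{a_hat}, \code{..._sd}); and \code{$residuals}, a long data frame
#'   of conditional residuals per observed cell.
#' @export
eb_estimates <- function(fit, data = fit$data, rule = gh_rule(fit$n_quad)) {
  stopifnot(inherits(fit, "melsm_fit"))
  if (!fit$converged)
    warning("fit did not converge; empirical Bayes estimates may be unreliable")
  spec <- fit$spec
  engine <- prepare_engine(data, spec)
  p <- unpack_params(pack_params(fit$params, engine$layout), engine$layout)
  rs <- spec$within$random_scale
  pstar <- engine$layout$pstar
  latent <- engine$latent

  if (rs) {
    nodes <- sqrt(2) * p$phi_a * rule$nodes
    logw <- log(rule$weights) - 0.5 * log(pi)
  } else { nodes <- 0; logw <- 0 }
  nq <- length(nodes)

  ups_hat <- matrix(0, engine$N, pstar)
  ups_sd <- matrix(0, engine$N, pstar)
  a_hat <- numeric(engine$N)
  a_sd <- numeric(engine$N)
  res_list <- list()

  for (g in engine$groups) {
    ns <- ncol(g$Y)
    rem <- re_moments(p, g$B)
    Phi_cond <- if (rs) rem$Phi - tcrossprod(rem$phi_ua) / p$phi_a^2 else rem$Phi
    slope <- if (rs) rem$phi_ua / p$phi_a^2 else numeric(pstar)
    eta_mean <- as.vector(g$Gamma %*% p$beta)
    logs2 <- as.vector(g$V %*% p$tau)
    if (latent) {
      mt <- p$measurement
      lam_cell <- mt$lambda[cbind(g$item_idx, g$occ_idx)]
      lam_cell[g$item_idx == spec$measurement$anchor] <- 1
      Lam <- matrix(0, g$nobs, g$n)
      Lam[cbind(seq_len(g$nobs), match(g$occ_idx, g$occasions))] <- lam_cell
      tau_y <- mt$tau[cbind(g$item_idx, g$occ_idx)]
      psi_y <- mt$psi[cbind(g$item_idx, g$occ_idx)]
      Ueff <- Lam %*% g$Z
    } else {
      Ueff <- g$Z
    }

    ld <- matrix(0, nq, ns)
    Ek <- array(0, c(nq, pstar, ns))
    Vk <- array(0, c(nq, pstar, pstar))
    for (k in seq_len(nq)) {
      a <- nodes[k]; m_a <- slope * a
      sig2 <- exp(logs2 + a)
      if (latent) {
        S_eta <- g$Z %*% Phi_cond %*% t(g$Z) + diag(sig2, g$n)
        mu <- tau_y + as.vector(Lam %*% (eta_mean + g$Z %*% m_a))
        Sig <- Lam %*% S_eta %*% t(Lam) + diag(psi_y, g$nobs)
      } else {
        mu <- eta_mean + as.vector(g$Z %*% m_a)
        Sig <- g$Z %*% Phi_cond %*% t(g$Z) + diag(sig2, g$n)
      }
      Resid <- g$Y - mu
      if (g$nobs) {
        cS <- chol(Sig)
        u <- backsolve(cS, Resid, transpose = TRUE)
        ld[k, ] <- -0.5 * (g$nobs * log2pi + 2 * sum(log(diag(cS))) +
                             colSums(u * u)) + logw[k]
        Cy <- Phi_cond %*% t(Ueff)                     # cov(upsilon, y | a)
        K <- t(backsolve(cS, backsolve(cS, t(Cy), transpose = TRUE)))
        Ek[k, , ] <- as.vector(m_a) + K %*% Resid
        Vk[k, , ] <- Phi_cond - K %*% t(Cy)
      } else {
        ld[k, ] <- logw[k]
        Ek[k, , ] <- m_a
        Vk[k, , ] <- Phi_cond
      }
    }
    wt <- exp(sweep(ld, 2L, logsumexp(ld)))            # nq x ns posterior wts
    a_hat[g$idx] <- as.vector(crossprod(wt, nodes))
    a_sd[g$idx] <- sqrt(pmax(as.vector(crossprod(wt, nodes^2)) -
                               a_hat[g$idx]^2, 0))
    for (s in seq_len(ns)) {
      i <- g$idx[s]
      Es <- matrix(Ek[, , s], nq, pstar)
      ups_hat[i, ] <- colSums(wt[, s] * Es)
      Evv <- matrix(0, pstar, pstar)
      for (k in seq_len(nq))
        Evv <- Evv + wt[k, s] * (matrix(Vk[k, , ], pstar, pstar) +
                                   tcrossprod(Es[k, ]))
      ups_sd[i, ] <- sqrt(pmax(diag(Evv) - ups_hat[i, ]^2, 0))
      ## conditional residuals at the posterior means
      if (!g$nobs) next
      fitted_eta <- eta_mean + as.vector(g$Z %*% ups_hat[i, ])
      if (latent) {
        resid <- g$Y[, s] - (tau_y + as.vector(Lam %*% fitted_eta))
        res_list[[length(res_list) + 1L]] <- data.frame(
          subject = g$subjects[s],
          occasion = g$occ_idx, item = g$item_idx, residual = resid)
      } else {
        res_list[[length(res_list) + 1L]] <- data.frame(
          subject = g$subjects[s],
          occasion = g$occasions, item = NA_integer_,
          residual = g$Y[, s] - fitted_eta)
      }
    }
  }

  nm <- sub("^beta\\.", "", engine$layout$names$beta)[
    match(spec$location$random, spec$location$x_terms)]
  subj_df <- data.frame(subject = engine$subjects, stringsAsFactors = FALSE)
  for (j in seq_len(pstar)) {
    subj_df[[paste0("upsilon_hat.", nm[j])]] <- ups_hat[, j]
    subj_df[[paste0("upsilon_sd.", nm[j])]] <- ups_sd[, j]
  }
  subj_df$a_hat <- a_hat
  subj_df$a_sd <- a_sd
  structure(list(subjects = subj_df,
                 residuals = do.call(rbind, res_list)),
            class = "eb_estimates")
}

#' @export
print.eb_estimates <- function(x, ...) {
  cat(sprintf("<eb_estimates> %d subjects, %d residual cells\n",
              nrow(x$subjects), nrow(x$residuals)))
  print(utils::head(x$subjects), ...)
  invisible(x)
}

#' Write empirical Bayes output to CSV
#'
#' Writes the per-subject posterior summaries and the long-format
#' conditional residuals as two CSV files.
#'
#' @param eb an [eb_estimates()] object.
#' @param subjects_path,residuals_path output paths.
#' @return The two paths, invisibly.
#' @export
write_eb_csv <- function(eb, subjects_path, residuals_path) {
  utils::write.csv(eb$subjects, subjects_path, row.names = FALSE)
  utils::write.csv(eb$residuals, residuals_path, row.names = FALSE)
  invisible(c(subjects_path, residuals_path))
}
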