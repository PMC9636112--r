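# shared toy fixtures; moderate scale-effect SDs keep the quadrature
# cross-checks sharply convergent at modest node counts

toy_manifest <- function() {
  list(spec = melsm_spec(),
       truth = list(beta = c("(Intercept)" = 2.5),
                    alpha = matrix(-1.0, 1, 1),
                    tau = c("(Intercept)" = -1.5),
                    phi_a = 0.6, rho_ua = -0.4, random_scale = TRUE))
}

toy_latent <- function(M = 2L, Tn = 2L) {
  ms <- measurement_spec(M, Tn)
  list(spec = melsm_spec(measurement = ms),
       truth = list(beta = c("(Intercept)" = 1.0),
                    alpha = matrix(-0.8, 1, 1),
                    tau = c("(Intercept)" = -1.0),
                    phi_a = 0.5, rho_ua = 0.3, random_scale = TRUE,
                    measurement = list(tau = c(0, seq_len(M - 1) / 10),
                                       lambda = c(1, 1 + seq_len(M - 1) / 5),
                                       psi = rep(0.3, M))))
}

## spec with the stressor covariates in all three submodels
stressor_spec <- function(random_scale = TRUE)
  melsm_spec(location = location_spec(x_terms = "stressors_pmc",
                                      w_terms = "stressors_pm"),
             between = between_spec(terms = "stressors_pm"),
             within = within_spec(x_terms = "stressors_pmc",
                                  w_terms = "stressors_pm",
                                  random_scale = random_scale))
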