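#' Simulate daily stressor counts
#'
#' Generates integer daily stressor counts on the 0-7 range from a
#' subject-level gamma-frailty Poisson: each subject draws a daily rate
#' from a gamma distribution calibrated so that the person means (across
#' occasions) have the target mean and SD, then daily counts are Poisson
#' draws truncated at the maximum.  Person-mean and person-mean-centered
#' columns are derived from the generated counts, so the centered column
#' sums to zero within every subject.
#'
#' @param n_subjects,n_occasions design size.
#' @param mean_pm target mean of the person means (default 0.53).
#' @param sd_pm target SD of the person means (default 0.42).
#' @param max_count upper truncation of a daily count (default 7).
#' @param seed optional RNG seed for reproducibility.
#' @return Data frame with columns \code{subject}, \code{occasion},
#'   \code{stressors}, \code{stressors_pm}, \code{stressors_pmc}.
#' @export
simulate_stressors <- function(n_subjects, n_occasions, mean_pm = 0.53,
                               sd_pm = 0.42, max_count = 7L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ## person-mean variance = var(rate) + E(rate)/T  =>  calibrate var(rate)
  v_rate <- max(sd_pm^2 - mean_pm / n_occasions, 1e-4)
  shape <- mean_pm^2 / v_rate
  rate_i <- stats::rgamma(n_subjects, shape = shape, rate = shape / mean_pm)
  counts <- pmin(stats::rpois(n_subjects * n_occasions,
                              rep(rate_i, each = n_occasions)), max_count)
  df <- data.frame(subject = rep(seq_len(n_subjects), each = n_occasions),
                   occasion = rep(seq_len(n_occasions), n_subjects),
                   stressors = counts)
  pm <- stats::ave(df$stressors, df$subject)
  df$stressors_pm <- pm
  df$stressors_pmc <- df$stressors - pm
  df
}

#' Default diary-study parameterizations
#'
#' Natural-scale truth values emulating an 8-day, 5-item daily positive
#' affect diary with 435 subjects: an intercept-only location model with a
#' random intercept, a log-linear between-subject variance, and a within-
#' subject variance with a random scale effect correlated with the
#' intercept.  The latent mode adds an invariant 5-item measurement model
#' (anchor item loading 1, intercept 0).  Magnitudes mirror a published
#' analysis of such data: trait variance exp(-1.21), occasion-level
#' variance exp(-2.66), scale-effect SD 1.37 and intercept-scale
#' correlation -0.43 in latent mode; exp(-0.65), exp(-1.84), 1.16 and
#' -0.36 in manifest mode.
#'
#' @param mode \code{"latent"} or \code{"manifest"}.
#' @return List with elements \code{spec} (a [melsm_spec]) and
#'   \code{truth} (parameter list for [simulate_melsm()] /
#'   [marginal_loglik()]).
#' @export
study_truth <- function(mode = c("latent", "manifest")) {
  mode <- match.arg(mode)
  if (mode == "latent") {
    ms <- measurement_spec(5L, 8L)
    spec <- melsm_spec(measurement = ms)
    truth <- list(
      beta = c("(Intercept)" = 2.99),
      alpha = matrix(-1.21, 1, 1), R_upsilon = diag(1),
      tau = c("(Intercept)" = -2.66),
      phi_a = 1.37, rho_ua = -0.43, random_scale = TRUE,
      measurement = list(tau = c(0, -0.58, -0.63, -0.56, -1.4),
                         lambda = c(1, 1.15, 1.13, 1.15, 1.32),
                         psi = c(0.20, 0.22, 0.35, 0.21, 0.52)))
  } else {
    spec <- melsm_spec()
    truth <- list(
      beta = c("(Intercept)" = 3.00),
      alpha = matrix(-0.65, 1, 1), R_upsilon = diag(1),
      tau = c("(Intercept)" = -1.84),
      phi_a = 1.16, rho_ua = -0.36, random_scale = TRUE)
  }
  list(spec = spec, truth = truth)
}

#' Simulate a diary dataset from a location scale model
#'
#' Generates manifest or item-level repeated-measures data from a
#' specified parameterization: per subject, the stacked random effects
#' \code{(upsilon_i, a_i)} are drawn from their joint normal distribution;
#' per occasion, the latent (or manifest) response is the location model
#' plus a residual with variance \code{exp(tau' v + a_i)}; in latent mode
#' the item responses add measurement intercepts, loadings and normal
#' unique factors.  Output is deterministic under a fixed seed.
#'
#' @param spec a [melsm_spec] defining the model structure (covariate term
#'   names must exist among the generated covariate columns).
#' @param truth natural-scale parameter list: \code{beta}, \code{alpha},
#'   \code{tau}, \code{phi_a}, \code{rho_ua}, optionally \code{R_upsilon}
#'   and a \code{measurement} list with per-item \code{tau},
#'   \code{lambda}, \code{psi} vectors (or full M x T tables).
#' @param n_subjects,n_occasions design size (defaults 435 x 8,
#'   emulating an 8-day diary study).
#' @param stressors generate daily stressor counts (and their person-mean
#'   and centered columns) as covariates?
#' @param missing_rate fraction of outcome/item cells set missing
#'   completely at random.
#' @param clip_range optional length-2 numeric: clamp responses to a
#'   bounded reporting scale (e.g. \code{c(0, 4)}) to emulate floor and
#'   ceiling effects.  Off by default: the fitted model is normal-theory.
#' @param seed optional RNG seed.
#' @return List with \code{data} (a [diary_data]), \code{truth} (echoed),
#'   and \code{effects}, a data frame of the drawn subject effects.
#' @export
simulate_melsm <- function(spec, truth, n_subjects = 435L, n_occasions = 8L,
                           stressors = FALSE, missing_rate = 0,
                           clip_range = NULL, seed = NULL) {
  stopifnot(inherits(spec, "melsm_spec"),
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  layout <- param_layout(spec)
  pstar <- layout$pstar
  latent <- is_latent(spec)

  df <- if (stressors) simulate_stressors(n_subjects, n_occasions)
        else data.frame(subject = rep(seq_len(n_subjects), each = n_occasions),
                        occasion = rep(seq_len(n_occasions), n_subjects))

  ## normalize truth into the internal natural-parameter shape
  tn <- truth
  tn$alpha <- if (is.matrix(truth$alpha)) truth$alpha
              else matrix(truth$alpha, nrow = pstar, byrow = TRUE)
  tn$R_upsilon <- truth$R_upsilon %||% diag(pstar)
  tn$phi_a <- truth$phi_a %||% 0
  tn$rho_ua <- rep(truth$rho_ua %||% 0, length.out = pstar)
  tn$random_scale <- spec$within$random_scale
  if (!tn$random_scale) { tn$phi_a <- 0; tn$rho_ua <- numeric(pstar) }
  ms <- spec$measurement
  if (latent) {
    m <- truth$measurement
    expand <- function(v) if (is.matrix(v)) v else matrix(v, ms$n_items, ms$n_occasions)
    tn$measurement <- list(tau = expand(m$tau), lambda = expand(m$lambda),
                           psi = expand(m$psi))
  }

  ## temporary dataset carrying the covariates so designs can be assembled
  shell <- df
  if (latent) {
    inames <- paste0("item", seq_len(ms$n_items))
    for (v in inames) shell[[v]] <- 0
  } else shell$y <- 0
  dat0 <- diary_data(shell, outcome = if (!latent) "y",
                     items = if (latent) paste0("item", seq_len(ms$n_items)),
                     x = setdiff(union(spec$location$x_terms,
                                       spec$within$x_terms), "1"),
                     w = setdiff(unique(c(spec$location$w_terms,
                                          spec$within$w_terms,
                                          spec$between$terms)), "1"))
  designs <- build_designs(dat0, spec)

  rows <- vector("list", n_subjects)
  effects <- matrix(0, n_subjects, pstar + 1L)
  for (i in seq_len(n_subjects)) {
    d <- designs[[i]]
    rem <- re_moments(tn, d$B)
    Phi_c <- rbind(cbind(rem$Phi, rem$phi_ua),
                   c(rem$phi_ua, tn$phi_a^2))
    r <- pstar + 1L
    ev <- eigen((Phi_c + t(Phi_c)) / 2, symmetric = TRUE)
    if (min(ev$values) < -1e-10) stop("truth implies an invalid random-effects covariance")
    Lc <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), r)
    ci <- as.vector(Lc %*% stats::rnorm(r))
    ups <- ci[seq_len(pstar)]; a <- ci[r]
    effects[i, ] <- ci
    sig2 <- exp(as.vector(d$V %*% tn$tau) + a)
    eta <- as.vector(d$Gamma %*% tn$beta + d$Z %*% ups) +
      stats::rnorm(d$n, sd = sqrt(sig2))
    if (latent) {
      Yi <- matrix(NA_real_, d$n, ms$n_items)
      for (t in seq_len(d$n)) {
        occ <- d$occasions[t]
        lam <- tn$measurement$lambda[, occ]; lam[ms$anchor] <- 1
        tau_m <- tn$measurement$tau[, occ]; tau_m[ms$anchor] <- 0
        Yi[t, ] <- tau_m + lam * eta[t] +
          stats::rnorm(ms$n_items, sd = sqrt(tn$measurement$psi[, occ]))
      }
      rows[[i]] <- Yi
    } else rows[[i]] <- eta
  }

  if (latent) {
    Y <- do.call(rbind, rows)
    if (missing_rate > 0)
      Y[stats::runif(length(Y)) < missing_rate] <- NA
    if (!is.null(clip_range))
      Y <- pmin(pmax(Y, clip_range[1]), clip_range[2])
    for (j in seq_len(ms$n_items)) shell[[paste0("item", j)]] <- Y[, j]
  } else {
    y <- unlist(rows)
    if (missing_rate > 0) y[stats::runif(length(y)) < missing_rate] <- NA
    if (!is.null(clip_range)) y <- pmin(pmax(y, clip_range[1]), clip_range[2])
    shell$y <- y
  }

  data <- diary_data(shell, outcome = if (!latent) "y",
                     items = if (latent) paste0("item", seq_len(ms$n_items)),
                     x = dd_attr(dat0, "x"), w = dd_attr(dat0, "w"))
  eff <- data.frame(subject = seq_len(n_subjects))
  for (j in seq_len(pstar)) eff[[paste0("upsilon.", j)]] <- effects[, j]
  eff$a <- effects[, pstar + 1L]
  list(data = data, truth = tn, effects = eff)
}
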