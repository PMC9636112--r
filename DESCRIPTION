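Package: lvmelsm
Title: Mixed-Effects Location Scale Models for Manifest and Latent Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maximum-likelihood estimation of mixed-effects location scale
    models (MELSM) for intensive longitudinal data such as daily diaries,
    including a second-order latent-variable extension in which a
    longitudinal confirmatory factor model links item responses to an
    occasion-specific latent variable that itself follows a MELSM.  The
    between-subject variance and the within-subject residual variance are
    modelled log-linearly in covariates, with a normally distributed random
    scale effect in the within-subject variance model.  The marginal
    likelihood is reduced analytically to a one-dimensional integral over
    the random scale effect and evaluated by Gauss-Hermite quadrature.
    Includes staged starting values, likelihood-ratio and Wald tests,
    measurement-invariance testing across occasions, empirical Bayes
    prediction of subject-level location and scale effects, and a
    synthetic daily-diary data simulator.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
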