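# lvmelsm

Mixed-effects location scale models (MELSM) for intensive longitudinal
data — daily diaries, ecological momentary assessment, any design with
many occasions nested in subjects — including a second-order
latent-variable extension for item-level responses.

## The problem and the model

Standard mixed models describe how people differ in their *average*
response; in many diary studies the scientifically interesting quantity
is how people differ in their *variability* from day to day.  The MELSM
models both.  For response $y_{ti}$ of subject $i$ on occasion $t$:

$$y_{ti} = \mathbf{x}_{ti}'(\boldsymbol\beta_x + \boldsymbol\upsilon_i)
  + \mathbf{w}_i'\boldsymbol\beta_w + \varepsilon_{ti},
  \qquad \varepsilon_{ti} \sim N(0, \sigma^2_{ti}),$$

with two log-linear variance submodels: the random-effect (trait)
variance $\exp\{\alpha_0 + \boldsymbol\alpha'\mathbf{w}_i\}$ and the
occasion-level (state) residual variance
$\sigma^2_{ti} = \exp\{\tau_0 + \boldsymbol\tau_x'\mathbf{x}_{ti} +
\boldsymbol\tau_w'\mathbf{w}_i + a_i\}$, where $a_i \sim N(0,\phi_a^2)$
is a **random scale effect** that lets day-to-day variability itself
differ between people and correlate (via $\rho_{\upsilon a}$) with the
person's level.

When responses are multi-item scales, averaging items mixes measurement
error into the state variance.  The latent (second-order) version puts a
longitudinal confirmatory factor model between the items and an
occasion-specific latent variable $\eta_{ti}$ — anchor item fixed at
loading 1 / intercept 0 each occasion — and applies the MELSM to
$\eta_{ti}$, so trait variance, state variance and item uniquenesses are
cleanly partitioned.

Estimation is marginal maximum likelihood: conditional on $a_i$ the
model is linear in $\boldsymbol\upsilon_i$, so the location effects are
integrated out analytically and only a one-dimensional integral over
$a_i$ remains, evaluated by Gauss–Hermite quadrature (10 points by
default).  See the methods vignette
(`vignettes/lvmelsm-methods.Rmd`) for the full account.

## Worked example

Simulate an 8-day, 5-item diary for 435 subjects at realistic magnitudes
and fit the latent intercept-only MELSM:

```r
library(lvmelsm)
base <- study_truth("latent")          # spec + generating parameters
sim  <- simulate_melsm(base$spec, base$truth,
                       n_subjects = 435, n_occasions = 8, seed = 2024)
fit  <- fit_melsm(sim$data, base$spec)
fit
#> Mixed-effects location scale model (latent mode)
#>   subjects: 435   free parameters: 18   quadrature points: 10
#>   logLik -16583.530   deviance 33167.06   AIC 33203.06   BIC 33276.42
#>                    estimate     se
#> beta.(Intercept)     2.9995 0.0262
#> alpha.(Intercept)   -1.3588 0.0792
#> tau.(Intercept)     -2.7718 0.1030
#> phi_a                1.5601 0.0940
#> rho_ua.(Intercept)  -0.3719 0.0574
#> ...
```

Reading the output: the average latent affect level is
`beta.(Intercept)` = 3.00; the trait variance is
`exp(-1.36)` = 0.26 (subjects differ moderately in their average
level); the state variance for a subject with $a_i = 0$ is
`exp(-2.77)` = 0.06, but the scale-effect SD `phi_a` = 1.56 says
day-to-day variability differs strongly across people, and
`rho_ua` = −0.37 says people with higher average levels tend to be
*more stable*.  The typical-subject state variance is the log-normal
mean:

```r
typical_subject_within_variance(fit$estimates[["tau.(Intercept)"]],
                                fit$estimates[["phi_a"]]^2)
#> 0.211
```

Per-subject empirical Bayes predictions of level and volatility:

```r
eb <- eb_estimates(fit)
head(eb$subjects[c("subject", "upsilon_hat.(Intercept)", "a_hat")], 3)
#>   subject upsilon_hat.(Intercept)      a_hat
#> 1       1              -0.4904164  0.8432244
#> 2       2               0.4109269 -1.1682357
#> 3       3              -0.7146771  2.3518477
```

Other entry points: `person_center()` splits an occasion-varying
covariate (e.g. daily stressor counts) into between- and within-person
parts for use in all three submodels; `invariance_sequence()` runs the
configural → equal-loadings → equal-intercepts → equal-uniquenesses
measurement ladder with LRT bookkeeping; `compare_melsm()`, `lrt()`,
`wald_linear()` cover model comparison; `run_config()` (and the thin
`inst/cli/lvmelsm.R` wrapper) drives simulate/fit/compare/eb/invariance
workflows from a YAML config.

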