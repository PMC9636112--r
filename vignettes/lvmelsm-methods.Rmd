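---
title: "Location scale models for diary data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Location scale models for diary data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvmelsm)
```

## The model

Daily-diary and other intensive longitudinal designs produce repeated
measures in which both the person-level mean and the day-to-day
variability around that mean are of scientific interest.  The
mixed-effects location scale model (MELSM) handles both at once.  For a
response $y_{ti}$ on occasion $t$ for subject $i$,

$$ y_{ti} = \mathbf{x}_{ti}'(\boldsymbol\beta_x + \boldsymbol\upsilon_i)
   + \mathbf{w}_i'\boldsymbol\beta_w + \varepsilon_{ti}, $$

with random location effects $\boldsymbol\upsilon_i$ on a subset of the
occasion-varying terms.  Two log-linear variance submodels complete the
specification:

* **between-subject**: the variance of a random location effect is
  $\exp\{\alpha_0 + \boldsymbol\alpha'\mathbf{w}_i\}$, so subject-level
  covariates can widen or narrow the spread of the person-specific
  intercepts (and slopes);
* **within-subject**: the occasion-level residual variance is
  $\sigma^2_{ti} = \exp\{\tau_0 + \boldsymbol\tau_x'\mathbf{x}_{ti} +
  \boldsymbol\tau_w'\mathbf{w}_i + a_i\}$, where $a_i \sim N(0,
  \phi_a^2)$ is a *random scale effect*: a subject-specific shift of the
  log residual variance.  $a_i$ may correlate with
  $\boldsymbol\upsilon_i$ (covariance $\boldsymbol\phi_{\upsilon a}$,
  reported as the correlation $\rho_{\upsilon a}$), capturing, e.g., the
  tendency of people with high average affect to also be more stable
  from day to day.

Because the within-subject variance is log-normal over subjects, the
residual variance for the *typical* subject is $\exp\{\tau_0 +
\phi_a^2/2\}$, not $\exp\{\tau_0\}$; `typical_subject_within_variance()`
computes this marginal mean.

### The latent (second-order) extension

Manifest scores that carry measurement error inflate the apparent
within-subject variation.  The latent extension inserts a longitudinal
confirmatory factor model between $M$ item responses and an
occasion-specific latent variable $\eta_{ti}$:

$$ \mathbf{y}_{i} = \boldsymbol\tau_i + \boldsymbol\Lambda_i(\boldsymbol\lambda)\,
   \boldsymbol\eta_i + \boldsymbol\delta_i, \qquad
   \boldsymbol\delta_i \sim N(\mathbf{0}, \boldsymbol\Psi_i), $$

with $\eta_{ti}$ itself following the MELSM above.  Identification fixes
an anchor item's intercept to 0 and loading to 1 at every occasion, so
the latent variable carries the anchor's scale over time; item sets may
differ across occasions as long as each occasion retains the anchor.
Under this model the trait variance (random-intercept variance), the
state residual variance, and the item uniquenesses are separated, each
free of measurement error.

## Marginal likelihood and its one-dimensional reduction

Conditional on the full random-effect vector the response is normal, but
the scale effect enters the covariance through $\exp\{a_i\}$, so the
marginal likelihood has no closed form.  The key computational fact is
that, *conditional on $a_i$*, the model is linear in
$\boldsymbol\upsilon_i$, and the conditional law of
$\boldsymbol\upsilon_i$ given $a_i$ is normal with mean
$\boldsymbol\beta + (\boldsymbol\phi_{\upsilon a}/\phi_a^2) a_i$ and
covariance $\boldsymbol\Phi_\upsilon - \boldsymbol\phi_{\upsilon a}
\boldsymbol\phi_{\upsilon a}'/\phi_a^2$ (independent of $a_i$).  The
location effects can therefore be integrated out analytically, leaving a
one-dimensional integral over $a_i$ per subject:

$$ \log L = \sum_i \log \int h(\mathbf{y}_i \mid a)\,
   \phi(a; 0, \phi_a^2)\, da . $$

`marginal_loglik()` evaluates this with nonadaptive Gauss–Hermite
quadrature after the substitution $a = \sqrt{2}\,\phi_a t$, which makes
the rule parameter-independent.  The default is 10 points (a config
knob); the test suite verifies that the value is stable between 10 and
30 points on fixed data, and that the reduced integral agrees with a
brute-force tensor quadrature over the full random-effect vector to
$10^{-8}$ on small instances — the module's central correctness
property.  When there is no random scale effect the integral collapses
to a single exact evaluation (the ordinary linear-mixed-model
likelihood, which the tests check against an independent `lme4` fit).

Numerical choices worth knowing:

* node densities are combined in log space (log-sum-exp), so the
  log-likelihood underflows only if a density is truly zero;
* each conditional covariance is *diagonal plus low rank*
  ($\boldsymbol\Psi_i + \boldsymbol\Lambda_i \boldsymbol\Sigma_\eta
  \boldsymbol\Lambda_i'$ in latent mode, $\boldsymbol\Theta_a +
  \mathbf{Z}_i \boldsymbol\Phi_{\upsilon.a} \mathbf{Z}_i'$ in manifest
  mode) and is evaluated in Woodbury form — log-determinants come from a
  small Cholesky factor, no dense covariance is inverted;
* subjects with identical designs and missingness patterns are grouped
  so the factorization is done once per group per node, which makes
  balanced designs (e.g. 435 subjects × 8 days × 5 items) fast;
* missing cells are handled by row deletion before moments are formed
  (missing at random);
* the conditional covariance of the location effects is accepted as
  positive semidefinite down to eigenvalues of $-10^{-10}$, which are
  clipped to zero.

## Estimation

`fit_melsm()` optimizes the unconstrained parameterization —
variance-model coefficients are already log-scale, the scale SD enters
as $\log \phi_a$, correlations as $\mathrm{atanh}\,\rho$, uniquenesses
as $\log \psi$ — with a quasi-Newton optimizer (`nlminb`) and
finite-difference gradients.  This keeps the implied joint
random-effects covariance positive definite at every iterate without
constrained optimization.

Starting values are staged the way these models are fit in practice
(`staged_start()`): a closed-form fixed-effects stage (least squares for
the location coefficients; a within/between moment decomposition of the
residuals for $\tau_0$ and $\alpha_0$), an optional ML refinement of the
model *without* the random scale effect, then $\phi_a$ freed at a small
positive value (0.5) with $\rho_{\upsilon a}$ at 0.  Covariate effects
in both variance models start at 0.  In latent mode the measurement
block starts at a one-factor analysis solution rescaled to the anchor
item.

Convergence requires the optimizer's own relative-tolerance criterion
(default $10^{-10}$) plus a gradient max-norm check.  Because the
gradient is computed by central differences on a log-likelihood of
magnitude $O(10^4)$, an absolute tolerance of $10^{-4}$ is below
finite-difference noise at realistic sample sizes; the check is
therefore scaled by $\max(1, |\log L|)$.  Standard errors come from the
inverse of the central-difference observed information at the optimum,
mapped to the natural scale (SDs, correlations, variances) by the delta
method; non-invertible information yields `NA` standard errors rather
than a silent failure, and iteration-cap exits are flagged
non-converged.

Model comparison uses the deviance ($-2\log L$): `lrt()` for nested
models (the naive $\chi^2$ reference is used for variance components —
e.g. 2 df for adding $\phi_a^2$ and $\phi_{\upsilon a}$ — without
boundary corrections, which is the convention this workflow follows),
`information_criteria()` for AIC ($\mathrm{dev} + 2k$) and BIC
($\mathrm{dev} + k\log N$, $N$ = subjects), and `wald_linear()` for
single-df linear hypotheses such as equality of the within- and
between-person effects of a covariate.

## Measurement invariance

A latent variable is only interpretable over time if the instrument
behaves consistently across occasions.  `invariance_sequence()` fits the
standard ladder — configural, equal loadings, equal intercepts, equal
loadings + intercepts, and additionally equal uniquenesses — and
reports LRTs whose degrees of freedom are differences in free-parameter
counts derived from the constraint maps (for a 5-item, 8-day design: 28,
28, 56, and 35; freeing individual cells, e.g. one item's intercept on
one day, adjusts the counts accordingly).  Equality constraints are
expressed as item × occasion label grids (`constraint_map()`,
`free_cells()`), so partial invariance is configured, not hard-coded.
During these fits the structural model for the latent scores is an
intercept-only model without the random scale effect: the invariance
decision should rest on the measurement block, and this choice keeps the
ladder cheap and well-identified.  It is a configurable default, not a
constraint of the engine.

## Empirical Bayes prediction

`eb_estimates()` summarizes each subject's posterior over
$(\boldsymbol\upsilon_i, a_i)$ at the ML estimates.  The posterior over
$a_i$ is discrete on the estimation quadrature grid (prior weight times
conditional density, renormalized); given $a$, the posterior of
$\boldsymbol\upsilon_i$ is conditional-normal, and reported values are
posterior *means* mixed over the grid — means rather than modes, because
they reuse the likelihood engine exactly and are well-defined under
asymmetric posteriors.  Posterior SDs exhibit the usual shrinkage
(always below the prior SDs once a subject contributes data);
conditional residuals are observed responses minus fitted means at the
posterior means of both effects.  Subjects with no observed responses
fall back to prior means and SDs.

## The simulator

`simulate_melsm()` generates manifest or item-level diary data from any
parameterization of the model, and `study_truth()` supplies the default
conditions the package is calibrated around: 435 subjects × 8 days × 5
items on a 0–4 response scale treated as continuous, intercept-only
location model, trait variance $\exp(-1.21)$, occasion-level variance
$\exp(-2.66)$, scale-effect SD 1.37, intercept–scale correlation
$-0.43$, invariant loadings $(1, 1.15, 1.13, 1.15, 1.32)$, intercepts
$(0, -0.58, -0.63, -0.56, -1.4)$ and uniquenesses $(0.20, 0.22, 0.35,
0.21, 0.52)$; the manifest variant uses $\exp(-0.65)$, $\exp(-1.84)$,
SD 1.16 and $-0.36$.  These magnitudes mirror published analyses of
daily positive affect, so simulation studies run at realistic
signal-to-noise ratios.

Daily stressor counts are generated by a subject-level gamma-frailty
Poisson truncated to 0–7, calibrated so the person means have mean 0.53
and SD 0.42 — the reported distributional targets for such covariates;
only those two moments are targeted because that is all the design
states, and the gamma-Poisson is the standard overdispersed count
mechanism.  Derived person-mean and person-mean-centered columns are
computed from the generated counts (from observed occasions only), so
the centered column sums to zero within subject by construction.

What the simulator does *not* emulate: ordinal item scales (responses
are continuous normal; an optional `clip_range` crudely mimics floor and
ceiling effects but the default leaves responses unclipped, matching the
normal-theory model being fit), systematic time trends, serially
correlated residuals, and informative missingness (`missing_rate` is
completely at random).  Passing tests on simulated data therefore
certify the estimation machinery under the model's own assumptions; they
do not certify robustness to ordinal measurement or to
missing-not-at-random mechanisms in real diaries.

## Problem sizes used by the test suite

The heavy checks are sized to run comfortably on one CPU: the
brute-force likelihood cross-checks use 3–5 subjects with 2–3 occasions
and 80-point rules; the `lme4` limiting-case comparison uses 300
subjects × 6 days; the parameter-recovery study runs 24 replicates of
the full latent design (400 subjects × 8 days × 5 items), enough for
Monte-Carlo standard errors near 0.01–0.03 on every parameter while
keeping the whole suite around ten minutes.  These sizes are the
package's own verification choices and are not tuning knobs of the
methods.

## Known limitations

* Quadrature is nonadaptive; with very large $\phi_a$ or very long
  series the integrand narrows relative to the prior and more nodes are
  needed (the node count is exposed everywhere).
* Covariate-dependent between-subject *correlations* are not supported:
  covariates act on random-effect variances only, correlations are
  covariate-free.
* LRTs for variance components use the naive $\chi^2$ reference;
  boundary-corrected mixtures are out of scope.
* The 0–4 item scale is treated as continuous; ordinal/IRT measurement
  models are out of scope.
* Standard errors are model-based (observed information); no
  robust/sandwich variant is provided.
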