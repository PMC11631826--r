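---
title: "Local IV estimation of heterogeneous treatment effects with livhte"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local IV estimation of heterogeneous treatment effects with livhte}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(livhte)
```

## The estimation problem

We want the effect of a binary treatment $D$ (e.g. starting a DPP4
inhibitor rather than a sulfonylurea at second-line intensification) on a
continuous outcome $Y$ (change in HbA1c, mmol/mol, at week 52), from
routine-care data in which prescribers choose $D$ partly on information
we never observe. Two kinds of unobservables matter:

* **confounding**: unobserved prognosis correlated with both treatment
  choice and the untreated outcome; and
* **essential heterogeneity**: selection on the unobserved *gain* itself
  — patients (or their prescribers) who expect to benefit more are more
  likely to be treated.

Under essential heterogeneity the treatment effect varies with the very
unobservable that drives selection, so selection-on-observables methods
(OLS, matching, IPTW) are biased for the ATE, and ordinary 2SLS — though
consistent for *an* instrument-weighted effect — does not generally
recover the ATE either. The local-instrumental-variable (LIV) approach
identifies the whole marginal-treatment-effect curve and lets us
aggregate it to any population of interest.

## Model

Treatment follows a latent-index rule
$$D_i = \mathbf 1\{\Phi(\mu_D(x_i, z_i)) > V_i\},\qquad V_i \sim U(0,1),$$
where $z$ is a continuous instrument and $V$ is the patient's unobserved
*resistance* to treatment. The propensity $p(x,z)=\Phi(\mu_D(x,z))$ is
estimated by a probit first stage (`fit_propensity()`); treated patients
are those whose resistance falls below their propensity.

The outcome regression (`fit_outcome()`) is
$$E[Y \mid x, p] = x'\beta + K(p) + p \cdot x_I'\gamma,$$
with $K(\cdot)$ a polynomial (degree 3 by default, fitted in an
orthogonal basis for numerical stability) and $x_I$ the covariates
interacted with the propensity. The **marginal treatment effect** at
resistance level $v = p$ is the analytic derivative
$$\mathrm{MTE}(x, p) = \frac{\partial E[Y\mid x,p]}{\partial p}
  = K'(p) + x_I'\gamma,$$
available from `mte()`. The orthogonal-basis coefficients are converted
exactly to the raw power basis (by solving a small Vandermonde system at
interpolation points), so the derivative is evaluated analytically, not
numerically.

**Personalised treatment effects** (`pet_effects()`) integrate the MTE
over the resistance values compatible with the patient's observed
treatment. One shared vector of draws $u \sim U(\min\hat p, \max\hat p)$
serves all patients: a treated patient averages the MTE over draws
$u < \hat p_i$ (they were treated, so their resistance lies below their
propensity), an untreated patient over $u \ge \hat p_i$. The shared
draws make the aggregation exact: for every patient, the
$w$-weighted combination of the two branch means equals the mean MTE over
*all* draws to machine precision, so sample averages of PeT effects are
internally consistent ATEs over the identified support. The average of
PeT effects over any subpopulation (subgroup CATEs, RCT-eligible
patients, and so on) is produced by `aggregate_effects()`.

### Term selection

`liv(select = "plugin")` chooses quadratic, covariate-interaction and
instrument(or propensity)-interaction terms with a plugin-penalty
("rigorous") lasso: the penalty is the Belloni-type
$\lambda = 2c\sqrt n\,\Phi^{-1}(1-\gamma/2p)$ with
heteroscedasticity-robust loadings $\hat\psi_j = \sqrt{\overline{x_j^2
\hat e^2}}$, iterated twice; main effects, the instrument and the
propensity polynomial are forced (never penalized). Selection runs in
both stages with stage-agnostic term names, and the **union** of the two
selected sets is used in both final models, so the first and second stage
share one specification.

## The instrument

The tendency-to-prescribe (`compute_ttp()`) is the fraction of the
cluster's prescriptions in the 365 days *before* the patient's index date
that were for the index drug class — a half-open window, so the patient's
own day-zero prescription never enters their instrument value.
Diagnostics:

* `weak_iv_test()` — first-stage F as the squared $t$ statistic of the
  instrument coefficient with CR1 cluster-robust (region-level) errors;
  the conventional strength benchmark for this design is F > 100;
* `balance_by_iv()` — standardized mean differences of covariates
  between top and bottom instrument bins (|SMD| ≤ 0.1 as the usual
  balance rule): the instrument should predict treatment, not case mix.

## Inference

`liv_boot()` wraps the full refit (propensity, outcome, PeT,
aggregation) in a stratified nonparametric bootstrap: patients are
resampled within region × treatment strata, the lasso-selected
specification is frozen at the full-sample choice, and intervals are
$\hat\theta \pm t_{1-\alpha/2,\,B-1}\,\mathrm{SD}(\hat\theta^*_b)$.
Replicate seeds derive from one master seed and are recorded.

## Comparators

* `iptw_ra()` — IPTW with regression adjustment and recycled
  predictions: probit treatment model on covariates only (the instrument
  is deliberately excluded), stabilized truncated weights, a weighted
  outcome regression with treatment × covariate terms, and per-patient
  predicted contrasts. Doubly robust, and identical to weighted
  g-computation by construction.
* `two_stage_least_squares()` — linear IV with CR1 cluster-robust
  errors; under essential heterogeneity it estimates an
  instrument-weighted average of marginal effects, not the ATE.
* `wald_late()` — the grouped-instrument Wald ratio.

## The synthetic cohort generator

`generate_cohort()` simulates the full observational structure so every
estimator can be checked against known truth:

* clusters (practices) within regions, each with a latent preference
  $\pi_k = \Phi(\Phi^{-1}(\text{base}) + \alpha_k)$,
  $\alpha_k \sim N(0, \text{spread}^2)$;
* a *dynamic* instrument: each patient's TTP is computed from the
  cluster's actual prescription history (background events plus earlier
  cohort patients' own treatments) over the preceding 365 days, after a
  burn-in year — so the instrument has realistic within-cluster
  autocorrelation and sampling noise, while treatment depends on the
  realized instrument value, keeping the probit first stage correctly
  specified;
* latent-index selection $D=\mathbf 1\{\Phi(\mu_D(x,z))>V\}$ with
  $V\sim U(0,1)$;
* potential outcomes
  $Y_1 - Y_0 = \tau_0 + x'\tau_x + \eta$, where
  $\eta = \rho_{ess}\sigma_{g}\Phi^{-1}(V)
  + \sqrt{1-\rho_{ess}^2}\,\sigma_{g}\,\xi$ creates essential
  heterogeneity with the closed form
  $\mathrm{MTE}(x,v) = \tau_0 + x'\tau_x +
  \rho_{ess}\sigma_{g}\Phi^{-1}(v)$ (`closed_form_mte()`), and the
  untreated residual is correlated with $V$ through $\rho_{conf}$
  (pure confounding);
* measurement realism: jittered follow-up dates with a ±90-day window
  around week 52, missing outcomes, baseline-measurement recency.

Default parameters mimic a UK primary-care type 2 diabetes cohort at
second-line intensification (HbA1c ≈ 73 ± 17 mmol/mol, ~40% female,
~37% treated, ~32% missing outcomes). The generator is intentionally
simple where realism does not pay for itself: covariates are mutually
independent truncated normals, cluster assignment ignores geography, and
calendar trends are absent.

```{r example}
sc <- generate_cohort(dgp_config(n_patients = 4000, n_clusters = 60,
                                 seed = 1))
cc <- complete_case_filter(sc$cohort)$cohort
weak_iv_test(cc)$f_statistic
fit <- liv(y ~ d | ttp, cc, select = "plugin")
summary(fit)
plot(fit, data = cc)
```

## Numerical and design choices

* **Polynomial degree 3** for $K(p)$ by default. The truth in the
  generator implies $K'(p) \propto \Phi^{-1}(p)$, which a cubic tracks
  well over the bulk of the unit interval; degree 4 buys no bias
  reduction at realistic sample sizes, and degree 5 inflates the
  derivative variance in the tails substantially. The degree is a
  parameter (`liv_terms(pscore_poly_degree = )`).
* **Oracle recovery configurations** (`oracle_config()`) used by the
  tests put the generator in a wide-support, low-noise regime: recovery
  tolerances then measure estimator bias rather than Monte-Carlo noise.
  A biased estimator fails those checks at any noise level; the noise
  level only controls the power of the check.
* **Propensity clipping** at $10^{-3}$ bounds influence of extreme
  fitted propensities; the PeT support is the observed range of clipped
  propensities, and effects are explicitly support-truncated.
* **Shared-draw PeT integration** uses sorted draws and prefix sums, so
  the per-patient conditional means are exact (no per-patient
  re-sampling), $O((n + m)\log m)$ overall.
* **Seeds** are explicit everywhere; per-cluster generator streams are
  derived from the master seed, and pipeline runs are byte-reproducible
  from their resolved config.

## Pipeline

`run_pipeline(run_config(...), out_dir)` executes: simulate (or load an
external cohort CSV) → eligibility flow → subgroup labels →
RCT-eligibility split → outcome windowing and complete-case filter →
instrument diagnostics → LIV fit → comparators → aggregation and
bootstrap → optional benchmark-agreement check, and writes all tables,
the resolved YAML config and a manifest (with an FNV-1a hash of the
config) to `out_dir`.
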