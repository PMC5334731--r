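---
title: "Random-effects generalized ordered probit models for BMI category panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-effects generalized ordered probit models for BMI category panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regoprobit)
```

## The model

`regoprobit` estimates ordered-response models for panel data in which the
outcome is one of `J` ordered categories — the motivating application is the
three WHO body-mass-index groups *normal* (1), *overweight* (2) and
*obese* (3) observed annually for the same individuals in a household survey.

The standard ordered probit posits a latent index `y* = x'b + e`,
`e ~ N(0, 1)`, cut by fixed thresholds: every covariate shifts all category
boundaries by the same amount (the *parallel lines* assumption).  The
generalized ordered response model relaxes this by letting the thresholds be
linear in the covariates, which is equivalent to giving each cumulative
equation its own coefficient vector.  We parameterize the `J - 1` cumulative
equations on the greater-than scale,

    P(y_it > j | x_it, alpha_i) = Phi(c_j + x_it' b_j + alpha_i),

so that a positive printed coefficient raises the probability of the heavier
categories, matching the way such coefficient tables are usually read.  On
this scale the classical thresholds are `gamma_j = -c_j`.  A covariate in the
model's *parallel set* has one coefficient shared by all equations; when every
covariate is shared the model collapses to the standard ordered probit
(verified against an independent reference implementation in the test suite).

Panel persistence enters through a shared individual effect
`alpha_i ~ N(0, sigma_alpha^2)`, drawn once per individual and common to all
waves and to both cumulative equations (a single effect, hence a single
persistence statistic).  With the idiosyncratic probit variance fixed at 1 for
identification, the share of latent variance due to the individual effect is

    rho = sigma_alpha^2 / (sigma_alpha^2 + 1),

the latent intra-individual correlation across waves.  The marginal likelihood
of an individual integrates the product of wave-level category probabilities
over `alpha`, approximated by non-adaptive Gauss–Hermite quadrature with the
change of variable `alpha = sqrt(2) * sigma_alpha * node`.

Because the generalized model does not constrain the cumulative curves to be
ordered, an interior category probability can be negative at some covariate
values.  The package keeps the two faces of this fact separate:
`category_probabilities()` truncates and renormalizes with a validity flag
(a proper distribution for prediction), while the likelihood uses raw
differences and returns `-Inf` for an observed outcome with non-positive
probability; `validity_diagnostic()` counts affected observations.  During
optimization only, per-observation probabilities are floored at `1e-300` so
the objective stays finite and steeply repelling rather than undefined.

## Estimation

`fit_mle()` maximizes the quadrature likelihood over the free parameters by
BFGS with the analytic score, followed by a damped Newton polish on the
observed information.  Choices that matter:

* **Equality constraints by parameter sharing.**  The free-parameter map
  assigns one slot to each parallel-set covariate and one slot per equation
  otherwise.  Constraints are therefore exact, and the covariance matrix
  lives directly on the free space — no penalties or Lagrange multipliers.
* **Internal standardization.**  The optimizer works on centered, unit-SD
  covariates.  The default cohort mixes binary indicators with age squared
  (values in the thousands) and annual expenditures (SD above 2000), giving
  raw-scale curvatures spread over eight orders of magnitude; standardizing
  is an exact linear reparameterization, undone — including the covariance,
  via the corresponding Jacobian — after convergence.
* **`sigma_alpha` on the log scale** keeps the optimizer unconstrained; the
  reported SE is delta-method transformed back.  An estimate collapsing to
  zero is reported as a boundary fit with `rho = 0`, not an error.
* **Convergence** is declared when the optimizer terminates normally and the
  score max-norm (on the standardized scale) falls below
  `grad_tol * max(1, |loglik| / n_individuals)` with `grad_tol = 1e-3` —
  a scale-relative criterion: an absolute score threshold has no single
  sensible value across log-likelihoods ranging from tens to tens of
  thousands.  At the default tolerance the residual parameter movement
  implied by the leftover score is orders of magnitude below one standard
  error.  The relative log-likelihood stop (`reltol = 1e-10`) and the final
  score norm are both recorded on the fit object.
* **Covariance** is the inverse observed information, a central-difference
  Hessian of the analytic score.  Cluster-robust alternatives are out of
  scope; the observed information is correct under the maintained model,
  which is also the model the synthetic cohort is drawn from.
* **Starting values** come from the fully parallel pooled ordered probit
  (itself fit from zero slopes and frequency-based intercepts), replicated
  across equations, with `sigma_alpha` started at 1.

## Quadrature accuracy

Non-adaptive Gauss–Hermite places nodes on the scale of the *prior* of
`alpha`, while the integrand concentrates on the posterior, whose width
shrinks like `1/sqrt(T)`.  Accuracy therefore degrades as
`sigma_alpha * sqrt(T)` grows.  Empirically (and exercised by the test
suite): for `sigma_alpha <= ~1` and up to four waves, 30 nodes agree with a
4001-point Simpson oracle to better than `1e-8`; at the persistence level of
the calibrated cohort (`sigma_alpha ~ 2.4`, five waves) the 15-node
likelihood carries a visible approximation error, which is part of the
fitting protocol being validated rather than a defect to be tuned away — the
recovery study below measures the combined simulation-plus-estimation error
of exactly that protocol.  The node count is configurable everywhere;
adaptive quadrature is deliberately out of scope.

## Testing down the parallel-lines restrictions

`wald_variable_equality()` tests, for one covariate, equality of its
coefficients across cumulative equations (one constraint when `J = 3`);
`wald_joint_parallel()` stacks several such restrictions, and
`wald_slopes_zero()` is the overall model test (free slope slots only, shared
parameters counted once).  All reduce to the standard quadratic form in the
free-parameter covariance; a restriction satisfied exactly by construction
returns statistic 0 without inverting a singular form.

`sequential_test_down()` implements the specific-to-general search used with
such models: fit, test every unrestricted covariate, restrict the one with
the largest p-value if it exceeds `alpha_stop` (default 0.05), refit, repeat
until every remaining relaxation is significant.  Design points, each
deliberate:

* each round's tests use the **current restricted fit**, matching the
  estimate–test–restrict cycle the procedure describes;
* **one restriction per round** (the single least-significant variable), not
  batch restriction;
* ties in p-value break by covariate order in the specification, making the
  trace a deterministic function of the data;
* **no multiplicity correction** is applied across rounds — the trace carries
  a note to that effect, since the sequential p-values are exploratory
  statistics, not error-controlled tests.

The trace records, per round, the restricted set, all per-variable p-values,
and the action taken, so either a per-round or a final-only rendering can be
produced.

## The synthetic cohort

No public data accompany the motivating application (household panels of this
kind are access-restricted), so the package ships a generator whose defaults
are the study conditions themselves, not adjustable conveniences:

* **Covariate marginals** follow the published descriptives of an Australian
  adult cohort: gender `Bernoulli(0.476)`; age truncated-normal on
  `[15, 95]` with mean 45.866 and SD 17.848; employment, lone-parent
  household and marital status indicators; remoteness area, life
  satisfaction, education and SEIFA-advantage-decile ordinal scores with
  their published frequency tables; log disposable income per person
  `N(10.108, 0.640)`; and the five FFM personality traits truncated-normal
  on the 1–7 scale.
* **Truncated normals are moment-matched**: the parent normal's parameters
  are solved (deterministically, from the closed-form truncated moments) so
  that the *truncated* distribution attains the target mean and SD — naive
  truncation of a normal with the target parameters would shift the age mean
  by about +1.5 years, violating the calibration the generator exists to
  provide.
* **Expenditures are moment-matched log-normals.**  Annual alcohol and
  meals-out spending have SDs exceeding their means, impossible for a normal
  on a non-negative support; a log-normal matched on the first two moments is
  the minimal right-skewed choice.
* **Ordinal scores enter as single numeric covariates** (no dummy
  expansion), exactly as single-coefficient-per-variable reporting implies.
* **Only age is time-varying** (plus its square, recomputed per wave): the
  remaining covariates are near-static over a five-wave window and only
  pooled marginals are published, so covariate dynamics are not modelled.
  Ages may drift slightly past the wave-1 upper bound in later waves; the
  calibration target is the wave-1 cross-section.
* **Covariates are independent** across columns.  Only marginals are
  published; any correlation structure would be invented.  Consequently the
  generator reproduces marginal calibration targets but *not* realistic
  covariate dependence (age–income, education–advantage, …), and passing
  recovery tests demonstrate estimator correctness under the maintained
  model, not robustness to real-data features such as attrition, household
  clustering, misreported anthropometrics, or correlated regressors.
* **Outcomes are drawn from the model itself**: per-individual normal effect,
  generalized cumulative probabilities per wave, one uniform draw per wave.
  Non-monotone cumulative pairs are clipped by default (with a reported
  counter; the calibrated truth yields a clip fraction of zero to well below
  0.1%), or can reject the affected individuals or raise an error.  All
  randomness flows from explicit seeds; the caller's RNG state is preserved.

Two published inconsistencies are flagged rather than resolved: the pooled
outcome-score mean of 2.810 is incompatible with the published category
frequencies (41.68/35.59/22.72, implying ~1.81), and the lone-parent
indicator's printed SD (0.181) is impossible for a 0/1 variable with mean
0.304.  The generator targets the frequency table and the Bernoulli mean,
respectively.  Under the calibrated truth with independent covariates the
simulated category split is approximately (38, 41, 21)% — same ranks for
categories 2 vs 3 but with *overweight* marginally ahead of *normal*; exact
reproduction of the published split is not possible without the real
covariate dependence.

## The calibration truth and the recovery study

`hilda_truth()` returns the data-generating parameter values used by the
validation harness: two 18-coefficient slope vectors with six covariates
(area, hhtype, alcohol, meals, agree, emote) held parallel, intercepts
(-5.2483, -4.4469), and `sigma_alpha = sqrt(0.852/0.148) ~ 2.40`, i.e.
`rho = 0.852` — a strongly persistent cohort.  `recovery_study()` simulates
panels of 3,000 individuals over 5 waves from this truth, refits the *fully
generalized* random-effects model (39 free parameters) with 15-node
quadrature, and averages over three seeds.  Problem sizes were chosen so the
full study runs in a few minutes on one CPU while leaving each coefficient's
Monte-Carlo standard error small relative to its magnitude; the test suite
asserts recovery of six representative coefficients within three Monte-Carlo
standard errors and of `rho` within 0.05.

The type-I-error study for the per-variable parallel-lines Wald test uses a
deliberately compact design — three covariates, 500 individuals, three waves,
`sigma_alpha = 1`, nine nodes, 200 replications — sized so that 200
generalized-model fits complete in a couple of minutes while the binomial
uncertainty of the estimated level (about ±0.046 at three SEs) is still
informative.

## Known limitations

* Ordered logit links, heteroskedastic probit, Mundlak-style correlated
  random effects, and more than one random effect are out of scope.
* Marginal effects are not computed.
* The Wald tests rely on the asymptotic normal approximation; no
  small-sample corrections are offered.
* Non-adaptive quadrature loses accuracy at large `sigma_alpha * sqrt(T)`
  (see above); users fitting highly persistent long panels should raise the
  node count and check sensitivity.

## A worked example

```{r example, eval = FALSE}
## all randomness flows through explicit seed arguments
panel <- simulate_gop_panel(n_individuals = 800, n_waves = 5, seed = 1)

## unrestricted generalized fit
spec <- gop_spec(setdiff(names(panel), c("id", "wave", "y")))
fit <- fit_mle(panel, spec, fit_options(nodes = 15))
print(fit)

## sequential test-down of the parallel-lines restrictions
td <- sequential_test_down(panel, spec, fit_options(nodes = 15))
print(td$trace)

## descriptives and dynamics
transition_matrix(panel)
render_fit_report(td$fit)
```
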