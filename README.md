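# regoprobit

Random-effects generalized ordered probit models for ordered categorical
panel outcomes, built around the dynamics of body-mass-index (BMI)
categories — *normal*, *overweight*, *obese* — in household panel surveys.
It is aimed at biostatisticians and applied econometricians who need to (i)
model an ordered outcome observed repeatedly for the same individuals, (ii)
test, covariate by covariate, whether the classical *parallel lines*
restriction of the ordered probit holds, and (iii) quantify how much of the
latent variation is persistent within individuals.

## The model

For individual *i* at wave *t* with outcome `y_it` in `{1, ..., J}` and
covariates `x_it`, the package parameterizes the `J - 1` cumulative
equations as

    P(y_it > j | x_it, alpha_i) = Phi(c_j + x_it' b_j + alpha_i),

with `alpha_i ~ N(0, sigma_alpha^2)` a shared individual effect and the
idiosyncratic probit variance fixed at 1.  Classical thresholds correspond
to `gamma_j = -c_j`.  Slopes `b_j` may differ by equation (the *generalized*
model); covariates in the model's parallel set carry a single coefficient
shared across equations, and restricting every covariate recovers the
standard ordered probit.  The individual effect is integrated out by
Gauss–Hermite quadrature, and the persistence ratio

    rho = sigma_alpha^2 / (sigma_alpha^2 + 1)

is the latent intra-individual correlation across waves.

Main entry points:

| purpose | functions |
|---|---|
| synthetic calibrated cohort | `default_hilda_spec()`, `generate_covariates()`, `simulate_outcomes()`, `simulate_gop_panel()`, `hilda_truth()` |
| probability model | `category_probabilities()`, `marginal_loglik_individual()`, `total_loglik()`, `validity_diagnostic()` |
| estimation | `fit_mle()`, `fit_standard_ordered_probit()`, `starting_values()`, `compute_rho()` |
| parallel-lines testing | `wald_variable_equality()`, `wald_joint_parallel()`, `wald_slopes_zero()`, `sequential_test_down()` |
| reporting | `bmi_to_category()`, `transition_matrix()`, `descriptive_tables()`, `render_fit_report()` |

A thin command-line front end (`inst/cli/regop-cli.R`) exposes `simulate`,
`fit`, `testdown`, `transitions` and `describe` subcommands over CSV panels.

## A worked example

```r
library(regoprobit)

## a calibrated synthetic cohort: 800 individuals over 5 waves
panel <- simulate_gop_panel(n_individuals = 800, n_waves = 5, seed = 1)

transition_matrix(panel)
#> Transition probabilities, wave 1 -> 5 (n = 800 )
#>     to
#> from     1     2     3
#>    1 0.764 0.233 0.003
#>    2 0.135 0.668 0.197
#>    3 0.011 0.262 0.727

fit <- fit_standard_ordered_probit(panel, random_effects = TRUE,
                                   options = fit_options(nodes = 15))
fit
#> Random-effects generalized ordered probit fit
#>   N obs = 4000  individuals = 800  nodes = 15
#>   log-likelihood = -2712.413, converged = TRUE (score max-norm 0.00179)
#>   sigma_alpha = 2.372  rho = 0.849
```

The transition matrix shows the strong diagonal persistence typical of BMI
categories (76–73% of individuals keep their category over four years), and
the fitted `rho = 0.849` attributes about 85% of the latent variance to the
stable individual effect — close to the generator's calibrated value of
0.852.  `sequential_test_down(panel, spec, ...)` would then relax the
parallel-lines restriction covariate by covariate; see the methods vignette
(`vignettes/regoprobit-methods.Rmd`) for the model, the testing procedure,
and every numerical design choice.

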