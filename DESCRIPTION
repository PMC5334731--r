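Package: regoprobit
Title: Random-Effects Generalized Ordered Probit Models for BMI Category Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimation and testing of random-effects generalized ordered probit
    models for ordered categorical panel outcomes, motivated by the dynamics of
    body-mass-index (BMI) categories (normal, overweight, obese) in household
    panel surveys. Provides the generalized (non-parallel) cumulative probit
    likelihood with a shared individual random effect integrated out by
    Gauss-Hermite quadrature, maximum marginal likelihood estimation under
    arbitrary cross-equation equality (parallel-lines) constraints, Wald tests
    of the parallel-lines hypothesis with the sequential test-down procedure,
    the intra-individual persistence ratio rho, empirical category transition
    matrices, WHO BMI categorization, and a calibrated synthetic panel
    generator emulating an Australian household survey cohort for validation
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
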