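## One moderately non-parallel fit shared across the Wald unit tests.
wald_fit <- local({
  pan <- small_panel(800, seed = 101,
                     params = small_params(eq1 = c(0.9, -0.4, 0.3),
                                           eq2 = c(0.1, -0.4, 0.3)))
  fit_mle(pan, small_spec(), fit_options(nodes = 9))
})

test_that("single-constraint Wald equals the squared z-ratio", {
  slot <- which(names(coef(wald_fit)) == "eq1:x1")
  R <- matrix(0, 1, wald_fit$map$n_free)
  R[1, slot] <- 1
  w <- wald_linear(wald_fit, R)
  z <- coef(wald_fit)[slot] / wald_fit$se[slot]
  expect_equal(w$statistic, unname(z^2), tolerance = 1e-10)
  expect_equal(w$df, 1L)
  ## invariance to row scaling
  w2 <- wald_linear(wald_fit, 7.3 * R)
  expect_equal(w2$statistic, w$statistic, tolerance = 1e-10)
})

test_that("constraints satisfied exactly give statistic 0 and p = 1", {
  pan <- small_panel(300, seed = 103)
  fit <- fit_mle(pan, small_spec(parallel_set = "x2"),
                 fit_options(nodes = 9))
  ## eq1:x2 - eq2:x2 = 0 holds by construction (shared slot)
  slot <- regoprobit:::free_slot(fit, 1, "x2")
  R <- matrix(0, 1, fit$map$n_free)
  R[1, slot] <- 1
  R[1, regoprobit:::free_slot(fit, 2, "x2")] <-
    R[1, regoprobit:::free_slot(fit, 2, "x2")] - 1   # same slot: row is zero
  w <- wald_linear(fit, R)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)
})

test_that("per-variable equality test matches its joint one-variable form", {
  w1 <- wald_variable_equality(wald_fit, "x1")
  wj <- wald_joint_parallel(wald_fit, "x1")
  expect_equal(w1$statistic, wj$statistic, tolerance = 1e-12)
  expect_equal(w1$df, wj$df)
  expect_error(wald_joint_parallel(wald_fit, character(0)), "no variables")
  ## strongly non-parallel x1 is detected, parallel x2 is not
  expect_lt(w1$p_value, 0.01)
  expect_gt(wald_variable_equality(wald_fit, "x2")$p_value, 0.01)
})

test_that("already-shared variables cannot be retested", {
  pan <- small_panel(300, seed = 107)
  fit <- fit_mle(pan, small_spec(parallel_set = "x3"),
                 fit_options(nodes = 9))
  expect_error(wald_variable_equality(fit, "x3"), "already constrained")
})

test_that("model Wald test has df equal to the free slope count", {
  w <- wald_slopes_zero(wald_fit)
  expect_equal(w$df, 6L)                       # 2 equations x 3 covariates
  expect_lt(w$p_value, 1e-6)                   # strong signal DGP
  pan <- small_panel(300, seed = 109)
  fit <- fit_mle(pan, small_spec(parallel_set = c("x1", "x2")),
                 fit_options(nodes = 9))
  expect_equal(wald_slopes_zero(fit)$df, 4L)   # 2 shared + 2 free
})

test_that("model Wald test keeps its nominal level under a null DGP", {
  ## all slopes zero: non-rejection expected at alpha = 0.05
  null_params <- small_params(eq1 = c(0, 0, 0), eq2 = c(0, 0, 0),
                              sigma_alpha = 1)
  rej <- 0
  for (s in 1:20) {
    pan <- small_panel(300, seed = 200 + s, params = null_params)
    fit <- fit_mle(pan, small_spec(), fit_options(nodes = 9))
    if (wald_slopes_zero(fit)$p_value < 0.05) rej <- rej + 1
  }
  expect_lte(rej, 4)                           # binomial(20, .05), generous
})

test_that("test-down restricts parallel variables and keeps non-parallel", {
  pan <- small_panel(800, seed = 113,
                     params = small_params(eq1 = c(1.2, -0.4, 0.3),
                                           eq2 = c(-0.6, -0.4, 0.3)))
  td <- sequential_test_down(pan, small_spec(),
                             fit_options(nodes = 9), alpha_stop = 0.05)
  final_parallel <- td$fit$spec$parallel_set
  expect_false("x1" %in% final_parallel)       # strongly non-parallel
  expect_true(length(td$trace$steps) <= length(small_vars) + 1L)
  ## restricted set grows monotonically along the trace
  sets <- lapply(td$trace$steps, `[[`, "parallel_set")
  for (i in seq_along(sets)[-1])
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  ## final step: every remaining relaxation significant (or none left)
  last <- td$trace$steps[[length(td$trace$steps)]]
  if (length(last$p_values))
    expect_true(all(last$p_values <= 0.05))
})

test_that("test-down is deterministic and terminates within K rounds", {
  pan <- small_panel(400, seed = 127)
  t1 <- sequential_test_down(pan, small_spec(), fit_options(nodes = 9))
  t2 <- sequential_test_down(pan, small_spec(), fit_options(nodes = 9))
  expect_identical(t1$trace, t2$trace)
  expect_identical(coef(t1$fit), coef(t2$fit))
  expect_lte(length(t1$trace$steps), length(small_vars) + 1L)
})

test_that("restriction chosen by Wald is consistent with likelihood ratio", {
  ## restricting a truly parallel variable moves the loglik by less than a
  ## chi-square(1) fluctuation
  pan <- small_panel(600, seed = 131)
  opts <- fit_options(nodes = 9, covariance = "none")
  full <- fit_mle(pan, small_spec(), opts)
  restr <- fit_mle(pan, small_spec(parallel_set = "x1"), opts)
  lr <- 2 * (full$loglik - restr$loglik)
  expect_gte(lr, -1e-6)
  expect_lt(lr, stats::qchisq(0.999, df = 1))
})
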