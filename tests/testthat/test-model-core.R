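test_that("linear index evaluates c_j + x'beta_j", {
  p <- gop_params(rbind(c(0.5, -0.25), c(0.1, 0.2)), c(1, 0))
  expect_equal(linear_index(c(0, 0), p, 1), 1)
  expect_equal(linear_index(c(1, 2), p, 1), 1 + 0.5 - 0.5)
  expect_equal(linear_index(c(0, 0),
                            gop_params(rbind(c(0, 0), c(0, 0)),
                                       c(-5.2483, -4.4469)), 1),
               -5.2483)
  expect_error(linear_index(c(1, 2, 3), p, 1), "length")
  expect_error(linear_index(c(1, 2), p, 3), "out of range")
})

test_that("category probabilities match the normal-CDF oracle", {
  z <- gop_params(rbind(c(0, 0), c(0, 0)), c(0, 0))
  expect_equal(unname(category_probabilities(c(0, 0), z)$p), c(0.5, 0, 0.5))

  p <- category_probabilities(c(0, 0),
                              gop_params(rbind(c(0, 0), c(0, 0)), c(0, -1)))
  expect_equal(unname(p$p),
               c(0.5, stats::pnorm(1) - 0.5, stats::pnorm(-1)),
               tolerance = 1e-12)
  expect_true(p$valid)

  ## random draws: probabilities in [0,1], summing to one
  withr::with_seed(5, for (i in 1:25) {
    prm <- gop_params(matrix(rnorm(6), 2, 3), sort(rnorm(2), decreasing = TRUE),
                      abs(rnorm(1)))
    pr <- category_probabilities(rnorm(3), prm, rnorm(1))
    expect_true(all(pr$p >= 0 & pr$p <= 1))
    expect_equal(sum(pr$p), 1, tolerance = 1e-12)
  })
})

test_that("invalid interior probabilities are flagged and renormalized", {
  ## beta_1 far below beta_2 along x makes Phi(z1) < Phi(z2)
  prm <- gop_params(rbind(c(-2, 0, 0), c(2, 0, 0)), c(0, 0))
  pr <- category_probabilities(c(1, 0, 0), prm)
  expect_false(pr$valid)
  expect_equal(sum(pr$p), 1, tolerance = 1e-12)
  expect_equal(unname(pr$p[2]), 0)
})

test_that("conditional panel log-likelihood is additive over waves", {
  prm <- gop_params(rbind(c(0, 0), c(0, 0)), c(0, -1))
  x <- matrix(0, 1, 2)
  l3 <- conditional_panel_loglik(3L, x, prm, 0)
  expect_equal(l3, log(stats::pnorm(-1)), tolerance = 1e-12)
  expect_equal(conditional_panel_loglik(c(3L, 3L), rbind(x, x), prm, 0),
               2 * l3, tolerance = 1e-12)
  ## zero probability -> -Inf, not an error
  prm0 <- gop_params(rbind(c(0, 0), c(0, 0)), c(0, 0))
  expect_identical(conditional_panel_loglik(2L, x, prm0, 0), -Inf)
})

test_that("marginal likelihood degenerates correctly at sigma_alpha = 0", {
  prm <- small_params(sigma_alpha = 0)
  X <- matrix(rnorm(6), 2, 3)
  expect_identical(marginal_loglik_individual(c(1L, 3L), X, prm, 15),
                   conditional_panel_loglik(c(1L, 3L), X, prm, 0))
})

test_that("slopes-free single wave has marginal P(y = 1) = 1/2 by symmetry", {
  ## E[1 - Phi(alpha)] = 1/2 for alpha symmetric about 0, any sigma
  for (sig in c(0.3, 1, 2.5)) {
    prm <- small_params(eq1 = c(0, 0, 0), eq2 = c(0, 0, 0),
                        intercepts = c(0, -1), sigma_alpha = sig)
    expect_equal(marginal_loglik_individual(1L, matrix(0, 1, 3), prm, 40),
                 log(0.5), tolerance = 1e-10)
  }
})

test_that("Gauss-Hermite marginal converges to the dense-grid oracle", {
  withr::with_seed(99, {
    errs <- matrix(NA_real_, 8, 3)
    for (i in 1:8) {
      inst <- random_marginal_instance()
      for (j in seq_along(c(5, 15, 30))) {
        nd <- c(5, 15, 30)[j]
        errs[i, j] <- abs(marginal_loglik_individual(inst$y, inst$X,
                                                     inst$params, nd) -
                            inst$oracle)
      }
    }
    ## error decreasing in node count; 30 nodes within 1e-8
    expect_true(all(errs[, 3] <= errs[, 1] + 1e-12))
    expect_lt(max(errs[, 3]), 1e-8)
  })
})

test_that("vectorized total log-likelihood equals the per-individual loop", {
  spec <- small_spec()
  pan <- small_panel(40, waves = 3L, seed = 13)
  prm <- small_params()
  expect_equal(total_loglik(pan, prm, spec, nodes = 15),
               naive_total_loglik(pan, prm, spec, nodes = 15),
               tolerance = 1e-10)
  ## additivity over disjoint datasets
  p1 <- pan[pan$id <= 20, ]
  p2 <- pan[pan$id > 20, ]
  expect_equal(total_loglik(pan, prm, spec),
               total_loglik(p1, prm, spec) + total_loglik(p2, prm, spec),
               tolerance = 1e-10)
})

test_that("parallel case reduces to the standard ordered probit formula", {
  ## all variables parallel, sigma = 0: p_j = Phi(gamma_j - x'b) -
  ## Phi(gamma_{j-1} - x'b) with gamma_j = -c_j
  prm <- small_params(sigma_alpha = 0)
  withr::with_seed(3, for (i in 1:10) {
    x <- rnorm(3)
    pr <- category_probabilities(x, prm)$p
    gam <- -prm$intercepts
    eta <- sum(x * prm$slopes[1, ])
    std <- c(stats::pnorm(gam[1] - eta),
             stats::pnorm(gam[2] - eta) - stats::pnorm(gam[1] - eta),
             1 - stats::pnorm(gam[2] - eta))
    expect_equal(unname(pr), std, tolerance = 1e-12)
  })
})

test_that("raising an eq1 slope weakly lowers p1 at positive covariates", {
  base <- small_params()
  bumped <- small_params(eq1 = c(0.9, -0.4, 0.3))
  withr::with_seed(8, for (i in 1:10) {
    x <- abs(rnorm(3))
    expect_lte(category_probabilities(x, bumped)$p[1],
               category_probabilities(x, base)$p[1])
  })
})

test_that("sign symmetry reverses the probability vector in the parallel case", {
  ## reversing the latent scale (y* -> -y*) maps slopes to their negatives
  ## and thresholds gamma to rev(-gamma), i.e. intercepts c to rev(-c)
  prm <- small_params(sigma_alpha = 0)
  neg <- gop_params(-prm$slopes, rev(-prm$intercepts), 0)
  withr::with_seed(4, for (i in 1:10) {
    x <- rnorm(3)
    expect_equal(unname(category_probabilities(x, prm)$p),
                 rev(unname(category_probabilities(x, neg)$p)),
                 tolerance = 1e-12)
  })
})

test_that("validity diagnostic counts negative-interior observations", {
  spec <- small_spec()
  pan <- small_panel(100, seed = 17)
  ## proper parallel model: none
  expect_identical(validity_diagnostic(pan, small_params(), spec)$count, 0L)
  ## crafted crossing along x1
  bad <- small_params(eq1 = c(-2, 0, 0), eq2 = c(2, 0, 0),
                      intercepts = c(0, 0))
  expect_gte(validity_diagnostic(pan, bad, spec)$count, 1L)
  ## empty dataset
  expect_identical(validity_diagnostic(pan[0, ], bad, spec)$count, 0L)
})

test_that("panel validation rejects malformed inputs", {
  pan <- small_panel(10, seed = 1)
  dup <- rbind(pan, pan[1, ])
  expect_error(validate_panel(dup), "duplicated")
  bad <- pan
  bad$y[1] <- 9L
  expect_error(validate_panel(bad, small_spec()), "1..3")
  nax <- pan
  nax$x1[2] <- NA
  expect_error(validate_panel(nax, small_spec()), "missing values")
})

test_that("panel CSV round-trip preserves the data", {
  pan <- small_panel(15, seed = 23)
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(pan, f)
  back <- read_panel(f, small_spec())
  expect_equal(back, as.data.frame(lapply(pan, unclass)),
               ignore_attr = TRUE)
})
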