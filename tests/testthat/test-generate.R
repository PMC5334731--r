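test_that("generation is deterministic in the seed and varies across seeds", {
  spec <- default_hilda_spec()
  a <- generate_covariates(spec, 200, 3, seed = 11)
  b <- generate_covariates(spec, 200, 3, seed = 11)
  c <- generate_covariates(spec, 200, 3, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("age advances one year per wave and age2 is its exact square", {
  pan <- generate_covariates(default_hilda_spec(), 50, 4, seed = 3)
  expect_equal(pan$age2, pan$age^2)
  byid <- split(pan, pan$id)
  for (d in byid[1:5])
    expect_equal(diff(d$age[order(d$wave)]), rep(1, 3))
  ## all other covariates constant within individual
  for (v in c("gender", "empstatus", "lndinc_p", "alcohol", "consc"))
    expect_true(all(vapply(byid, function(d) length(unique(d[[v]])) == 1L,
                           logical(1))), label = v)
})

test_that("generated marginals converge to the calibration targets", {
  pan <- generate_covariates(default_hilda_spec(), 10000, 1, seed = 42)
  n <- nrow(pan)
  ## 3 Monte-Carlo standard errors around each target
  chk <- function(x, mean, sd) {
    expect_lt(abs(base::mean(x) - mean), 3 * sd / sqrt(n))
    expect_lt(abs(stats::sd(x) - sd), 3 * sd / sqrt(n))  # generous for SD
  }
  chk(pan$age, 45.866, 17.848)
  chk(pan$lndinc_p, 10.108, 0.640)
  chk(pan$agree, 5.369, 0.912)
  expect_lt(abs(mean(pan$gender) - 0.476), 3 * 0.5 / sqrt(n))
  expect_lt(abs(mean(pan$marstatus) - 0.658), 3 * 0.48 / sqrt(n))
  ## skewed expenditures: mean within 3 SEs of its own SD
  expect_lt(abs(mean(pan$alcohol) - 1450.713), 3 * 2355.439 / sqrt(n))
  ## categorical frequencies
  f_area <- as.numeric(table(factor(pan$area, levels = 0:4))) / n
  expect_lt(max(abs(f_area - c(0.6169, 0.2528, 0.1119, 0.0150, 0.0034))),
            3 * sqrt(0.62 * 0.38 / n))
})

test_that("outcome simulation is seed-deterministic and model-consistent", {
  params <- small_params()
  a <- small_panel(300, seed = 7)
  b <- small_panel(300, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$y %in% 1:3))
  expect_identical(attr(a, "n_clipped"), 0L)

  ## single-wave empirical frequencies vs analytic probabilities at the
  ## generated covariates, within 3 MC standard errors
  cov <- small_covariates(50000, waves = 1L, seed = 9)
  pan <- simulate_outcomes(cov, truth_config(params, seed = 10))
  X <- as.matrix(cov[small_vars])
  sig <- params$sigma_alpha
  ## analytic marginal: integrate Phi over alpha -> scale contraction
  scale <- sqrt(1 + sig^2)
  p_gt1 <- mean(stats::pnorm((params$intercepts[1] +
                                X %*% params$slopes[1, ]) / scale))
  p_gt2 <- mean(stats::pnorm((params$intercepts[2] +
                                X %*% params$slopes[2, ]) / scale))
  p_true <- c(1 - p_gt1, p_gt1 - p_gt2, p_gt2)
  emp <- as.numeric(table(factor(pan$y, levels = 1:3))) / nrow(pan)
  se <- sqrt(p_true * (1 - p_true) / nrow(pan))
  expect_true(all(abs(emp - p_true) < 3 * se))
})

test_that("calibrated truth reproduces the broad published category split", {
  pan <- simulate_gop_panel(4000, 5, seed = 19)
  freq <- as.numeric(table(factor(pan$y, levels = 1:3))) / nrow(pan)
  ## obese least frequent; normal/overweight each roughly at their published
  ## shares (exact reproduction needs the unpublished covariate dependence)
  expect_equal(which.min(freq), 3L)
  expect_lt(max(abs(freq - c(0.4168, 0.3559, 0.2272))), 0.10)
})

test_that("degenerate intercepts force every outcome into category 1", {
  params <- small_params(eq1 = c(0, 0, 0), eq2 = c(0, 0, 0),
                         intercepts = c(-10, -10), sigma_alpha = 0)
  pan <- small_panel(200, seed = 2, params = params)
  expect_true(all(pan$y == 1L))
})

test_that("clip policies behave as documented", {
  ## strongly crossed slopes make p2 < p1 easy to hit
  params <- small_params(eq1 = c(2, 0, 0), eq2 = c(-2, 0, 0),
                         intercepts = c(0, 0.2), sigma_alpha = 0)
  cov <- small_covariates(300, waves = 2L, seed = 21)
  clip <- simulate_outcomes(cov, truth_config(params, seed = 1))
  expect_gt(attr(clip, "n_clipped"), 0L)
  expect_error(simulate_outcomes(cov, truth_config(params, seed = 1,
                                                   clip_policy = "error")),
               "invalid cumulative")
  rej <- simulate_outcomes(cov, truth_config(params, seed = 1,
                                             clip_policy = "reject"))
  expect_lt(length(unique(rej$id)), length(unique(cov$id)))

  ## parallel slopes with ordered intercepts never clip
  ok <- simulate_outcomes(cov, truth_config(small_params(), seed = 2))
  expect_identical(attr(ok, "n_clipped"), 0L)
})

test_that("within-individual outcome persistence increases with sigma_alpha", {
  icc <- function(sig) {
    pan <- small_panel(1500, waves = 4L, seed = 31,
                       params = small_params(sigma_alpha = sig))
    ind <- matrix(pan$y > 1, ncol = 4, byrow = TRUE)
    mean(stats::cor(ind)[upper.tri(diag(4))])
  }
  r0 <- icc(0.5)
  r1 <- icc(2.0)
  expect_gt(r0, 0)
  expect_gt(r1, r0)
})
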