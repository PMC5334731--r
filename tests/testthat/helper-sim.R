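## Shared fixtures: a compact three-covariate world that keeps fits fast.

small_vars <- c("x1", "x2", "x3")

small_params <- function(eq1 = c(0.5, -0.4, 0.3), eq2 = c(0.5, -0.4, 0.3),
                         intercepts = c(0.8, -0.8), sigma_alpha = 1) {
  slopes <- rbind(eq1, eq2)
  colnames(slopes) <- small_vars
  gop_params(slopes, intercepts, sigma_alpha)
}

small_spec <- function(parallel_set = character(), random_effects = TRUE) {
  gop_spec(small_vars, J = 3L, parallel_set = parallel_set,
           random_effects = random_effects)
}

## covariates: one continuous, one binary, one ordinal score; static over waves
small_covariates <- function(n, waves = 3L, seed = 1) {
  withr::with_seed(seed, data.frame(
    id = rep(seq_len(n), each = waves),
    wave = rep(seq_len(waves), times = n),
    x1 = rep(stats::rnorm(n), each = waves),
    x2 = rep(stats::rbinom(n, 1, 0.5), each = waves),
    x3 = rep(sample(1:4, n, replace = TRUE), each = waves)
  ))
}

small_panel <- function(n, waves = 3L, seed = 1, params = small_params(),
                        clip_policy = "clip") {
  cov <- small_covariates(n, waves, seed)
  simulate_outcomes(cov, truth_config(params, seed = seed + 5000L,
                                      clip_policy = clip_policy))
}

## Independent dense-grid oracle for the marginal likelihood of one
## individual: composite Simpson rule over alpha in +/- 8 sigma.
dense_marginal_loglik <- function(y_i, X_i, params, n_grid = 4001L) {
  s <- params$sigma_alpha
  stopifnot(s > 0)
  a <- seq(-8 * s, 8 * s, length.out = n_grid)
  h <- a[2] - a[1]
  f <- vapply(a, function(al) {
    exp(conditional_panel_loglik(y_i, X_i, params, al)) *
      stats::dnorm(al, 0, s)
  }, numeric(1))
  stopifnot(n_grid %% 2L == 1L)
  wts <- c(1, rep(c(4, 2), length.out = n_grid - 2L), 1)
  log(sum(wts * f) * h / 3)
}

## Random single-individual instance for quadrature validation: moderate
## random-effect scale (the regime where fixed-node Gauss-Hermite is
## accurate; see the methods vignette), mildly non-parallel slopes, redrawn
## if the outcome sequence has zero likelihood (possible under crossing
## cumulative curves).
random_marginal_instance <- function() {
  repeat {
    base <- stats::rnorm(3, 0, 0.5)
    prm <- small_params(eq1 = base,
                        eq2 = base + stats::rnorm(3, 0, 0.15),
                        intercepts = sort(stats::rnorm(2), decreasing = TRUE),
                        sigma_alpha = stats::runif(1, 0.2, 0.9))
    Tw <- sample(1:4, 1)
    X <- matrix(stats::rnorm(3 * Tw), Tw, 3)
    y <- sample(1:3, Tw, replace = TRUE)
    oracle <- dense_marginal_loglik(y, X, prm)
    if (is.finite(oracle))
      return(list(params = prm, X = X, y = y, oracle = oracle))
  }
}

## Naive per-individual loop for the total log-likelihood.
naive_total_loglik <- function(data, params, spec, nodes = 15L) {
  quad <- gh_rule(nodes)
  s <- 0
  for (i in unique(data$id)) {
    d <- data[data$id == i, ]
    d <- d[order(d$wave), ]
    s <- s + marginal_loglik_individual(
      d$y, as.matrix(d[spec$covariate_names]), params, quad)
  }
  s
}
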