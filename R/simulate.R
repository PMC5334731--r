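#' Generate a covariate panel from covariate specifications
#'
#' Draws one value per individual for each non-time-varying covariate and
#' replicates it across waves; age advances one year per wave and derived
#' covariates (age squared) are recomputed per wave.  Deterministic given the
#' seed; the caller's RNG state is left untouched.
#'
#' @param spec list of [covariate_spec()] objects (see
#'   [default_hilda_spec()]).
#' @param n_individuals number of individuals (>= 1).
#' @param n_waves number of waves (>= 1).
#' @param seed integer RNG seed (required; no hidden global state).
#' @return long-format data frame with columns `id`, `wave`, then one column
#'   per covariate.
#' @export
generate_covariates <- function(spec, n_individuals, n_waves = 1L, seed) {
  n_individuals <- as.integer(n_individuals)
  n_waves <- as.integer(n_waves)
  if (n_individuals < 1L || n_waves < 1L)
    stop("n_individuals and n_waves must be >= 1")
  if (missing(seed)) stop("an explicit seed is required")
  if (!all(vapply(spec, inherits, logical(1), "covariate_spec")))
    stop("spec must be a list of covariate_spec objects")

  base <- withr::with_seed(as.integer(seed), {
    cols <- list()
    for (cs in spec) {
      if (cs$kind == "derived") next
      cols[[cs$name]] <- draw_covariate(cs, n_individuals)
    }
    cols
  })

  out <- data.frame(
    id = rep(seq_len(n_individuals), each = n_waves),
    wave = rep(seq_len(n_waves), times = n_individuals)
  )
  for (cs in spec) {
    if (cs$kind == "derived") {
      parent <- out[[cs$params$parent]]
      if (is.null(parent))
        stop("derived covariate '", cs$name, "': parent '",
             cs$params$parent, "' not generated yet")
      out[[cs$name]] <- parent^2
    } else {
      v <- rep(base[[cs$name]], each = n_waves)
      if (cs$time_varying) v <- v + (out$wave - 1L)  # ages one year per wave
      out[[cs$name]] <- v
    }
  }
  out
}

draw_covariate <- function(cs, n) {
  p <- cs$params
  switch(cs$kind,
    binary = stats::rbinom(n, 1L, p$p),
    categorical = sample(p$values, n, replace = TRUE, prob = p$freqs),
    continuous = switch(p$dist,
      normal = stats::rnorm(n, p$mean, p$sd),
      lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
      truncnorm = {
        lo <- stats::pnorm((p$lower - p$mu) / p$sigma)
        hi <- stats::pnorm((p$upper - p$mu) / p$sigma)
        p$mu + p$sigma * stats::qnorm(stats::runif(n, lo, hi))
      }),
    stop("cannot draw kind '", cs$kind, "'"))
}

#' Truth configuration for the outcome simulator
#'
#' Bundles the data-generating parameters with the seed and the policy for
#' invalid cumulative-probability pairs (a generalized model does not
#' guarantee `P(y <= 1) <= P(y <= 2)` at every covariate value).
#'
#' @param params a [gop_params()] object (the true values).
#' @param seed integer RNG seed.
#' @param clip_policy `"clip"` (default: raise the offending cumulative
#'   probability to restore monotonicity, counting occurrences), `"reject"`
#'   (drop every individual whose panel contains an invalid pair), or
#'   `"error"`.
#' @return list of class `"truth_config"`.
#' @export
truth_config <- function(params, seed, clip_policy = c("clip", "reject",
                                                       "error")) {
  stopifnot(inherits(params, "gop_params"))
  if (missing(seed)) stop("an explicit seed is required")
  list(params = params, seed = as.integer(seed),
       clip_policy = match.arg(clip_policy))
}

#' Simulate ordered outcomes on a covariate panel
#'
#' For each individual draws `alpha_i ~ N(0, sigma_alpha^2)` once, computes
#' the cumulative probabilities `P(y <= j | x, alpha)` of the generalized
#' ordered probit per wave, applies the clip policy to any non-monotone pair,
#' and draws the outcome from one uniform variate per wave.  Deterministic
#' given the seed.
#'
#' @param covariates covariate panel from [generate_covariates()] (columns
#'   `id`, `wave`, covariates).
#' @param truth a [truth_config()]; covariate columns must include every
#'   column name of `truth$params$slopes`.
#' @return the panel with an added outcome column `y`, plus attributes
#'   `n_clipped` (observations with an invalid pair) and `clip_fraction`.
#'   Under `clip_policy = "reject"` affected individuals are removed.
#' @export
simulate_outcomes <- function(covariates, truth) {
  params <- truth$params
  vars <- colnames(params$slopes)
  miss <- setdiff(vars, names(covariates))
  if (length(miss))
    stop("covariate panel lacks column(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(covariates[vars])
  N <- nrow(X)
  ids <- unique(covariates$id)
  Jm1 <- nrow(params$slopes)

  withr::with_seed(truth$seed, {
    alpha <- stats::rnorm(length(ids), 0, params$sigma_alpha)
    al <- alpha[match(covariates$id, ids)]
    ## P(y <= j) = 1 - Phi(c_j + x'b_j + alpha), must be non-decreasing in j
    Ple <- matrix(0, N, Jm1)
    for (j in seq_len(Jm1))
      Ple[, j] <- stats::pnorm(-(params$intercepts[j] +
                                   drop(X %*% params$slopes[j, ]) + al))
    bad <- rep(FALSE, N)
    if (Jm1 >= 2L)
      for (j in 2:Jm1) bad <- bad | (Ple[, j] < Ple[, j - 1L])
    if (any(bad) && truth$clip_policy == "error")
      stop("invalid cumulative probability pair for ", sum(bad),
           " observation(s)")
    if (Jm1 >= 2L)
      for (j in 2:Jm1) Ple[, j] <- pmax(Ple[, j], Ple[, j - 1L])
    u <- stats::runif(N)
    y <- 1L + rowSums(u > Ple)
    out <- covariates
    out$y <- as.integer(y)
    out <- out[c("id", "wave", "y", setdiff(names(covariates),
                                            c("id", "wave")))]
    if (truth$clip_policy == "reject" && any(bad)) {
      drop_ids <- unique(out$id[bad])
      out <- out[!(out$id %in% drop_ids), , drop = FALSE]
    }
    attr(out, "n_clipped") <- sum(bad)
    attr(out, "clip_fraction") <- mean(bad)
    out
  })
}

#' One-call synthetic panel: covariates plus model-consistent outcomes
#'
#' @param cov_spec list of [covariate_spec()]s (default the HILDA-like
#'   cohort).
#' @param truth_params a [gop_params()] truth (default [hilda_truth()]).
#' @param n_individuals,n_waves panel dimensions.
#' @param seed integer seed governing both covariates and outcomes.
#' @param clip_policy see [truth_config()].
#' @return panel data frame with `id`, `wave`, `y`, covariates.
#' @export
simulate_gop_panel <- function(n_individuals, n_waves, seed,
                               cov_spec = default_hilda_spec(),
                               truth_params = hilda_truth()$params,
                               clip_policy = "clip") {
  cov <- generate_covariates(cov_spec, n_individuals, n_waves, seed = seed)
  simulate_outcomes(cov, truth_config(truth_params, seed = seed + 1L,
                                      clip_policy = clip_policy))
}

#' Default calibration truth for the HILDA-like cohort
#'
#' The data-generating parameter values used by the package's validation and
#' parameter-recovery harness: a three-category random-effects generalized
#' ordered probit over the 18 covariates of [default_hilda_spec()],
#' calibrated to be representative of an Australian adult cohort.  Six
#' covariates (area, hhtype, alcohol, meals, agree, emote) obey the
#' parallel-lines restriction; the random-effect SD implies a persistence
#' ratio `rho` of 0.852.
#'
#' @return list with `params` (a [gop_params()]) and `spec` (a [gop_spec()]
#'   whose `parallel_set` holds the six parallel covariates).
#' @export
hilda_truth <- function() {
  vars <- c("gender", "age", "age2", "empstatus", "area", "hhtype", "losat",
            "lndinc_p", "alcohol", "meals", "educ", "advantage", "marstatus",
            "agree", "consc", "emote", "extrv", "opene")
  eq1 <- c(0.8837, 0.1905, -0.0016, -0.0203, 0.0790, 0.0447, 0.0537,
           0.1132, -5.34e-06, 1.32e-06, 0.1160, -0.0850, 0.3846,
           0.0920, -0.1555, -0.0572, 0.0623, -0.0939)
  eq2 <- c(0.0620, 0.1432, -0.0013, -0.1500, 0.0790, 0.0447, -0.1123,
           0.0173, -5.34e-06, 1.32e-06, 0.1682, -0.1096, 0.2161,
           0.0920, -0.1956, -0.0572, 0.0100, -0.0572)
  slopes <- rbind(eq1 = eq1, eq2 = eq2)
  colnames(slopes) <- vars
  rho <- 0.852
  sigma_alpha <- sqrt(rho / (1 - rho))
  list(
    params = gop_params(slopes, intercepts = c(-5.2483, -4.4469),
                        sigma_alpha = sigma_alpha),
    spec = gop_spec(vars, J = 3L,
                    parallel_set = c("area", "hhtype", "alcohol", "meals",
                                     "agree", "emote"),
                    random_effects = TRUE)
  )
}
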