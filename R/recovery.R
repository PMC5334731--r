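#' Parameter-recovery study on the calibrated synthetic cohort
#'
#' The package's validation harness: simulates panels from the default
#' HILDA-like covariate generator and the calibrated truth ([hilda_truth()]),
#' refits the random-effects generalized ordered probit by maximum marginal
#' likelihood, and averages the recovered free parameters over seeds.  With
#' the generator and estimator sharing the same model family, the averaged
#' estimates should recover the truth up to Monte-Carlo error.
#'
#' @param seeds integer vector of simulation seeds (one fit per seed).
#' @param n_individuals,n_waves panel dimensions per seed.
#' @param nodes Gauss-Hermite node count for the fits.
#' @param truth optional list with `params`/`spec` as from [hilda_truth()].
#' @param generalized logical; fit the fully generalized model (default) or
#'   the truth's restricted pattern.
#' @param covariance compute per-fit covariances? (Not needed for recovery
#'   itself; default off for speed.)
#' @return list with `fits` (per-seed `"gop_fit"`s), `estimates` (averaged
#'   [gop_params()]), `rho` (averaged), `sigma_alpha` (averaged), and
#'   `converged` (all fits converged?).
#' @export
recovery_study <- function(seeds = 1:3, n_individuals = 3000L, n_waves = 5L,
                           nodes = 15L, truth = hilda_truth(),
                           generalized = TRUE, covariance = FALSE) {
  spec <- truth$spec
  if (generalized)
    spec <- gop_spec(spec$covariate_names, J = spec$J,
                     parallel_set = character(),
                     random_effects = spec$random_effects)
  opts <- fit_options(nodes = nodes,
                      covariance = if (covariance) "observed" else "none")
  fits <- lapply(seeds, function(s) {
    panel <- simulate_gop_panel(n_individuals, n_waves, seed = s,
                                truth_params = truth$params)
    fit_mle(panel, spec, options = opts)
  })
  slopes <- Reduce(`+`, lapply(fits, function(f) f$estimates$slopes)) /
    length(fits)
  ints <- Reduce(`+`, lapply(fits, function(f) f$estimates$intercepts)) /
    length(fits)
  sig <- mean(vapply(fits, function(f) f$estimates$sigma_alpha, numeric(1)))
  rho <- mean(vapply(fits, function(f) f$rho, numeric(1)))
  list(fits = fits,
       estimates = gop_params(slopes, ints, sig),
       rho = rho, sigma_alpha = sig,
       converged = all(vapply(fits, function(f) f$converged, logical(1))))
}
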