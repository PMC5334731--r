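#' Model specification for a (generalized) ordered probit panel model
#'
#' A `gop_spec` records the structure of the model: the number of ordered
#' outcome categories `J`, the covariate names entering the latent index, the
#' subset of covariates constrained to obey the parallel-lines assumption (one
#' coefficient shared across all `J - 1` cumulative equations), and whether a
#' shared individual random effect is included.
#'
#' The model has `J - 1` cumulative ("greater-than") equations.  Equation `j`
#' models `P(y > j | x, alpha) = Phi(c_j + x' beta_j + alpha)`, where `beta_j`
#' may differ across equations except for covariates in `parallel_set`, which
#' carry a single coefficient common to every equation.  When every covariate
#' is in `parallel_set` the model collapses to the standard ordered probit.
#'
#' @param covariate_names character vector of covariate labels (columns of the
#'   panel data used in the latent index).
#' @param J number of ordered categories (default 3: normal, overweight,
#'   obese).  `J = 2` degenerates to a binary probit and is permitted.
#' @param parallel_set subset of `covariate_names` whose coefficients are
#'   constrained equal across equations.  Default: none (fully generalized).
#' @param random_effects logical; include a shared normal individual effect
#'   `alpha_i` with standard deviation `sigma_alpha`?
#' @return an object of class `"gop_spec"`.
#' @seealso [gop_params()], [fit_mle()]
#' @export
gop_spec <- function(covariate_names, J = 3L, parallel_set = character(),
                     random_effects = TRUE) {
  covariate_names <- as.character(covariate_names)
  J <- as.integer(J)
  if (J < 2L) stop("J must be at least 2")
  if (anyDuplicated(covariate_names))
    stop("duplicated covariate names")
  parallel_set <- as.character(parallel_set)
  if (!all(parallel_set %in% covariate_names))
    stop("parallel_set must be a subset of covariate_names")
  structure(
    list(J = J, covariate_names = covariate_names,
         parallel_set = parallel_set,
         random_effects = isTRUE(random_effects)),
    class = "gop_spec"
  )
}

#' @export
print.gop_spec <- function(x, ...) {
  cat("Generalized ordered probit specification\n")
  cat("  categories (J):", x$J, "\n")
  cat("  covariates (", length(x$covariate_names), "): ",
      paste(x$covariate_names, collapse = ", "), "\n", sep = "")
  cat("  parallel-lines set:",
      if (length(x$parallel_set)) paste(x$parallel_set, collapse = ", ")
      else "(none)", "\n")
  cat("  random effects:", x$random_effects, "\n")
  invisible(x)
}

#' Parameter container for the generalized ordered probit
#'
#' Holds one slope vector per cumulative equation, the equation intercepts
#' `c_j` (defined by `P(y > j | x, alpha) = Phi(c_j + x' beta_j + alpha)`),
#' and the random-effect standard deviation `sigma_alpha`.  The idiosyncratic
#' error variance is fixed at 1 for probit identification.
#'
#' @param slopes numeric matrix of dimension `(J - 1) x K`; row `j` is the
#'   slope vector of cumulative equation `j`.  Column names are the covariate
#'   names.
#' @param intercepts numeric vector of length `J - 1`; the `c_j`.
#' @param sigma_alpha non-negative scalar, SD of the individual effect.
#' @return an object of class `"gop_params"`.
#' @export
gop_params <- function(slopes, intercepts, sigma_alpha = 0) {
  slopes <- as.matrix(slopes)
  storage.mode(slopes) <- "double"
  intercepts <- as.numeric(intercepts)
  if (nrow(slopes) != length(intercepts))
    stop("nrow(slopes) must equal length(intercepts) (= J - 1)")
  if (!is.numeric(sigma_alpha) || length(sigma_alpha) != 1L || sigma_alpha < 0)
    stop("sigma_alpha must be a non-negative scalar")
  if (is.null(colnames(slopes)))
    colnames(slopes) <- paste0("x", seq_len(ncol(slopes)))
  rownames(slopes) <- paste0("eq", seq_len(nrow(slopes)))
  structure(
    list(slopes = slopes, intercepts = intercepts,
         sigma_alpha = as.numeric(sigma_alpha)),
    class = "gop_params"
  )
}

#' @export
print.gop_params <- function(x, ...) {
  cat("Generalized ordered probit parameters (J =", nrow(x$slopes) + 1L, ")\n")
  tab <- rbind(t(x$slopes), constant = x$intercepts)
  print(round(tab, 4))
  cat("sigma_alpha =", format(x$sigma_alpha, digits = 4),
      " (rho =", format(compute_rho(x$sigma_alpha), digits = 4), ")\n")
  invisible(x)
}

n_equations <- function(spec) spec$J - 1L

## Free-parameter map: covariates in parallel_set occupy ONE free slot shared
## by all equations; the rest get one slot per equation.  Intercepts follow,
## then log(sigma_alpha) if random effects are on.  The map underpins packing,
## gradients, covariance and Wald constraint construction.
par_map <- function(spec) {
  K <- length(spec$covariate_names)
  Jm1 <- n_equations(spec)
  slope_index <- matrix(0L, Jm1, K,
                        dimnames = list(paste0("eq", seq_len(Jm1)),
                                        spec$covariate_names))
  labels <- character(0)
  slot <- 0L
  for (k in seq_len(K)) {
    vn <- spec$covariate_names[k]
    if (vn %in% spec$parallel_set) {
      slot <- slot + 1L
      slope_index[, k] <- slot
      labels[slot] <- vn
    } else {
      for (j in seq_len(Jm1)) {
        slot <- slot + 1L
        slope_index[j, k] <- slot
        labels[slot] <- paste0("eq", j, ":", vn)
      }
    }
  }
  int_index <- slot + seq_len(Jm1)
  labels[int_index] <- paste0("eq", seq_len(Jm1), ":constant")
  slot <- slot + Jm1
  sig_index <- NA_integer_
  if (spec$random_effects) {
    slot <- slot + 1L
    sig_index <- slot
    labels[sig_index] <- "log_sigma_alpha"
  }
  list(n_free = slot, slope_index = slope_index, int_index = int_index,
       sig_index = sig_index, labels = labels,
       n_slopes = slot - Jm1 - as.integer(spec$random_effects))
}

## params -> free theta (log scale for sigma_alpha)
pack_params <- function(params, spec, map = par_map(spec)) {
  theta <- numeric(map$n_free)
  Jm1 <- n_equations(spec)
  for (k in seq_along(spec$covariate_names))
    for (j in seq_len(Jm1))
      theta[map$slope_index[j, k]] <- params$slopes[j, k]
  theta[map$int_index] <- params$intercepts
  if (spec$random_effects)
    theta[map$sig_index] <- log(max(params$sigma_alpha, 1e-8))
  names(theta) <- map$labels
  theta
}

## free theta -> params
unpack_params <- function(theta, spec, map = par_map(spec)) {
  Jm1 <- n_equations(spec)
  K <- length(spec$covariate_names)
  slopes <- matrix(theta[map$slope_index], Jm1, K,
                   dimnames = list(paste0("eq", seq_len(Jm1)),
                                   spec$covariate_names))
  sigma <- if (spec$random_effects) exp(theta[map$sig_index]) else 0
  gop_params(slopes, theta[map$int_index], sigma)
}
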