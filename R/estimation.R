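#' Options controlling maximum marginal likelihood estimation
#'
#' @param nodes Gauss-Hermite node count for the random-effect integral.
#' @param grad_tol convergence threshold on the max-norm of the score at the
#'   optimum; the fit is declared converged when the optimizer terminates
#'   normally and the score max-norm is below this value.
#' @param reltol relative log-likelihood change tolerance passed to the
#'   quasi-Newton optimizer.
#' @param maxit maximum optimizer iterations.
#' @param start starting-value strategy: `"ordered-probit"` fits the fully
#'   parallel pooled ordered probit and replicates its slopes into every
#'   equation (sigma_alpha started at 1); `"zero"` starts slopes at zero with
#'   intercepts from the empirical category frequencies.
#' @param covariance `"observed"` (inverse observed information from a
#'   numerical Hessian of the analytic score) or `"none"`.
#' @return list of class `"gop_options"`.
#' @export
fit_options <- function(nodes = 15L, grad_tol = 1e-3, reltol = 1e-10,
                        maxit = 1000L,
                        start = c("ordered-probit", "zero"),
                        covariance = c("observed", "none")) {
  if (nodes < 2L) stop("nodes must be >= 2")
  if (grad_tol <= 0 || reltol <= 0) stop("tolerances must be positive")
  list(nodes = as.integer(nodes), grad_tol = grad_tol, reltol = reltol,
       maxit = as.integer(maxit), start = match.arg(start),
       covariance = match.arg(covariance))
}

#' Persistence ratio of the random-effects probit
#'
#' `rho = sigma_alpha^2 / (sigma_alpha^2 + 1)` with the idiosyncratic probit
#' variance fixed at 1: the share of latent variance due to the individual
#' effect, and the latent intra-individual correlation across waves.
#'
#' @param sigma_alpha non-negative random-effect SD.
#' @return value in `[0, 1)`.
#' @export
compute_rho <- function(sigma_alpha) {
  stopifnot(sigma_alpha >= 0)
  sigma_alpha^2 / (sigma_alpha^2 + 1)
}

## Intercept starting values from empirical cumulative frequencies:
## c_j = qnorm(P(y > j)), which is decreasing in j.
start_intercepts <- function(y, J) {
  pgt <- vapply(seq_len(J - 1L), function(j) mean(y > j), numeric(1))
  pgt <- pmin(pmax(pgt, 1e-4), 1 - 1e-4)
  stats::qnorm(pgt)
}

#' Starting values for the generalized random-effects fit
#'
#' Fits the fully parallel pooled ordered probit (no random effect) by its
#' exact likelihood and replicates the resulting slope vector into every
#' cumulative equation; `sigma_alpha` is initialized at 1.
#'
#' @param data panel data frame.
#' @param spec a [gop_spec()].
#' @param options a [fit_options()] list.
#' @return a [gop_params()] object satisfying the constraints of `spec`.
#' @export
starting_values <- function(data, spec, options = fit_options()) {
  validate_panel(data, spec)
  tab <- table(factor(data$y, levels = seq_len(spec$J)))
  if (any(tab == 0))
    stop("degenerate outcome distribution: category ",
         paste(which(tab == 0), collapse = ", "), " absent")
  pooled_spec <- gop_spec(spec$covariate_names, J = spec$J,
                          parallel_set = spec$covariate_names,
                          random_effects = FALSE)
  pooled <- fit_mle(data, pooled_spec,
                    options = fit_options(nodes = options$nodes,
                                          grad_tol = options$grad_tol,
                                          start = "zero",
                                          covariance = "none"))
  slopes <- matrix(rep(pooled$estimates$slopes[1L, ], each = spec$J - 1L),
                   spec$J - 1L, length(spec$covariate_names),
                   dimnames = dimnames(pooled$estimates$slopes))
  gop_params(slopes, pooled$estimates$intercepts,
             sigma_alpha = if (spec$random_effects) 1 else 0)
}

#' Fit the random-effects generalized ordered probit by maximum marginal
#' likelihood
#'
#' Maximizes the Gauss-Hermite marginal log-likelihood over the free
#' parameters implied by `spec` (covariates in the parallel set occupy a
#' single shared slot across equations; `sigma_alpha` is profiled on the log
#' scale) using BFGS with the analytic score.  Non-convergence is reported,
#' never silently ignored.
#'
#' @param data panel data frame (long format, see [validate_panel()]).
#' @param spec a [gop_spec()].
#' @param options a [fit_options()] list.
#' @param start optional [gop_params()] starting values (overrides the
#'   strategy in `options`).
#' @return an object of class `"gop_fit"`: estimates ([gop_params()]),
#'   free-parameter vector and covariance with labels, log-likelihood, `rho`
#'   (with a delta-method standard error when the covariance is computed),
#'   convergence information, and the data dimensions.
#' @export
fit_mle <- function(data, spec, options = fit_options(), start = NULL) {
  mf <- model_frame(data, spec)
  map <- par_map(spec)
  gh <- gh_rule(options$nodes)

  ## Internal standardization: the optimizer works on centered, unit-SD
  ## covariates (the raw design mixes scales across four orders of
  ## magnitude, which cripples quasi-Newton conditioning); estimates and
  ## covariance are mapped back exactly afterwards.
  center <- colMeans(mf$X)
  scale <- apply(mf$X, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  mf_s <- mf
  mf_s$X <- sweep(sweep(mf$X, 2, center, "-"), 2, scale, "/")

  if (is.null(start)) {
    if (options$start == "ordered-probit" &&
        !(length(spec$parallel_set) == length(spec$covariate_names) &&
          !spec$random_effects)) {
      start <- starting_values(data, spec, options)
    } else {
      K <- length(spec$covariate_names)
      start <- gop_params(
        matrix(0, spec$J - 1L, K,
               dimnames = list(NULL, spec$covariate_names)),
        start_intercepts(mf$y, spec$J),
        sigma_alpha = if (spec$random_effects) 1 else 0)
    }
  }
  start_s <- rescale_params(start, center, scale, to_scaled = TRUE)
  theta0 <- pack_params(start_s, spec, map)

  negll <- function(th) {
    e <- gop_engine(th, spec, mf_s, gh, want_grad = FALSE)
    if (!is.finite(e$loglik)) return(1e12)
    -e$loglik
  }
  neggr <- function(th) {
    e <- gop_engine(th, spec, mf_s, gh, want_grad = TRUE)
    if (!all(is.finite(e$grad))) return(rep(0, length(th)))
    -e$grad
  }

  gtol <- function(ll) options$grad_tol * max(1, abs(ll) / mf$n_ind)
  opt <- stats::optim(theta0, negll, neggr, method = "BFGS",
                      control = list(maxit = options$maxit,
                                     reltol = options$reltol))
  theta_s <- opt$par
  final <- gop_engine(theta_s, spec, mf_s, gh, want_grad = TRUE)

  ## Newton polish on the observed information: BFGS with a relative
  ## log-likelihood stop leaves a small residual score at large n; a few
  ## damped Newton steps (reusing the Hessian needed for the covariance)
  ## drive the score norm to the tolerance.
  info <- NULL
  if (opt$convergence == 0L && max(abs(final$grad)) >= gtol(final$loglik)) {
    info <- free_information(theta_s, spec, mf_s, gh)
    ok <- !inherits(try(chol(info), silent = TRUE), "try-error")
    if (ok) {
      for (it in 1:10) {
        if (max(abs(final$grad)) < gtol(final$loglik)) break
        step <- solve(info, final$grad)
        lam <- 1
        repeat {
          cand <- theta_s + lam * step
          e2 <- gop_engine(cand, spec, mf_s, gh, want_grad = TRUE)
          if (is.finite(e2$loglik) && e2$loglik >= final$loglik - 1e-10)
            break
          lam <- lam / 2
          if (lam < 1e-4) break
        }
        if (lam < 1e-4) break
        moved <- max(abs(cand - theta_s))
        theta_s <- cand
        final <- e2
        if (moved < 1e-12) break
      }
      info <- NULL                       # recompute at the polished optimum
    }
  }
  gnorm <- max(abs(final$grad))
  converged <- opt$convergence == 0L && is.finite(gnorm) &&
    gnorm < gtol(final$loglik)

  est <- rescale_params(unpack_params(theta_s, spec, map), center, scale,
                        to_scaled = FALSE)
  theta <- pack_params(est, spec, map)
  boundary <- spec$random_effects && est$sigma_alpha < 1e-4

  vc <- NULL
  se <- rep(NA_real_, map$n_free)
  if (options$covariance == "observed") {
    vc_s <- observed_covariance(theta_s, spec, mf_s, gh, map, info = info)
    Tm <- rescale_jacobian(spec, map, center, scale)
    vc <- Tm %*% vc_s %*% t(Tm)
    dimnames(vc) <- list(map$labels, map$labels)
    se <- sqrt(pmax(diag(vc), 0))
  }
  ## delta method for rho = s^2/(1 + s^2): d rho / d s = 2 s / (1 + s^2)^2
  rho_se <- if (!is.null(vc) && spec$random_effects) {
    s <- est$sigma_alpha
    unname(se[map$sig_index]) * 2 * s / (1 + s^2)^2
  } else NA_real_

  structure(list(
    spec = spec, estimates = est, theta = theta, map = map,
    covariance = vc, se = stats::setNames(se, map$labels),
    loglik = final$loglik, rho = compute_rho(est$sigma_alpha),
    rho_se = rho_se,
    converged = converged, boundary = boundary,
    grad_norm = gnorm, optim_convergence = opt$convergence,
    counts = opt$counts, n_obs = mf$n_obs, n_individuals = mf$n_ind,
    nodes = options$nodes
  ), class = "gop_fit")
}

## Map parameters between the raw covariate scale and the standardized
## (centered, unit-SD) scale used by the optimizer.  An exact linear
## reparameterization: beta_s = beta * scale, c_s = c + sum(center * beta).
rescale_params <- function(params, center, scale, to_scaled) {
  slopes <- params$slopes
  if (to_scaled) {
    slopes_new <- sweep(slopes, 2, scale, "*")
    ints_new <- params$intercepts + drop(slopes %*% center)
  } else {
    slopes_new <- sweep(slopes, 2, scale, "/")
    ints_new <- params$intercepts - drop(slopes_new %*% center)
  }
  gop_params(slopes_new, ints_new, params$sigma_alpha)
}

## Jacobian of the raw free-parameter vector (natural sigma scale) with
## respect to the standardized one; used to transform the covariance.
rescale_jacobian <- function(spec, map, center, scale) {
  Tm <- diag(map$n_free)
  Jm1 <- n_equations(spec)
  for (k in seq_along(spec$covariate_names)) {
    for (j in seq_len(Jm1)) {
      slot <- map$slope_index[j, k]
      Tm[slot, slot] <- 1 / scale[k]
      Tm[map$int_index[j], slot] <- Tm[map$int_index[j], slot] -
        center[k] / scale[k]
    }
  }
  Tm
}

## Observed information on the free-parameter scale: central-difference
## Hessian of the analytic score (symmetrized).
free_information <- function(theta, spec, mf, gh) {
  p <- length(theta)
  H <- matrix(0, p, p)
  h <- 1e-4 * pmax(abs(theta), 1)
  for (k in seq_len(p)) {
    tp <- tm <- theta
    tp[k] <- tp[k] + h[k]
    tm[k] <- tm[k] - h[k]
    gp <- gop_engine(tp, spec, mf, gh, want_grad = TRUE)$grad
    gm <- gop_engine(tm, spec, mf, gh, want_grad = TRUE)$grad
    H[, k] <- (gp - gm) / (2 * h[k])
  }
  -(H + t(H)) / 2
}

## Inverse observed information; the log(sigma_alpha) slot is mapped back to
## the natural sigma_alpha scale by the delta method.
observed_covariance <- function(theta, spec, mf, gh, map, info = NULL) {
  p <- length(theta)
  H <- info %||% free_information(theta, spec, mf, gh)
  V <- tryCatch(solve(H), error = function(e) {
    ev <- eigen(H, symmetric = TRUE)
    flat <- ev$vectors[, which.min(abs(ev$values)), drop = TRUE]
    stop("observed information is singular; flattest direction loads on: ",
         paste(map$labels[order(-abs(flat))[1:3]], collapse = ", "))
  })
  if (spec$random_effects) {
    s <- map$sig_index
    sigma <- exp(theta[s])
    J <- rep(1, p); J[s] <- sigma           # d sigma / d log sigma = sigma
    V <- V * tcrossprod(J)
  }
  dimnames(V) <- list(map$labels, map$labels)
  V
}

#' Standard (fully parallel) ordered probit fit
#'
#' The most restrictive nested special case: every covariate in the parallel
#' set, a single slope vector, fixed thresholds.  With `random_effects =
#' FALSE` this is the pooled ordered probit.
#'
#' @inheritParams fit_mle
#' @param covariate_names covariates to include; defaults to every column of
#'   `data` other than `id`, `wave`, `y`.
#' @param J number of categories.
#' @param random_effects include the individual random effect?
#' @return a `"gop_fit"` object.
#' @export
fit_standard_ordered_probit <- function(data, covariate_names = NULL, J = 3L,
                                        random_effects = FALSE,
                                        options = fit_options()) {
  if (is.null(covariate_names))
    covariate_names <- setdiff(names(data), c("id", "wave", "y"))
  spec <- gop_spec(covariate_names, J = J, parallel_set = covariate_names,
                   random_effects = random_effects)
  fit_mle(data, spec, options = options)
}

#' @export
print.gop_fit <- function(x, ...) {
  cat("Random-effects generalized ordered probit fit\n")
  cat("  N obs =", x$n_obs, " individuals =", x$n_individuals,
      " nodes =", x$nodes, "\n")
  cat("  log-likelihood = ", format(x$loglik, digits = 8),
      ", converged = ", x$converged,
      " (score max-norm ", format(x$grad_norm, digits = 3), ")\n", sep = "")
  cat("  sigma_alpha =", format(x$estimates$sigma_alpha, digits = 4),
      " rho =", format(x$rho, digits = 4),
      if (x$boundary) " [boundary]" else "", "\n")
  invisible(x)
}

#' @export
coef.gop_fit <- function(object, ...) {
  stats::setNames(object$theta, object$map$labels)
}

#' @export
vcov.gop_fit <- function(object, ...) object$covariance

#' @export
logLik.gop_fit <- function(object, ...) {
  structure(object$loglik, df = object$map$n_free, class = "logLik")
}

## Free-parameter vector on the natural (reporting) scale: sigma_alpha
## instead of its log.  Wald machinery operates on this scale, matching the
## covariance returned by observed_covariance().
natural_theta <- function(fit) {
  th <- fit$theta
  if (fit$spec$random_effects)
    th[fit$map$sig_index] <- exp(th[fit$map$sig_index])
  stats::setNames(th, fit$map$labels)
}

## Free slot of (equation j, covariate name); shared covariates map every
## equation to the same slot.
free_slot <- function(fit, j, variable) {
  k <- match(variable, fit$spec$covariate_names)
  if (is.na(k)) stop("unknown covariate: ", variable)
  fit$map$slope_index[j, k]
}
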