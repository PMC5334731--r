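#' Wald test of linear restrictions on a fitted model
#'
#' Computes the Wald statistic `(R theta - r)' (R V R')^{-1} (R theta - r)`
#' on the fit's free-parameter vector (natural scale) and covariance, with
#' `df = nrow(R)` and an upper-tail chi-squared p-value.  A restriction that
#' is satisfied exactly (for instance on a parameter pair already shared by
#' construction) returns statistic 0 and p-value 1 without requiring
#' `R V R'` to be invertible.
#'
#' @param fit a converged `"gop_fit"` with a covariance matrix.
#' @param R constraint matrix, one row per restriction, columns in the order
#'   of `coef(fit)`.
#' @param r right-hand-side constants (default zero).
#' @param description optional character vector describing each restriction.
#' @return object of class `"gop_wald"`: `statistic`, `df`, `p_value`,
#'   `restrictions`.
#' @export
wald_linear <- function(fit, R, r = rep(0, nrow(R)), description = NULL) {
  if (is.null(fit$covariance))
    stop("fit has no covariance matrix (refit with covariance = 'observed')")
  R <- rbind(R)
  if (nrow(R) == 0L) stop("no constraints supplied")
  if (ncol(R) != fit$map$n_free)
    stop("R must have ", fit$map$n_free, " columns")
  theta <- natural_theta(fit)
  d <- drop(R %*% theta) - r
  df <- nrow(R)
  if (all(abs(d) < 1e-12)) {
    stat <- 0
  } else {
    if (qr(R)$rank < nrow(R)) stop("constraint rows are linearly dependent")
    M <- R %*% fit$covariance %*% t(R)
    Mi <- tryCatch(solve(M, d), error = function(e)
      stop("singular R V R': redundant constraints"))
    stat <- drop(crossprod(d, Mi))
  }
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 restrictions = description %||%
                   paste0("R[", seq_len(df), "] theta = r")),
            class = "gop_wald")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gop_wald <- function(x, ...) {
  cat("Wald chi2(", x$df, ") = ", format(x$statistic, digits = 4),
      ",  Pr > chi2 = ", format(x$p_value, digits = 4), "\n", sep = "")
  for (d in x$restrictions) cat("  H0:", d, "\n")
  invisible(x)
}

#' Wald test that one covariate obeys the parallel-lines restriction
#'
#' Tests equality of the covariate's coefficient across all cumulative
#' equations (`J - 2` constraints; one for `J = 3`).
#'
#' @param fit a `"gop_fit"`.
#' @param variable covariate name, currently unrestricted in the fit.
#' @return a `"gop_wald"` object.
#' @export
wald_variable_equality <- function(fit, variable) {
  if (variable %in% fit$spec$parallel_set)
    stop("variable '", variable, "' is already constrained parallel")
  Jm1 <- n_equations(fit$spec)
  if (Jm1 < 2L) stop("parallel-lines tests need J >= 3")
  R <- matrix(0, Jm1 - 1L, fit$map$n_free)
  desc <- character(Jm1 - 1L)
  for (j in seq_len(Jm1 - 1L)) {
    R[j, free_slot(fit, j, variable)] <- 1
    R[j, free_slot(fit, j + 1L, variable)] <- -1
    desc[j] <- paste0("eq", j, " ", variable, " - eq", j + 1L, " ",
                      variable, " = 0")
  }
  wald_linear(fit, R, description = desc)
}

#' Joint Wald test of the parallel-lines restriction for several covariates
#'
#' Stacks the per-variable equality constraints; for `J = 3` the degrees of
#' freedom equal the number of variables tested.
#'
#' @param fit a `"gop_fit"`.
#' @param variables non-empty character vector of unrestricted covariates.
#' @return a `"gop_wald"` object.
#' @export
wald_joint_parallel <- function(fit, variables) {
  if (length(variables) == 0L) stop("no variables supplied")
  Jm1 <- n_equations(fit$spec)
  rows <- list(); desc <- character(0)
  for (v in variables) {
    if (v %in% fit$spec$parallel_set)
      stop("variable '", v, "' is already constrained parallel")
    for (j in seq_len(Jm1 - 1L)) {
      rr <- numeric(fit$map$n_free)
      rr[free_slot(fit, j, v)] <- 1
      rr[free_slot(fit, j + 1L, v)] <- -1
      rows[[length(rows) + 1L]] <- rr
      desc <- c(desc, paste0("eq", j, " ", v, " - eq", j + 1L, " ", v, " = 0"))
    }
  }
  wald_linear(fit, do.call(rbind, rows), description = desc)
}

#' Overall model Wald test: all slope coefficients zero
#'
#' Jointly restricts every free slope parameter to zero, leaving intercepts
#' and the random-effect SD unrestricted.  Degrees of freedom equal the
#' number of free slope slots (shared parameters count once).
#'
#' @param fit a `"gop_fit"`.
#' @return a `"gop_wald"` object.
#' @export
wald_slopes_zero <- function(fit) {
  slots <- sort(unique(as.integer(fit$map$slope_index)))
  R <- matrix(0, length(slots), fit$map$n_free)
  R[cbind(seq_along(slots), slots)] <- 1
  wald_linear(fit, R,
              description = paste0("all ", length(slots),
                                   " free slope parameters = 0"))
}

#' Sequential test-down of the parallel-lines restrictions
#'
#' Starting from the model implied by `spec` (typically fully generalized),
#' repeatedly: fit; compute the per-variable parallel-lines Wald test for
#' every unrestricted covariate; if the largest p-value exceeds `alpha_stop`,
#' constrain that covariate to a single shared coefficient and refit.  The
#' loop stops when every remaining relaxation is significant at `alpha_stop`
#' (or everything is restricted).  Ties in p-value are broken by covariate
#' order in `spec`.  No multiplicity correction is applied across the
#' sequence of tests.
#'
#' @param data panel data frame.
#' @param spec a [gop_spec()]; its `parallel_set` seeds the restricted set.
#' @param options a [fit_options()] list.
#' @param alpha_stop stopping threshold on the per-variable Wald p-value.
#' @return list with `fit` (the final restricted `"gop_fit"`) and `trace`
#'   (class `"gop_testdown"`): one step per round recording the current
#'   restricted set, all per-variable p-values, the variable restricted, and
#'   the stopping reason.
#' @export
sequential_test_down <- function(data, spec, options = fit_options(),
                                 alpha_stop = 0.05) {
  restricted <- spec$parallel_set
  steps <- list()
  fit <- NULL
  repeat {
    cur <- gop_spec(spec$covariate_names, J = spec$J,
                    parallel_set = restricted,
                    random_effects = spec$random_effects)
    fit <- fit_mle(data, cur, options = options)
    free_vars <- setdiff(spec$covariate_names, restricted)
    if (!fit$converged) {
      steps[[length(steps) + 1L]] <- list(
        parallel_set = restricted, p_values = NULL,
        restricted_variable = NA_character_, loglik = fit$loglik,
        reason = "non-convergent fit")
      warning("test-down aborted: intermediate fit did not converge")
      break
    }
    if (length(free_vars) == 0L) {
      steps[[length(steps) + 1L]] <- list(
        parallel_set = restricted, p_values = numeric(0),
        restricted_variable = NA_character_, loglik = fit$loglik,
        reason = "all variables restricted")
      break
    }
    pv <- vapply(free_vars,
                 function(v) wald_variable_equality(fit, v)$p_value,
                 numeric(1))
    if (max(pv) > alpha_stop) {
      pick <- free_vars[which.max(pv)]     # which.max: first of tied maxima
      steps[[length(steps) + 1L]] <- list(
        parallel_set = restricted, p_values = pv,
        restricted_variable = pick, loglik = fit$loglik,
        reason = sprintf("max p = %.4g > %.3g, restricting '%s'",
                         max(pv), alpha_stop, pick))
      restricted <- c(restricted, pick)
    } else {
      steps[[length(steps) + 1L]] <- list(
        parallel_set = restricted, p_values = pv,
        restricted_variable = NA_character_, loglik = fit$loglik,
        reason = sprintf("all p <= %.3g, stop", alpha_stop))
      break
    }
  }
  trace <- structure(list(steps = steps, alpha_stop = alpha_stop,
                          note = paste("p-values are unadjusted for the",
                                       "sequential multiplicity of tests")),
                     class = "gop_testdown")
  list(fit = fit, trace = trace)
}

#' @export
print.gop_testdown <- function(x, ...) {
  cat("Sequential parallel-lines test-down (alpha =", x$alpha_stop, ")\n")
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf("round %d: restricted = {%s}\n", i,
                paste(s$parallel_set, collapse = ", ")))
    if (length(s$p_values))
      cat("  p:", paste(sprintf("%s=%.3g", names(s$p_values), s$p_values),
                        collapse = ", "), "\n")
    cat(" ", s$reason, "\n")
  }
  cat("note:", x$note, "\n")
  invisible(x)
}
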