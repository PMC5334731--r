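## Probability model: generalized ordered probit with a shared individual
## random effect.  Cumulative equations are parameterized on the
## "greater-than" scale,
##     P(y > j | x, alpha) = Phi(c_j + x' beta_j + alpha),   j = 1..J-1,
## so positive slopes raise the probability of the heavier categories and the
## printed sign of a coefficient matches its direction of effect.  The
## category probabilities are first differences of the cumulative ones; with
## non-parallel slopes an interior difference can be negative at some x, which
## is flagged rather than hidden (see validity_diagnostic).

#' Gauss-Hermite quadrature rule for a normal mixing distribution
#'
#' Returns nodes and probability weights such that
#' `E[g(alpha)] ~ sum w_q g(sqrt(2) * sigma * x_q)` for
#' `alpha ~ N(0, sigma^2)`.  Weights sum to 1.
#'
#' @param nodes number of quadrature nodes (>= 2 for a non-degenerate rule).
#' @return list with components `x` (Hermite nodes) and `w` (probability
#'   weights).
#' @export
gh_rule <- function(nodes) {
  nodes <- as.integer(nodes)
  if (nodes < 1L) stop("need at least one quadrature node")
  g <- pracma::gaussHermite(nodes)
  list(x = g$x, w = g$w / sqrt(pi))
}

#' Linear index of one cumulative equation
#'
#' Computes `c_j + x' beta_j`, the systematic part of cumulative equation `j`
#' (excluding the random effect).
#'
#' @param x numeric covariate vector of length `K`.
#' @param params a [gop_params()] object.
#' @param j equation index in `1..(J-1)`.
#' @return scalar linear index.
#' @export
linear_index <- function(x, params, j) {
  j <- as.integer(j)
  if (j < 1L || j > nrow(params$slopes)) stop("equation index out of range")
  if (length(x) != ncol(params$slopes))
    stop("covariate vector has length ", length(x), ", expected ",
         ncol(params$slopes))
  params$intercepts[j] + sum(x * params$slopes[j, ])
}

#' Category probabilities at one observation
#'
#' Evaluates the `J` category probabilities at covariate vector `x` and
#' individual effect `alpha`:
#' `p_1 = 1 - Phi(c_1 + x'b_1 + alpha)`, `p_J = Phi(c_{J-1} + x'b_{J-1} +
#' alpha)`, interior `p_j` as differences of consecutive cumulative
#' probabilities.  A negative interior difference (possible when the
#' parallel-lines restriction is relaxed) is truncated to zero with
#' renormalization and the `valid` flag set to `FALSE`.
#'
#' @param x covariate vector.
#' @param params a [gop_params()] object.
#' @param alpha individual effect value (default 0).
#' @return list with `p` (length-`J` probability vector summing to 1) and
#'   `valid` (`FALSE` if any raw interior probability was negative).
#' @export
category_probabilities <- function(x, params, alpha = 0) {
  Jm1 <- nrow(params$slopes)
  z <- params$intercepts + drop(params$slopes %*% x) + alpha
  S <- c(1, stats::pnorm(z), 0)            # S_j = P(y > j), j = 0..J
  p <- S[-length(S)] - S[-1]
  valid <- TRUE
  if (any(p < 0)) {
    valid <- FALSE
    p <- pmax(p, 0)
    p <- p / sum(p)
  }
  names(p) <- paste0("p", seq_along(p))
  list(p = p, valid = valid)
}

#' Conditional panel log-likelihood for one individual
#'
#' Log-likelihood of an individual's outcome sequence given the random effect
#' `alpha`: the sum over waves of `log p_{y_t}(x_t, params, alpha)`.  Raw
#' probability differences are used; a non-positive probability for an
#' observed outcome yields `-Inf` (not an error).
#'
#' @param y_i integer outcome vector over waves (values in `1..J`).
#' @param X_i covariate matrix, one row per wave.
#' @param params a [gop_params()] object.
#' @param alpha individual effect value.
#' @return scalar log-likelihood (possibly `-Inf`).
#' @export
conditional_panel_loglik <- function(y_i, X_i, params, alpha = 0) {
  X_i <- rbind(X_i)
  if (length(y_i) != nrow(X_i))
    stop("y_i and X_i must have one entry/row per wave")
  Z <- sweep(X_i %*% t(params$slopes), 2, params$intercepts, "+") + alpha
  S <- cbind(1, stats::pnorm(Z), 0)
  P <- S[, -ncol(S), drop = FALSE] - S[, -1, drop = FALSE]
  pobs <- P[cbind(seq_along(y_i), as.integer(y_i))]
  if (any(pobs <= 0)) return(-Inf)
  sum(log(pobs))
}

#' Marginal log-likelihood for one individual
#'
#' Integrates the conditional panel likelihood over the individual effect
#' `alpha ~ N(0, sigma_alpha^2)` by Gauss-Hermite quadrature with the change
#' of variable `alpha = sqrt(2) * sigma_alpha * node`.  When
#' `sigma_alpha = 0` the conditional log-likelihood at `alpha = 0` is
#' returned exactly.
#'
#' @inheritParams conditional_panel_loglik
#' @param quad either an integer number of nodes or a rule from [gh_rule()].
#' @return scalar marginal log-likelihood.
#' @export
marginal_loglik_individual <- function(y_i, X_i, params, quad = 15L) {
  if (params$sigma_alpha == 0)
    return(conditional_panel_loglik(y_i, X_i, params, alpha = 0))
  if (is.numeric(quad) && length(quad) == 1L) quad <- gh_rule(quad)
  if (length(quad$x) < 2L) stop("quadrature rule needs at least 2 nodes")
  a <- sqrt(2) * params$sigma_alpha * quad$x
  ll <- vapply(a, function(al) conditional_panel_loglik(y_i, X_i, params, al),
               numeric(1))
  m <- max(ll)
  if (!is.finite(m)) {
    if (all(ll == -Inf)) return(-Inf)
    stop("non-finite integrand at all quadrature nodes")
  }
  m + log(sum(quad$w * exp(ll - m)))
}

#' Total marginal log-likelihood of a panel dataset
#'
#' Sum over individuals of the Gauss-Hermite marginal log-likelihood, computed
#' by a vectorized engine (identical to the per-individual loop within
#' numerical noise).  Raw probability differences are used; a non-positive
#' probability of an observed outcome at every node makes the result `-Inf`.
#'
#' @param data panel data frame (see [validate_panel()]).
#' @param params a [gop_params()] object.
#' @param spec a [gop_spec()] object.
#' @param nodes Gauss-Hermite node count.
#' @return scalar log-likelihood.
#' @export
total_loglik <- function(data, params, spec, nodes = 15L) {
  mf <- model_frame(data, spec)
  gh <- gh_rule(nodes)
  eng <- gop_engine(pack_params(params, spec), spec, mf, gh,
                    want_grad = FALSE, clamp = 0)
  eng$loglik
}

#' Diagnose invalid probability regions of a generalized model
#'
#' Counts observations whose raw interior category probabilities (at
#' `alpha = 0`) are negative under `params` — the price of relaxing the
#' parallel-lines restriction.  A fully parallel model with ordered
#' intercepts never produces any.
#'
#' @inheritParams total_loglik
#' @return list with `count` and `fraction` of affected observations.
#' @export
validity_diagnostic <- function(data, params, spec) {
  if (nrow(data) == 0L) return(list(count = 0L, fraction = 0))
  validate_panel(data, spec, require_outcome = FALSE)
  X <- as.matrix(data[spec$covariate_names])
  Z <- sweep(X %*% t(params$slopes), 2, params$intercepts, "+")
  S <- stats::pnorm(Z)                     # P(y > j), j = 1..J-1
  bad <- rep(FALSE, nrow(X))
  if (ncol(S) >= 2L)
    for (j in seq_len(ncol(S) - 1L))
      bad <- bad | (S[, j] < S[, j + 1L])  # interior p_{j+1} < 0
  list(count = sum(bad), fraction = mean(bad))
}

## ---------------------------------------------------------------------------
## Vectorized likelihood/gradient engine over observations x quadrature nodes.
##
## theta is the free-parameter vector (see par_map); mf a model frame; gh a
## probability-weight quadrature rule.  clamp > 0 floors per-observation
## probabilities inside logs so the optimizer always sees a finite, repelling
## surface; clamp = 0 gives the honest likelihood (-Inf possible).
gop_engine <- function(theta, spec, mf, gh, want_grad = TRUE,
                       clamp = 1e-300, map = par_map(spec)) {
  Jm1 <- n_equations(spec)
  y <- mf$y; X <- mf$X; idx <- mf$id_index
  N <- mf$n_obs; nI <- mf$n_ind

  slopes <- matrix(theta[map$slope_index], Jm1, length(spec$covariate_names))
  cints <- theta[map$int_index]
  sigma <- if (spec$random_effects) exp(theta[map$sig_index]) else 0

  if (sigma > 0) {
    a <- sqrt(2) * sigma * gh$x
    w <- gh$w
  } else {
    a <- 0
    w <- 1
  }
  Q <- length(a)

  eta <- X %*% t(slopes)
  eta <- sweep(eta, 2, cints, "+")         # N x (J-1)

  Lo <- Up <- Den <- vector("list", Jm1)
  for (j in seq_len(Jm1)) {
    Z <- outer(eta[, j], a, "+")           # N x Q
    Lo[[j]]  <- stats::pnorm(Z)
    Up[[j]]  <- stats::pnorm(Z, lower.tail = FALSE)
    Den[[j]] <- stats::dnorm(Z)
    if (j == 1L) Zs <- list(Z) else Zs[[j]] <- Z
  }

  ## per-observation category probability at each node
  P <- matrix(0, N, Q)
  r1 <- y == 1L
  if (any(r1)) P[r1, ] <- Up[[1L]][r1, , drop = FALSE]
  rJ <- y == Jm1 + 1L
  if (any(rJ)) P[rJ, ] <- Lo[[Jm1]][rJ, , drop = FALSE]
  if (Jm1 >= 2L) {
    for (cc in 2:Jm1) {                    # interior categories
      rc <- y == cc
      if (!any(rc)) next
      lo_form <- Lo[[cc - 1L]][rc, , drop = FALSE] - Lo[[cc]][rc, , drop = FALSE]
      up_form <- Up[[cc]][rc, , drop = FALSE] - Up[[cc - 1L]][rc, , drop = FALSE]
      use_up <- (Zs[[cc - 1L]][rc, , drop = FALSE] +
                 Zs[[cc]][rc, , drop = FALSE]) > 0
      P[rc, ] <- ifelse(use_up, up_form, lo_form)
    }
  }

  Peff <- if (clamp > 0) pmax(P, clamp) else P
  lp <- log(Peff)                          # -Inf possible when clamp = 0

  lp_ind <- rowsum(lp, idx, reorder = TRUE)          # nI x Q
  if (Q == 1L) {
    ll_i <- lp_ind[, 1L]
    Srow <- exp(ll_i * 0)                  # ones
    A <- matrix(1, nI, 1L)
    m <- ll_i
  } else {
    m <- do.call(pmax, c(as.data.frame(lp_ind), na.rm = TRUE))
    ok <- is.finite(m)
    A <- exp(lp_ind - ifelse(ok, m, 0))
    if (any(!ok)) A[!ok, ] <- 0
    Srow <- drop(A %*% w)
    ll_i <- ifelse(ok, m + log(Srow), -Inf)
  }
  loglik <- sum(ll_i)

  out <- list(loglik = loglik, loglik_i = ll_i, sigma = sigma,
              p_floor_hits = if (clamp > 0) sum(P < clamp) else 0L)
  if (!want_grad) return(out)
  if (!is.finite(loglik))
    return(c(out, list(grad = rep(NA_real_, map$n_free))))

  ## node weights per individual, expanded to observations
  if (Q == 1L) {
    Wobs <- matrix(1, N, 1L)
  } else {
    Wind <- sweep(A, 2, w, "*") / Srow
    Wobs <- Wind[idx, , drop = FALSE]
  }

  grad <- numeric(map$n_free)
  Ga <- if (spec$random_effects) matrix(0, N, Q) else NULL
  for (j in seq_len(Jm1)) {
    sj <- (y == j + 1L) - (y == j)         # +phi for y=j+1, -phi for y=j
    Gj <- Den[[j]] * sj / Peff
    uj <- rowSums(Wobs * Gj)
    gj <- drop(crossprod(X, uj))           # slope gradient, equation j
    tgt <- map$slope_index[j, ]
    for (k in seq_along(tgt)) grad[tgt[k]] <- grad[tgt[k]] + gj[k]
    grad[map$int_index[j]] <- sum(uj)
    if (!is.null(Ga)) Ga <- Ga + Gj
  }
  if (spec$random_effects) {
    ## d alpha_q / d log(sigma) = alpha_q
    grad[map$sig_index] <- sum(colSums(Wobs * Ga) * a)
  }
  names(grad) <- map$labels
  out$grad <- grad
  out
}
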