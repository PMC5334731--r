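#' Covariate specification for the synthetic panel generator
#'
#' Describes one covariate's marginal distribution.  Kinds:
#' \describe{
#'   \item{binary}{Bernoulli; `params$p` in `[0, 1]`.}
#'   \item{continuous}{`params$dist` one of `"normal"`, `"truncnorm"`,
#'     `"lognormal"`; `mean`/`sd` are the *target* moments.  Truncated
#'     normals take `lower`/`upper` support bounds and are moment-matched:
#'     the parent normal's parameters are solved so the truncated
#'     distribution attains the target mean and SD.  Log-normals are
#'     moment-matched on the natural scale.}
#'   \item{categorical}{ordinal score; `params$values` and `params$freqs`
#'     (summing to 1 within 1e-9).}
#'   \item{derived}{deterministic transform of exactly one parent covariate;
#'     `params$parent` and `params$transform` (currently `"square"`).}
#' }
#'
#' @param name column label.
#' @param kind one of `"binary"`, `"continuous"`, `"categorical"`,
#'   `"derived"`.
#' @param params list of distribution parameters (see Details).
#' @param time_varying logical; does the covariate change across waves?
#'   (Only age — and its derived square — does in the default cohort.)
#' @return object of class `"covariate_spec"`.
#' @export
covariate_spec <- function(name, kind, params, time_varying = FALSE) {
  kind <- match.arg(kind, c("binary", "continuous", "categorical", "derived"))
  if (kind == "binary") {
    if (is.null(params$p) || params$p < 0 || params$p > 1)
      stop("binary covariate '", name, "' needs p in [0, 1]")
  } else if (kind == "continuous") {
    params$dist <- match.arg(params$dist,
                             c("normal", "truncnorm", "lognormal"))
    if (is.null(params$sd) || params$sd <= 0)
      stop("continuous covariate '", name, "' needs sd > 0")
    if (params$dist == "truncnorm") {
      if (is.null(params$lower) || is.null(params$upper) ||
          params$lower >= params$upper)
        stop("truncated normal '", name, "' needs lower < upper")
      mm <- truncnorm_match(params$mean, params$sd,
                            params$lower, params$upper)
      params$mu <- mm$mu
      params$sigma <- mm$sigma
    } else if (params$dist == "lognormal") {
      if (params$mean <= 0)
        stop("lognormal covariate '", name, "' needs mean > 0")
      s2 <- log(1 + (params$sd / params$mean)^2)
      params$sdlog <- sqrt(s2)
      params$meanlog <- log(params$mean) - s2 / 2
    }
  } else if (kind == "categorical") {
    f <- params$freqs
    if (is.null(f) || length(f) != length(params$values))
      stop("categorical covariate '", name,
           "' needs matching values and freqs")
    if (abs(sum(f) - 1) > 1e-9)
      stop("categorical frequencies of '", name, "' must sum to 1")
    if (any(f < 0)) stop("negative frequency in '", name, "'")
  } else {
    if (is.null(params$parent) || length(params$parent) != 1L)
      stop("derived covariate '", name, "' must reference exactly one parent")
    params$transform <- match.arg(params$transform, "square")
  }
  structure(list(name = name, kind = kind, params = params,
                 time_varying = isTRUE(time_varying)),
            class = "covariate_spec")
}

## Truncated-normal moments for parent N(mu, sigma^2) on [lower, upper].
truncnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

## Solve for the parent normal whose truncation to [lower, upper] has the
## target mean and SD.  Deterministic; Nelder-Mead on (mu, log sigma).
truncnorm_match <- function(mean, sd, lower, upper) {
  obj <- function(par) {
    mm <- truncnorm_moments(par[1], exp(par[2]), lower, upper)
    ((mm$mean - mean) / sd)^2 + ((mm$sd - sd) / sd)^2
  }
  o <- stats::optim(c(mean, log(sd)), obj,
                    control = list(reltol = 1e-14, maxit = 2000))
  if (o$value > 1e-8)
    stop("truncated-normal moment matching failed (residual ",
         format(o$value), "); targets may be infeasible on [",
         lower, ", ", upper, "]")
  list(mu = o$par[1], sigma = exp(o$par[2]))
}

#' Default HILDA-like covariate specification
#'
#' Eighteen covariate specs calibrated so that generated marginals match, in
#' expectation, the descriptive statistics of an Australian adult household
#' panel cohort: demographic indicators, remoteness area, life satisfaction,
#' log equivalized disposable income, household expenditures on alcohol and
#' meals out (right-skewed, moment-matched log-normals), education and
#' socio-economic advantage (SEIFA decile) scores, marital status, and the
#' five FFM personality traits on the 1-7 scale.  Only age (and its square)
#' varies across waves, advancing one year per wave.
#'
#' @return list of 18 [covariate_spec()] objects, in the canonical column
#'   order.
#' @export
default_hilda_spec <- function() {
  list(
    covariate_spec("gender", "binary", list(p = 0.476)),
    covariate_spec("age", "continuous",
                   list(dist = "truncnorm", mean = 45.866, sd = 17.848,
                        lower = 15, upper = 95),
                   time_varying = TRUE),
    covariate_spec("age2", "derived",
                   list(parent = "age", transform = "square"),
                   time_varying = TRUE),
    covariate_spec("empstatus", "binary", list(p = 0.658)),
    covariate_spec("area", "categorical",
                   list(values = 0:4,
                        freqs = c(61.69, 25.28, 11.19, 1.50, 0.34) / 100)),
    covariate_spec("hhtype", "binary", list(p = 0.304)),
    covariate_spec("losat", "categorical",
                   list(values = 1:3,
                        freqs = local({
                          f <- c(1.11, 10.12, 88.78); f / sum(f)
                        }))),
    covariate_spec("lndinc_p", "continuous",
                   list(dist = "normal", mean = 10.108, sd = 0.640)),
    covariate_spec("alcohol", "continuous",
                   list(dist = "lognormal", mean = 1450.713, sd = 2355.439)),
    covariate_spec("meals", "continuous",
                   list(dist = "lognormal", mean = 2443.758, sd = 2809.403)),
    covariate_spec("educ", "categorical",
                   list(values = 1:4,
                        freqs = local({
                          f <- c(23.31, 31.16, 14.96, 30.58); f / sum(f)
                        }))),
    covariate_spec("advantage", "categorical",
                   list(values = 1:10,
                        freqs = c(8.51, 10.24, 10.46, 9.44, 9.99, 9.35,
                                  9.96, 10.58, 11.00, 10.47) / 100)),
    covariate_spec("marstatus", "binary", list(p = 0.658)),
    covariate_spec("agree", "continuous",
                   list(dist = "truncnorm", mean = 5.369, sd = 0.912,
                        lower = 1, upper = 7)),
    covariate_spec("consc", "continuous",
                   list(dist = "truncnorm", mean = 5.105, sd = 1.020,
                        lower = 1, upper = 7)),
    covariate_spec("emote", "continuous",
                   list(dist = "truncnorm", mean = 5.234, sd = 1.068,
                        lower = 1, upper = 7)),
    covariate_spec("extrv", "continuous",
                   list(dist = "truncnorm", mean = 4.429, sd = 1.068,
                        lower = 1, upper = 7)),
    covariate_spec("opene", "continuous",
                   list(dist = "truncnorm", mean = 4.188, sd = 1.057,
                        lower = 1, upper = 7))
  )
}
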