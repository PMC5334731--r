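#' WHO BMI categorization
#'
#' Maps BMI (kg/m^2) to the modelled ordered categories using half-open WHO
#' intervals: `[18.5, 25) -> 1` (normal), `[25, 30) -> 2` (overweight),
#' `[30, Inf) -> 3` (obese).  BMI below 18.5 is coded 0 (underweight) and is
#' excluded from modelling datasets.
#'
#' @param bmi numeric vector of positive BMI values.
#' @return integer vector with values in `{0, 1, 2, 3}` (0 = underweight).
#' @export
bmi_to_category <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    stop("BMI values must be positive and finite")
  as.integer(cut(bmi, breaks = c(0, 18.5, 25, 30, Inf),
                 labels = FALSE, right = FALSE)) - 1L
}

#' Empirical between-wave category transition matrix
#'
#' Conditional probabilities `P(category at wave_b | category at wave_a)`
#' over individuals observed in both waves (complete-case).  Rows index the
#' category at `wave_a`, columns the category at `wave_b`; rows with a
#' positive count sum to 1.
#'
#' @param data panel data frame with `id`, `wave`, `y`.
#' @param wave_a,wave_b wave indices; default first and last wave present.
#' @param J number of categories (default: maximum observed outcome).
#' @return object of class `"transition_matrix"`: `P` (J x J), `counts`
#'   (row totals at `wave_a`), `waves`.
#' @export
transition_matrix <- function(data, wave_a = NULL, wave_b = NULL, J = NULL) {
  validate_panel(data)
  wave_a <- wave_a %||% min(data$wave)
  wave_b <- wave_b %||% max(data$wave)
  a <- data[data$wave == wave_a, c("id", "y")]
  b <- data[data$wave == wave_b, c("id", "y")]
  m <- merge(a, b, by = "id", suffixes = c("_a", "_b"))
  if (nrow(m) == 0L)
    stop("no individuals observed in both wave ", wave_a, " and wave ",
         wave_b)
  J <- J %||% max(data$y)
  tab <- table(factor(m$y_a, levels = seq_len(J)),
               factor(m$y_b, levels = seq_len(J)))
  counts <- rowSums(tab)
  P <- tab / ifelse(counts > 0, counts, 1)
  P <- matrix(as.numeric(P), J, J,
              dimnames = list(from = seq_len(J), to = seq_len(J)))
  structure(list(P = P, counts = as.integer(counts),
                 waves = c(wave_a, wave_b), n = nrow(m)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Transition probabilities, wave", x$waves[1], "->", x$waves[2],
      "(n =", x$n, ")\n")
  print(round(x$P, 3))
  invisible(x)
}

#' Descriptive statistics blocks for a panel dataset
#'
#' Means and SDs for continuous and binary columns (a binary mean is the
#' proportion of ones) and percentage frequency distributions for
#' categorical columns.
#'
#' @param data panel data frame.
#' @param categorical character vector of columns to tabulate as
#'   frequencies; defaults to the ordinal-score columns of the default
#'   cohort present in `data` (plus `y`).
#' @return list with `moments` (data frame of mean/SD) and `frequencies`
#'   (named list of percentage tables).
#' @export
descriptive_tables <- function(data,
                               categorical = intersect(
                                 c("area", "losat", "educ", "advantage", "y"),
                                 names(data))) {
  num_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                      c("id", "wave", categorical))
  moments <- data.frame(
    variable = num_cols,
    mean = vapply(num_cols, function(v) mean(data[[v]]), numeric(1)),
    sd = vapply(num_cols, function(v) stats::sd(data[[v]]), numeric(1)),
    row.names = NULL
  )
  freqs <- lapply(categorical, function(v) {
    tab <- table(data[[v]])
    100 * tab / sum(tab)
  })
  names(freqs) <- categorical
  list(moments = moments, frequencies = freqs)
}

#' Render a coefficient report for a fitted model
#'
#' Deterministic tabular rendering of a `"gop_fit"`: one coefficient and
#' standard-error column pair per cumulative equation, shared
#' (parallel-restricted) rows repeated identically in every equation and
#' marked, significance stars at the two-sided 1% level, plus `rho`,
#' log-likelihood, sample sizes, and the overall model Wald test.
#'
#' @param fit a converged `"gop_fit"` with covariance.
#' @param tests optional list of `"gop_wald"` objects to attach.
#' @return object of class `"gop_report"`; `as_json()` gives its JSON form.
#' @export
render_fit_report <- function(fit, tests = list()) {
  spec <- fit$spec
  Jm1 <- n_equations(spec)
  zcrit <- stats::qnorm(0.995)
  rows <- list()
  for (v in spec$covariate_names) {
    for (j in seq_len(Jm1)) {
      slot <- free_slot(fit, j, v)
      co <- natural_theta(fit)[slot]
      se <- fit$se[slot]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, equation = paste0("eq", j), coef = unname(co),
        se = unname(se), star = is.finite(se) && abs(co / se) > zcrit,
        shared = v %in% spec$parallel_set)
    }
  }
  for (j in seq_len(Jm1)) {
    slot <- fit$map$int_index[j]
    co <- natural_theta(fit)[slot]; se <- fit$se[slot]
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "constant", equation = paste0("eq", j), coef = unname(co),
      se = unname(se), star = is.finite(se) && abs(co / se) > zcrit,
      shared = FALSE)
  }
  table <- do.call(rbind, rows)
  model_test <- tryCatch(wald_slopes_zero(fit), error = function(e) NULL)
  structure(list(
    table = table,
    rho = fit$rho,
    sigma_alpha = fit$estimates$sigma_alpha,
    loglik = fit$loglik,
    n_obs = fit$n_obs,
    n_individuals = fit$n_individuals,
    model_wald = model_test,
    tests = tests,
    star_level = "1% (two-sided)"
  ), class = "gop_report")
}

#' @rdname render_fit_report
#' @param report a `"gop_report"`.
#' @export
as_json <- function(report) {
  stopifnot(inherits(report, "gop_report"))
  x <- unclass(report)
  if (!is.null(x$model_wald)) x$model_wald <- unclass(x$model_wald)
  x$tests <- lapply(x$tests, unclass)
  jsonlite::toJSON(x, dataframe = "columns", auto_unbox = TRUE, digits = NA)
}

#' @export
print.gop_report <- function(x, ...) {
  cat("Number of Observations =", x$n_obs,
      " (", x$n_individuals, "individuals )\n")
  cat("Log Likelihood =", format(x$loglik, digits = 8), "\n")
  if (!is.null(x$model_wald))
    cat(sprintf("Wald chi2(%d) = %.2f;  Pr > chi2 = %.4g\n",
                x$model_wald$df, x$model_wald$statistic,
                x$model_wald$p_value))
  tab <- x$table
  wide <- NULL
  for (eq in unique(tab$equation)) {
    sub <- tab[tab$equation == eq, ]
    cols <- data.frame(
      coef = sprintf("%s%9.4f%s", ifelse(sub$shared, "=", " "), sub$coef,
                     ifelse(sub$star, " *", "  ")),
      se = sprintf("%8.4f", sub$se))
    names(cols) <- paste0(eq, c(".coef", ".se"))
    wide <- if (is.null(wide)) cbind(data.frame(variable = sub$variable),
                                     cols) else cbind(wide, cols)
  }
  print(wide, row.names = FALSE)
  cat("rho =", format(x$rho, digits = 4),
      "  (* ", x$star_level, "; '=' parallel-restricted row)\n")
  invisible(x)
}
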