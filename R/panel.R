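#' Validate a long-format panel dataset
#'
#' A panel dataset is a data frame with one row per (individual, wave)
#' observation: an `id` column, an integer `wave` column, optionally an
#' ordered outcome `y` in `1..J`, and covariate columns.  Validation enforces
#' uniqueness of `(id, wave)`, outcome range, and absence of missing values in
#' the model columns.
#'
#' @param data data frame in long format.
#' @param spec optional [gop_spec()]; when supplied the covariate columns and
#'   the outcome range are checked against it.
#' @param require_outcome logical; must a `y` column be present?
#' @return `data`, invisibly, after passing all checks.
#' @export
validate_panel <- function(data, spec = NULL, require_outcome = TRUE) {
  if (!is.data.frame(data)) stop("panel data must be a data frame")
  need <- c("id", "wave")
  if (require_outcome) need <- c(need, "y")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("panel data lacks required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(data[c("id", "wave")]))
    stop("duplicated (id, wave) pairs in panel data")
  if (!is.null(spec)) {
    missx <- setdiff(spec$covariate_names, names(data))
    if (length(missx))
      stop("panel data lacks covariate column(s): ",
           paste(missx, collapse = ", "))
    cols <- c(need, spec$covariate_names)
    if (anyNA(data[cols]))
      stop("missing values in model columns")
    if (require_outcome) {
      y <- data$y
      if (!all(y %in% seq_len(spec$J)))
        stop("outcome y must lie in 1..", spec$J)
    }
  } else if (require_outcome) {
    if (anyNA(data$y) || any(data$y < 1))
      stop("outcome y must be a positive category code without missing values")
  }
  invisible(data)
}

## Internal: panel -> dense model arrays sorted by individual.
model_frame <- function(data, spec) {
  validate_panel(data, spec)
  ord <- order(data$id, data$wave)
  data <- data[ord, , drop = FALSE]
  ids <- unique(data$id)
  list(
    y = as.integer(data$y),
    X = as.matrix(data[spec$covariate_names]),
    id_index = match(data$id, ids),
    n_ind = length(ids),
    n_obs = nrow(data),
    ids = ids
  )
}

#' Read / write a panel dataset as delimited text
#'
#' Plain CSV with a header row: `id`, `wave`, `y` (if present), then covariate
#' columns.
#'
#' @param file path to a CSV file.
#' @param data panel data frame.
#' @param spec optional [gop_spec()] used for validation on read.
#' @return `read_panel()` returns the validated data frame; `write_panel()`
#'   returns `file` invisibly.
#' @export
read_panel <- function(file, spec = NULL) {
  data <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_panel(data, spec, require_outcome = "y" %in% names(data))
  data
}

#' @rdname read_panel
#' @export
write_panel <- function(data, file) {
  utils::write.csv(data, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
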