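#' Feature schema for a categorical clinical variable
#'
#' A feature schema fixes the vocabulary of a categorical feature: its name,
#' the ordered list of admissible category labels, whether that order is
#' meaningful (ordinal), and the token that marks a missing value in CSV
#' files. Rank-based tests and mode-imputation tie-breaking both use the
#' listing order, so the order in `categories` is part of the contract.
#'
#' @param name Feature name (single string).
#' @param categories Character vector of unique, non-empty category labels.
#'   Order matters: it defines ordinal ranks and the imputation tie-break.
#' @param ordinal Logical; `TRUE` when the category order carries meaning
#'   (graded scales such as IQ bands), `FALSE` for purely nominal features.
#' @param missing_token String marking missingness in CSV files; must not
#'   collide with a category label. Default `"NA"`.
#'
#' @return An object of class `feature_schema`.
#' @export
#' @examples
#' feature_schema("Side", c("Left", "Right"))
feature_schema <- function(name, categories, ordinal = FALSE,
                           missing_token = "NA") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  categories <- as.character(categories)
  if (length(categories) == 0L || anyDuplicated(categories) ||
      any(!nzchar(categories))) {
    stop("'categories' must be a non-empty vector of unique, non-empty labels",
         call. = FALSE)
  }
  stopifnot(is.character(missing_token), length(missing_token) == 1L)
  if (missing_token %in% categories) {
    stop("missing token '", missing_token, "' collides with a category of '",
         name, "'", call. = FALSE)
  }
  structure(
    list(name = name, categories = categories, ordinal = isTRUE(ordinal),
         missing_token = missing_token),
    class = "feature_schema"
  )
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> ", x$name,
      if (x$ordinal) " (ordinal)" else " (nominal)", ": ",
      paste(x$categories, collapse = " < "), "\n", sep = "")
  invisible(x)
}

#' Read a list of feature schemas from JSON
#'
#' The JSON file is an array of objects with fields `name`, `categories`,
#' and optionally `ordinal` and `missing_token`.
#'
#' @param path Path to a JSON schema file.
#' @return A named list of [feature_schema()] objects, in file order.
#' @export
read_schema <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- lapply(raw, function(s) {
    feature_schema(
      name = s$name,
      categories = unlist(s$categories),
      ordinal = isTRUE(s$ordinal),
      missing_token = if (is.null(s$missing_token)) "NA" else s$missing_token
    )
  })
  names(out) <- vapply(out, function(s) s$name, character(1))
  out
}

#' Write a list of feature schemas to JSON
#'
#' @param schema Named list of [feature_schema()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  payload <- lapply(unname(schema), function(s) {
    list(name = s$name, categories = s$categories, ordinal = s$ordinal,
         missing_token = s$missing_token)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Predictive-variable schema of the epilepsy surgery cohort
#'
#' The 19 pre-surgical predictive variables of the study cohort: 8 clinical
#' features (gender, seizure-onset side, binned surgery age, binned onset
#' age, binned elapsed time, seizure type, seizure frequency, febrile
#' seizure history) and 11 neuropsychological features (WAIS-III IQ bands,
#' WMS memory bands, Rorschach indices and personality style). Category
#' orders follow the published vocabulary listing; graded scales are flagged
#' ordinal.
#'
#' @return Named list of 19 [feature_schema()] objects.
#' @export
#' @examples
#' names(study_schema())
study_schema <- function() {
  read_schema(system.file("extdata", "table2_schema.json",
                          package = "episelect", mustWork = TRUE))
}
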