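#' Class-conditional mode imputation
#'
#' Fills every missing feature value with the most frequent observed
#' category among patients of the *same outcome class*, the convention used
#' to complete the study cohort before classification. Within-class modal
#' ties break towards the category listed first in the schema, so reruns
#' are deterministic. When a feature is entirely missing within one class
#' the overall (class-pooled) mode is used instead, with a warning.
#'
#' Imputing once on the full cohort leaks outcome information into any
#' subsequent cross-validation; this mirrors the original procedure. Set
#' `strict_cv = TRUE` on [loocv_evaluate()] to re-impute inside each
#' training fold instead when comparing methodologies.
#'
#' @param cohort A [cohort_table()] with a complete outcome column.
#' @return A `cohort_table` with no missing cells; observed cells, ids and
#'   outcomes are untouched.
#' @export
#' @examples
#' sch <- list(f = feature_schema("f", c("A", "B")))
#' co <- cohort_table(letters[1:4],
#'                    data.frame(f = c("A", "A", NA, "B")),
#'                    rep(c("seizure_free", "improvement_only"), 2), sch)
#' impute_class_conditional_mode(co)$features$f
impute_class_conditional_mode <- function(cohort) {
  feats <- cohort$features
  cls <- as.integer(cohort$outcome)
  for (nm in names(feats)) {
    col <- feats[[nm]]
    miss <- is.na(col)
    if (!any(miss)) next
    cats <- cohort$schema[[nm]]$categories
    for (k in 1:2) {
      in_k <- cls == k
      if (!any(miss & in_k)) next
      obs <- col[in_k & !miss]
      if (length(obs) == 0L) {
        obs <- col[!miss]
        warning("feature '", nm, "' entirely missing in class ",
                levels(cohort$outcome)[k], "; using overall mode",
                call. = FALSE)
        if (length(obs) == 0L) {
          stop("feature '", nm, "' has no observed values at all",
               call. = FALSE)
        }
      }
      counts <- table(factor(obs, levels = cats))
      col[miss & in_k] <- cats[which.max(counts)]  # first max = schema order
    }
    feats[[nm]] <- col
  }
  cohort_table(cohort$patient_ids, feats, as.character(cohort$outcome),
               cohort$schema)
}
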