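#' Construct a categorical cohort table
#'
#' The central data container of the pipeline: one row per patient, one
#' categorical column per schema feature, plus a binary surgical-outcome
#' label (`seizure_free` vs `improvement_only`). Missing feature values are
#' stored as `NA`; the outcome must be complete.
#'
#' @param patient_ids Character vector of unique patient identifiers.
#' @param features Data frame (or named list) of character columns, one per
#'   schema entry, values drawn from the schema categories or `NA`.
#' @param outcome Character/factor vector with values `"seizure_free"` or
#'   `"improvement_only"`, no missing entries.
#' @param schema Named list of [feature_schema()] objects covering every
#'   column of `features`.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(patient_ids, features, outcome, schema) {
  patient_ids <- as.character(patient_ids)
  n <- length(patient_ids)
  if (anyDuplicated(patient_ids)) {
    stop("duplicate patient ids: ",
         paste(unique(patient_ids[duplicated(patient_ids)]), collapse = ", "),
         call. = FALSE)
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE,
                            check.names = FALSE, optional = TRUE)
  if (n == 0L && ncol(features) == 0L) {
    features <- as.data.frame(
      stats::setNames(rep(list(character(0)), length(schema)), names(schema)),
      check.names = FALSE)
  }
  if (nrow(features) != n) {
    stop("features have ", nrow(features), " rows but ", n, " patient ids",
         call. = FALSE)
  }
  missing_schema <- setdiff(names(features), names(schema))
  if (length(missing_schema)) {
    stop("no schema for feature(s): ", paste(missing_schema, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(features)) {
    col <- as.character(features[[nm]])
    bad <- !is.na(col) & !(col %in% schema[[nm]]$categories)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("schema violation: value '", col[i], "' in column '", nm,
           "', row ", i, " (patient ", patient_ids[i],
           ") is not a category of '", nm, "'", call. = FALSE)
    }
    features[[nm]] <- col
  }
  outcome <- as.character(outcome)
  if (length(outcome) != n || anyNA(outcome)) {
    stop("outcome must be complete and of length n", call. = FALSE)
  }
  bad <- !(outcome %in% c("seizure_free", "improvement_only"))
  if (any(bad)) {
    stop("outcome values must be 'seizure_free' or 'improvement_only'; got '",
         outcome[which(bad)[1L]], "'", call. = FALSE)
  }
  structure(
    list(patient_ids = patient_ids, features = features,
         outcome = factor(outcome, levels = c("seizure_free",
                                              "improvement_only")),
         schema = schema[names(features)], n = n),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  n_miss <- sum(is.na(as.matrix(x$features)))
  cat("<cohort_table> ", x$n, " patients, ", ncol(x$features),
      " features, ", n_miss, " missing cells\n", sep = "")
  cat("  outcome: seizure_free ", sum(x$outcome == "seizure_free"),
      " / improvement_only ", sum(x$outcome == "improvement_only"),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) c(x$n, ncol(x$features))

#' Feature names of a cohort
#'
#' @param cohort A [cohort_table()].
#' @return Character vector of feature column names, in schema order.
#' @export
feature_names <- function(cohort) names(cohort$features)

#' Restrict a cohort to a subset of patients or features
#'
#' @param cohort A [cohort_table()].
#' @param patients Optional integer/logical index or character ids.
#' @param features Optional character vector of feature names to keep.
#' @return A new `cohort_table`.
#' @export
subset_cohort <- function(cohort, patients = NULL, features = NULL) {
  idx <- seq_len(cohort$n)
  if (!is.null(patients)) {
    idx <- if (is.character(patients)) {
      match(patients, cohort$patient_ids)
    } else {
      idx[patients]
    }
    if (anyNA(idx)) stop("unknown patient id(s)", call. = FALSE)
  }
  keep <- if (is.null(features)) feature_names(cohort) else features
  unknown <- setdiff(keep, feature_names(cohort))
  if (length(unknown)) {
    stop("unknown feature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cohort_table(cohort$patient_ids[idx],
               cohort$features[idx, keep, drop = FALSE],
               as.character(cohort$outcome)[idx],
               cohort$schema[keep])
}

#' Load a cohort from CSV against a schema
#'
#' The CSV must carry a header with a `patient_id` column, an `outcome`
#' column (`seizure_free` / `improvement_only`) and one column per schema
#' feature. Each schema's missing token (default `"NA"`) is mapped to a
#' missing cell; any other out-of-vocabulary label raises a schema-violation
#' error naming the offending row and column.
#'
#' @param path Path to a CSV file (RFC-4180, UTF-8, header row).
#' @param schema Named list of [feature_schema()] objects.
#' @param id_col,outcome_col Column names for ids and outcome.
#' @return A [cohort_table()].
#' @export
load_cohort <- function(path, schema, id_col = "patient_id",
                        outcome_col = "outcome") {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character(0))
  for (col in c(id_col, outcome_col)) {
    if (!col %in% names(df)) {
      stop("required column '", col, "' not found in ", path, call. = FALSE)
    }
  }
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols)) {
    stop("cohort file lacks schema column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  feats <- df[names(schema)]
  for (nm in names(schema)) {
    feats[[nm]][feats[[nm]] == schema[[nm]]$missing_token] <- NA_character_
  }
  cohort_table(df[[id_col]], feats, df[[outcome_col]], schema)
}

#' Write a cohort to CSV in the canonical dialect
#'
#' Missing cells are written as each feature's missing token, so
#' `load_cohort(write_cohort(x))` round-trips byte-identically.
#'
#' @param cohort A [cohort_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  feats <- cohort$features
  for (nm in names(feats)) {
    feats[[nm]][is.na(feats[[nm]])] <- cohort$schema[[nm]]$missing_token
  }
  df <- cbind(data.frame(patient_id = cohort$patient_ids,
                         stringsAsFactors = FALSE),
              feats,
              data.frame(outcome = as.character(cohort$outcome),
                         stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Collapse an Engel grade to the binary outcome label
#'
#' Engel class I (seizure-free) maps to `seizure_free`; classes II (rare
#' seizures) and III (worthwhile improvement) both indicate improvement
#' without full recovery and are grouped as `improvement_only`. Class IV
#' does not occur in this cohort and is rejected.
#'
#' @param grade Character vector of Engel grades (`"I"`, `"II"`, `"III"`).
#' @return Character vector of outcome labels.
#' @export
#' @examples
#' engel_to_binary(c("I", "II", "III"))
engel_to_binary <- function(grade) {
  grade <- as.character(grade)
  bad <- !(grade %in% c("I", "II", "III"))
  if (any(bad)) {
    stop("unsupported Engel grade '", grade[which(bad)[1L]],
         "' (only I, II, III occur in this cohort)", call. = FALSE)
  }
  ifelse(grade == "I", "seizure_free", "improvement_only")
}

# Bin a numeric value into labelled integer-edge bins "a-b". The printed bin
# edges are integers; real-valued records (onset age 0.7, 1.8) and the
# duration 40 force the bins to tile the real line: a value below a bin's
# upper edge + 1 joins that bin, and the last bin is open above.
bin_label <- function(x, labels) {
  edges <- vapply(strsplit(labels, "-"), function(v) as.numeric(v[2]),
                  numeric(1))
  out <- character(length(x))
  for (i in seq_along(x)) {
    if (!is.finite(x[i])) stop("cannot bin non-finite value", call. = FALSE)
    j <- which(x[i] < edges + 1)
    out[i] <- if (length(j)) labels[j[1L]] else labels[length(labels)]
  }
  out
}

#' Discretise raw clinical records into the study vocabulary
#'
#' Maps a raw clinical record (as read from the packaged cohort file) to the
#' categorical vocabulary of [study_schema()]: surgery age to two bins,
#' onset age and elapsed time (disease duration) to three bins each, seizure
#' type and frequency to their category labels, sex and side expanded to
#' `Male`/`Female` and `Left`/`Right`.
#'
#' Bins are read as covering the whole range: a value under a bin's upper
#' edge joins that bin (an onset age of 1.8 falls in `0-1`, below the `2-10`
#' bin), and the last bin is open above (a duration of 40 joins `20-39`).
#' Seizure-frequency
#' strings carrying a range collapse to the single nearest weekly label and
#' `"Not regular"` maps to `Other`, the unique mapping consistent with the
#' published category cardinalities.
#'
#' @param raw Data frame with columns `age`, `sex`, `side`, `onset_age`,
#'   `duration_years`, `seizure_type`, `seizure_freq`.
#' @return Data frame of categorical columns named as in [study_schema()].
#' @export
discretize_clinical <- function(raw) {
  freq_map <- c("daily" = "Daily", "weekly" = "Weekly",
                "2 weekly" = "2-Weekly", "3 weekly" = "3-Weekly",
                "4 weekly" = "4-Weekly", "0-3 weekly" = "3-Weekly",
                "3-5 weekly" = "4-Weekly", "Not regular" = "Other")
  type_map <- c("gen" = "Generalized", "PC" = "PartialComplex",
                "PC, gen" = "Both")
  for (col in c("seizure_freq", "seizure_type")) {
    map <- if (col == "seizure_freq") freq_map else type_map
    bad <- !(raw[[col]] %in% names(map))
    if (any(bad)) {
      stop("unrecognised ", col, " value '", raw[[col]][which(bad)[1L]], "'",
           call. = FALSE)
    }
  }
  data.frame(
    Gender = ifelse(raw$sex == "m", "Male", "Female"),
    Side = ifelse(raw$side == "L", "Left", "Right"),
    SurgeryAge = bin_label(raw$age, c("17-32", "33-54")),
    OnsetAge = bin_label(raw$onset_age, c("0-1", "2-10", "11-20")),
    ElapsedTime = bin_label(raw$duration_years, c("7-13", "14-19", "20-39")),
    SeizureType = unname(type_map[raw$seizure_type]),
    SeizureFreq = unname(freq_map[raw$seizure_freq]),
    stringsAsFactors = FALSE
  )
}

#' The packaged 23-patient clinical table
#'
#' Raw clinical records of the 23 resected TLE patients with confirmed
#' hippocampal sclerosis: age at surgery, sex, seizure-onset side, age of
#' onset, disease duration, seizure type and frequency, Engel outcome grade
#' and follow-up years.
#'
#' @return Data frame with 23 rows.
#' @export
clinical_records <- function() {
  utils::read.csv(system.file("extdata", "table1_cohort.csv",
                              package = "episelect", mustWork = TRUE),
                  colClasses = c(age = "numeric", onset_age = "numeric",
                                 duration_years = "numeric",
                                 followup_years = "numeric"),
                  check.names = FALSE, na.strings = character(0))
}

#' The packaged cohort as a discretised `cohort_table`
#'
#' Discretises the raw clinical records via [discretize_clinical()] and
#' attaches the binary outcome from the Engel grade. Febrile-seizure history
#' is part of the study vocabulary but was not published per patient, so the
#' resulting cohort carries 7 of the 8 clinical features; the 11
#' neuropsychological features were likewise never published per patient and
#' are available only through the synthetic generator.
#'
#' @return A [cohort_table()] with 23 patients and 7 clinical features.
#' @export
clinical_cohort <- function() {
  raw <- clinical_records()
  feats <- discretize_clinical(raw)
  sch <- study_schema()[names(feats)]
  cohort_table(raw$patient_id, feats, engel_to_binary(raw$engel), sch)
}

#' A synthetic analysis-subset selection of the packaged cohort
#'
#' Four of the 23 patients lacked behavioral testing and were excluded from
#' the published 19-patient analysis, but their identities were not
#' disclosed. The only derivable constraints are that the dropped set
#' comprises three Engel-I patients and one Engel-II/III patient, all
#' female. This helper returns one deterministic subset satisfying those
#' constraints — the *last* three female Engel-I patients and the last
#' female Engel-II/III patient in table order are dropped. It is a synthetic
#' stand-in for the unknown true subset, suitable for exercising the
#' pipeline at the published sample size.
#'
#' @return Character vector of 19 retained patient ids.
#' @export
analysis_subset_synthetic <- function() {
  raw <- clinical_records()
  female <- raw$sex == "f"
  drop_free <- utils::tail(raw$patient_id[female & raw$engel == "I"], 3)
  drop_improv <- utils::tail(raw$patient_id[female & raw$engel != "I"], 1)
  setdiff(raw$patient_id, c(drop_free, drop_improv))
}

# Integer-code a cohort's features against the schema; 0-rows stay empty.
# Returns list(x = n x p integer matrix (NA for missing), y = integer 1/2
# outcome (1 = seizure_free), ncat = per-feature category counts).
encode_cohort <- function(cohort, features = feature_names(cohort)) {
  x <- vapply(features, function(nm) {
    match(cohort$features[[nm]], cohort$schema[[nm]]$categories)
  }, integer(cohort$n))
  x <- matrix(as.integer(x), nrow = cohort$n,
              dimnames = list(cohort$patient_ids, features))
  list(x = x, y = as.integer(cohort$outcome),
       ncat = vapply(cohort$schema[features],
                     function(s) length(s$categories), integer(1)))
}
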