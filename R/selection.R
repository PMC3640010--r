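#' Configuration of the racing search
#'
#' @param alpha Significance level of the t-tests that eliminate a
#'   candidate subset from a lap. Default 0.05.
#' @param max_laps Cap on elimination laps; default one per feature.
#' @param paired Use a paired t-test on the per-fold error differences
#'   (the folds are shared); `FALSE` switches to an unpaired Welch test.
#' @return An object of class `race_config`.
#' @export
race_config <- function(alpha = 0.05, max_laps = Inf, paired = TRUE) {
  stopifnot(alpha > 0, alpha < 1, max_laps >= 1)
  structure(list(alpha = alpha, max_laps = max_laps, paired = isTRUE(paired)),
            class = "race_config")
}

# two-sided p for "candidate worse than incumbent" given 0/1 error vectors
race_t_pvalue <- function(err_cand, err_inc, paired = TRUE) {
  if (paired) {
    d <- err_cand - err_inc
    if (all(d == 0) || stats::sd(d) == 0) return(1)
    tt <- mean(d) / (stats::sd(d) / sqrt(length(d)))
    2 * stats::pt(-abs(tt), df = length(d) - 1)
  } else {
    if (stats::sd(err_cand) == 0 && stats::sd(err_inc) == 0) {
      return(if (mean(err_cand) == mean(err_inc)) 1 else 0)
    }
    stats::t.test(err_cand, err_inc)$p.value
  }
}

#' Backward-elimination race search over feature subsets
#'
#' Starting from the full feature set, each lap races the incumbent subset
#' against every single-deletion candidate on their per-fold LOOCV 0/1
#' error vectors. A candidate significantly *worse* than the incumbent
#' (paired t-test on the shared folds, `p < alpha`) is eliminated from the
#' lap; among the survivors, the candidate with the lowest mean error wins
#' the lap (ties to the earliest feature in subset order) and replaces the
#' incumbent if its mean error is strictly lower. The search stops when no
#' deletion improves the incumbent or only one feature remains.
#'
#' Given complete data the search is fully deterministic; missing cells
#' are imputed up front via [impute_class_conditional_mode()].
#'
#' @param cohort A [cohort_table()].
#' @param spec A [classifier_spec()].
#' @param config A [race_config()].
#' @param features Starting feature set (default: all features).
#' @return Character vector: the selected (incumbent) feature subset,
#'   never empty.
#' @export
race_search_backward <- function(cohort, spec, config = race_config(),
                                 features = feature_names(cohort)) {
  stopifnot(inherits(config, "race_config"))
  if (nlevels(droplevels(cohort$outcome)) < 2L) {
    stop("outcome is constant; the race is undefined", call. = FALSE)
  }
  if (anyNA(as.matrix(cohort$features[features]))) {
    cohort <- impute_class_conditional_mode(cohort)
  }
  evaluator <- make_loocv_evaluator(spec, cohort)
  incumbent <- features
  err_inc <- evaluator(incumbent)$errors
  laps <- 0L
  while (length(incumbent) > 1L && laps < config$max_laps) {
    laps <- laps + 1L
    cand_err <- lapply(seq_along(incumbent), function(j) {
      evaluator(incumbent[-j])$errors
    })
    means <- vapply(cand_err, mean, numeric(1))
    eliminated <- vapply(seq_along(cand_err), function(j) {
      means[j] > mean(err_inc) &&
        race_t_pvalue(cand_err[[j]], err_inc, config$paired) < config$alpha
    }, logical(1))
    if (all(eliminated)) break
    alive <- which(!eliminated)
    winner <- alive[which.min(means[alive])]  # first min: stable tie-break
    # parsimony rule: a deletion matching the incumbent's mean error wins
    # the lap, so redundant features are pruned rather than retained
    if (means[winner] <= mean(err_inc)) {
      err_inc <- cand_err[[winner]]
      incumbent <- incumbent[-winner]
    } else {
      break
    }
  }
  incumbent
}

#' Bootstrap selection-frequency ranking
#'
#' Produces B stratified bootstrap resamples of the cohort — drawing, with
#' replacement, exactly the original number of patients from each outcome
#' class — runs the backward race search on each (LOOCV on the resampled
#' dataset, duplicated rows treated as distinct instances), and counts for
#' every feature the number of resamples whose selected subset contains
#' it. Features are ranked by descending count with stable ties (original
#' feature order).
#'
#' Resample `r` seeds its own RNG stream at `seed + r`, so runs are
#' reproducible and individual resamples can be replayed in isolation.
#'
#' @param cohort A [cohort_table()]; missing cells are imputed once up
#'   front.
#' @param spec A [classifier_spec()].
#' @param B Number of bootstrap resamples (the study used 1,000).
#' @param seed Integer base seed.
#' @param config A [race_config()].
#' @return An object of class `frequency_ranking`: `counts` (named, in
#'   `[0, B]`), `order` (features by descending count), `B`, `spec`.
#' @export
bootstrap_selection_frequencies <- function(cohort, spec, B = 1000L,
                                            seed = 1L,
                                            config = race_config()) {
  stopifnot(B >= 1)
  if (anyNA(as.matrix(cohort$features))) {
    cohort <- impute_class_conditional_mode(cohort)
  }
  feats <- feature_names(cohort)
  counts <- stats::setNames(integer(length(feats)), feats)
  cls <- split(seq_len(cohort$n), cohort$outcome)
  for (r in seq_len(B)) {
    set.seed(seed + r)
    idx <- unlist(lapply(cls, function(ix) {
      ix[sample.int(length(ix), length(ix), replace = TRUE)]
    }), use.names = FALSE)
    boot <- cohort_table(sprintf("b%04d", seq_along(idx)),
                         cohort$features[idx, , drop = FALSE],
                         as.character(cohort$outcome)[idx],
                         cohort$schema)
    sel <- tryCatch(
      race_search_backward(boot, spec, config),
      error = function(e) {
        stop("race search failed on resample ", r, ": ",
             conditionMessage(e), call. = FALSE)
      })
    counts[sel] <- counts[sel] + 1L
  }
  ord <- feats[order(-counts, seq_along(feats))]
  structure(list(counts = counts, order = ord, B = as.integer(B),
                 spec = spec),
            class = "frequency_ranking")
}

#' @export
print.frequency_ranking <- function(x, ...) {
  cat("<frequency_ranking> ", x$spec$paradigm, ", B=", x$B, "\n", sep = "")
  df <- data.frame(feature = x$order, occ = unname(x$counts[x$order]))
  print(df, row.names = seq_len(nrow(df)))
  invisible(x)
}

#' @export
as.data.frame.frequency_ranking <- function(x, ...) {
  data.frame(rank = seq_along(x$order), feature = x$order,
             occ = unname(x$counts[x$order]))
}

#' Top-down incremental evaluation of ranked feature prefixes
#'
#' Evaluates, by LOOCV, the nested feature subsets formed by adding
#' features one at a time from most to least frequently selected, and
#' picks the best prefix: highest accuracy, ties resolved towards the
#' smaller subset, remaining ties towards the higher AUC.
#'
#' @param ranking A [bootstrap_selection_frequencies()] result (or any
#'   object with an `order` covering all cohort features).
#' @param cohort A fully observed [cohort_table()].
#' @param spec A [classifier_spec()].
#' @return An object of class `selection_curve`: `points` (one row per
#'   prefix size: size, accuracy, auc, f_measure), `subsets` (list of
#'   feature prefixes), `best` (chosen subset), `best_size`.
#' @export
incremental_subset_evaluation <- function(ranking, cohort, spec) {
  ord <- ranking$order
  if (!setequal(ord, feature_names(cohort))) {
    stop("ranking does not cover the cohort's features", call. = FALSE)
  }
  if (anyNA(as.matrix(cohort$features))) {
    cohort <- impute_class_conditional_mode(cohort)
  }
  p <- length(ord)
  res <- lapply(seq_len(p), function(s) {
    loocv_evaluate(spec, cohort, ord[seq_len(s)])
  })
  points <- data.frame(
    size = seq_len(p),
    accuracy = vapply(res, `[[`, numeric(1), "accuracy"),
    auc = vapply(res, `[[`, numeric(1), "auc"),
    f_measure = vapply(res, `[[`, numeric(1), "f_measure")
  )
  best <- order(-points$accuracy, points$size, -points$auc)[1L]
  structure(list(points = points,
                 subsets = lapply(seq_len(p), function(s) ord[seq_len(s)]),
                 best = ord[seq_len(best)], best_size = best,
                 spec = spec),
            class = "selection_curve")
}

#' @export
print.selection_curve <- function(x, ...) {
  cat("<selection_curve> ", x$spec$paradigm, ": best size ", x$best_size,
      " {", paste(x$best, collapse = ", "), "}\n", sep = "")
  print(x$points, row.names = FALSE)
  invisible(x)
}
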