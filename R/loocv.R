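#' Leave-one-out cross-validation of a classifier on a cohort
#'
#' Fits n models, each trained on all patients but one and tested on the
#' held-out patient. Accuracy is the mean held-out 0/1 correctness; AUC is
#' a single ROC over the n pooled held-out scores (posterior probability of
#' `seizure_free`); the F-measure and confusion counts treat `seizure_free`
#' as the positive class.
#'
#' If the cohort still contains missing cells they are imputed once on the
#' full cohort by [impute_class_conditional_mode()] before validation —
#' faithful to the original procedure but leaking outcome information into
#' the folds, so a warning is emitted. With `strict_cv = TRUE` imputation
#' happens inside each training fold instead, and the held-out case's
#' missing cells are filled with the training fold's overall (class-blind)
#' modes.
#'
#' @param spec A [classifier_spec()].
#' @param cohort A [cohort_table()] with `n >= 3` and both classes present.
#' @param features Character vector of feature names (may be empty).
#' @param strict_cv Impute within folds rather than once up front.
#' @return An object of class `cv_result`: `accuracy`, `auc`, `f_measure`,
#'   `confusion` (TP/FP/TN/FN), `fold_scores`, `fold_labels`, `n`.
#' @export
loocv_evaluate <- function(spec, cohort, features = feature_names(cohort),
                           strict_cv = FALSE) {
  stopifnot(inherits(spec, "classifier_spec"), inherits(cohort, "cohort_table"))
  if (cohort$n < 3L) stop("LOOCV needs n >= 3", call. = FALSE)
  if (nlevels(droplevels(cohort$outcome)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  has_missing <- anyNA(as.matrix(cohort$features[features]))
  if (has_missing && !strict_cv) {
    warning("missing cells imputed once on the full cohort before LOOCV; ",
            "this leaks class information across folds (use strict_cv = TRUE ",
            "to impute within folds)", call. = FALSE)
    cohort <- impute_class_conditional_mode(cohort)
  }
  if (has_missing && strict_cv) {
    scores <- numeric(cohort$n)
    labels <- character(cohort$n)
    for (i in seq_len(cohort$n)) {
      train <- impute_class_conditional_mode(
        subset_cohort(cohort, patients = -i))
      test <- impute_overall_mode(subset_cohort(cohort, patients = i),
                                  train)
      prd <- predict(fit_classifier(spec, train, features), test)
      scores[i] <- prd$score
      labels[i] <- prd$label
    }
  } else {
    sc <- make_loocv_evaluator(spec, cohort)(features)
    scores <- sc$score
    labels <- sc$label
  }
  truth <- as.character(cohort$outcome)
  cf <- confusion_counts(labels, truth)
  structure(
    list(accuracy = mean(labels == truth),
         auc = roc_auc(scores, truth),
         f_measure = f_measure(cf),
         confusion = cf,
         fold_scores = stats::setNames(scores, cohort$patient_ids),
         fold_labels = stats::setNames(labels, cohort$patient_ids),
         n = cohort$n, features = features, spec = spec),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> n=%d  accuracy=%.4f  AUC=%.4f  F=%.4f\n",
              x$n, x$accuracy, x$auc, x$f_measure))
  cat("  confusion: ",
      paste(names(x$confusion), x$confusion, sep = "=", collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

# fill a (held-out) cohort's missing cells with reference-cohort overall modes
impute_overall_mode <- function(cohort, reference) {
  feats <- cohort$features
  for (nm in names(feats)) {
    miss <- is.na(feats[[nm]])
    if (!any(miss)) next
    cats <- cohort$schema[[nm]]$categories
    obs <- reference$features[[nm]]
    counts <- table(factor(obs[!is.na(obs)], levels = cats))
    feats[[nm]][miss] <- cats[which.max(counts)]
  }
  cohort_table(cohort$patient_ids, feats, as.character(cohort$outcome),
               cohort$schema)
}

# Precompute per-case, per-feature, per-class leave-one-out log
# contributions so that the LOOCV log-posterior of any feature subset S is
# prior_term + rowSums over the columns of S. Leaving case i out only
# changes the counts of i's own categories and its class total, which is
# why a closed-form per-case adjustment suffices.
nb_loocv_precompute <- function(cohort, laplace_alpha = 1) {
  enc <- encode_cohort(cohort)
  if (anyNA(enc$x)) stop("naive Bayes requires fully observed features",
                         call. = FALSE)
  n <- cohort$n
  p <- ncol(enc$x)
  y <- enc$y
  ncls <- tabulate(y, 2L)
  G <- list(matrix(0, n, p), matrix(0, n, p))
  for (j in seq_len(p)) {
    cnt <- vapply(1:2, function(k) tabulate(enc$x[y == k, j], enc$ncat[j]),
                  numeric(enc$ncat[j]))
    cnt <- matrix(cnt, nrow = enc$ncat[j])
    for (c in 1:2) {
      own <- y == c  # holding out case i removes one count from its own cell
      num <- log(cnt[enc$x[, j], c] - as.numeric(own) + laplace_alpha)
      den <- log(ncls[c] - as.numeric(own) + laplace_alpha * enc$ncat[j])
      G[[c]][, j] <- num - den
    }
  }
  colnames(G[[1]]) <- colnames(G[[2]]) <- colnames(enc$x)
  # leave-one-out class counts; priors are unsmoothed except for folds in
  # which a class vanishes entirely (singleton class held out)
  nc1 <- ncls[1] - as.numeric(y == 1L)
  nc2 <- ncls[2] - as.numeric(y == 2L)
  degenerate <- nc1 == 0 | nc2 == 0
  prior <- cbind(log(nc1 / (n - 1)), log(nc2 / (n - 1)))
  if (any(degenerate)) {
    warning("a training fold lost an entire class; smoothing priors",
            call. = FALSE)
    prior[degenerate, 1] <- log((nc1[degenerate] + 1) / (n - 1 + 2))
    prior[degenerate, 2] <- log((nc2[degenerate] + 1) / (n - 1 + 2))
  }
  # fold majority class for tie-breaking (ties towards seizure_free)
  fold_major <- ifelse(nc2 > nc1, 2L, 1L)
  list(G1 = G[[1]], G2 = G[[2]], prior = prior, y = y,
       fold_major = fold_major, features = colnames(enc$x))
}

# held-out scores/labels/errors for a feature subset, from the precompute
nb_loocv_scores <- function(pre, features) {
  idx <- match(features, pre$features)
  if (anyNA(idx)) stop("feature absent from model", call. = FALSE)
  l1 <- pre$prior[, 1] + if (length(idx)) {
    rowSums(pre$G1[, idx, drop = FALSE])
  } else 0
  l2 <- pre$prior[, 2] + if (length(idx)) {
    rowSums(pre$G2[, idx, drop = FALSE])
  } else 0
  score <- 1 / (1 + exp(l2 - l1))
  pred <- ifelse(l1 > l2, 1L, ifelse(l1 < l2, 2L, pre$fold_major))
  list(score = score,
       label = c("seizure_free", "improvement_only")[pred],
       errors = as.numeric(pred != pre$y))
}

# Build a closure mapping a feature subset to its LOOCV held-out scores,
# labels and 0/1 errors, with per-paradigm precomputation done once so the
# race search can evaluate many subsets of the same cohort cheaply. All
# paths reproduce the fold-by-fold refit exactly (same smoothing, tie and
# fallback rules).
make_loocv_evaluator <- function(spec, cohort) {
  lv <- c("seizure_free", "improvement_only")
  switch(
    spec$paradigm,
    naive_bayes = {
      pre <- nb_loocv_precompute(cohort, spec$laplace_alpha)
      function(features) nb_loocv_scores(pre, features)
    },
    knn = {
      enc <- encode_cohort(cohort)
      n <- cohort$n
      if (spec$k > n - 1L) {
        stop("k = ", spec$k, " exceeds training size ", n - 1L,
             call. = FALSE)
      }
      mism <- lapply(seq_len(ncol(enc$x)), function(j) {
        outer(enc$x[, j], enc$x[, j], "!=") * 1L
      })
      names(mism) <- colnames(enc$x)
      y <- enc$y
      function(features) {
        D <- Reduce(`+`, mism[features], matrix(0L, n, n))
        score <- vapply(seq_len(n), function(i) {
          nn <- order(D[i, -i], seq_len(n - 1L))[seq_len(spec$k)]
          mean(y[-i][nn] == 1L)
        }, numeric(1))
        fold_major <- ifelse(tabulate(y, 2L)[2] - (y == 2L) >
                               tabulate(y, 2L)[1] - (y == 1L), 2L, 1L)
        pred <- ifelse(score > 0.5, 1L, ifelse(score < 0.5, 2L,
                                               fold_major))
        list(score = score, label = lv[pred],
             errors = as.numeric(pred != y))
      }
    },
    ridge_logistic = {
      enc <- encode_cohort(cohort)
      X <- one_hot(enc)
      # column indices of each feature's one-hot block
      blocks <- split(seq_len(ncol(X) - 1L) + 1L,
                      rep(seq_len(ncol(enc$x)), enc$ncat))
      names(blocks) <- colnames(enc$x)
      y01 <- as.numeric(enc$y == 1L)
      n <- cohort$n
      function(features) {
        cols <- c(1L, unlist(blocks[features], use.names = FALSE))
        any_unconverged <- FALSE
        score <- vapply(seq_len(n), function(i) {
          fit <- ridge_newton(X[-i, cols, drop = FALSE], y01[-i],
                              spec$ridge_lambda)
          if (!fit$converged) any_unconverged <<- TRUE
          stats::plogis(sum(X[i, cols] * fit$beta))
        }, numeric(1))
        if (any_unconverged) {
          warning("ridge logistic did not reach gradient tolerance in ",
                  "some folds (separable data at tiny lambda?)",
                  call. = FALSE)
        }
        fold_major <- ifelse(tabulate(enc$y, 2L)[2] - (enc$y == 2L) >
                               tabulate(enc$y, 2L)[1] - (enc$y == 1L),
                             2L, 1L)
        pred <- ifelse(score > 0.5, 1L, ifelse(score < 0.5, 2L,
                                               fold_major))
        list(score = score, label = lv[pred],
             errors = as.numeric(pred != enc$y))
      }
    })
}

# per-fold 0/1 LOOCV error vector for any paradigm; `evaluator` (from
# make_loocv_evaluator) short-circuits the refit
loocv_errors <- function(spec, cohort, features, evaluator = NULL) {
  if (is.null(evaluator)) evaluator <- make_loocv_evaluator(spec, cohort)
  evaluator(features)$errors
}
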