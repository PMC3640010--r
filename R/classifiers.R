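#' Specify a classification paradigm and its hyperparameters
#'
#' Three supervised paradigms operate on the categorical features: a
#' categorical naive Bayes, a ridge-penalised logistic regression on one-hot
#' encodings, and a k-nearest-neighbour vote under Hamming (feature
#' mismatch) distance.
#'
#' @param paradigm One of `"naive_bayes"`, `"ridge_logistic"`, `"knn"`.
#' @param laplace_alpha Laplace smoothing pseudo-count added to each
#'   class-conditional category count of the naive Bayes (class priors are
#'   left unsmoothed). Default 1.
#' @param ridge_lambda Ridge penalty on the logistic slopes (the intercept
#'   is unpenalised). Default `1e-8`, a conventional near-unpenalised value.
#' @param k Neighbour count for k-NN; must be a positive integer, odd by
#'   convention to reduce vote ties. Default 3.
#' @return An object of class `classifier_spec`.
#' @export
#' @examples
#' classifier_spec("naive_bayes")
#' classifier_spec("knn", k = 5)
classifier_spec <- function(paradigm = c("naive_bayes", "ridge_logistic",
                                         "knn"),
                            laplace_alpha = 1, ridge_lambda = 1e-8, k = 3) {
  paradigm <- match.arg(paradigm)
  stopifnot(laplace_alpha >= 0, ridge_lambda >= 0, k >= 1, k == round(k))
  structure(list(paradigm = paradigm, laplace_alpha = laplace_alpha,
                 ridge_lambda = ridge_lambda, k = as.integer(k)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- switch(x$paradigm,
               naive_bayes = paste0("alpha=", x$laplace_alpha),
               ridge_logistic = paste0("lambda=", x$ridge_lambda),
               knn = paste0("k=", x$k))
  cat("<classifier_spec> ", x$paradigm, " (", hp, ")\n", sep = "")
  invisible(x)
}

fit_classifier <- function(spec, cohort, features) {
  switch(spec$paradigm,
         naive_bayes = fit_naive_bayes(cohort, features,
                                       laplace_alpha = spec$laplace_alpha),
         ridge_logistic = fit_ridge_logistic(cohort, features,
                                             ridge_lambda = spec$ridge_lambda),
         knn = make_knn(cohort, features, k = spec$k))
}

# Smoothed-if-degenerate class priors: unsmoothed n_c/n normally; if a class
# is absent from the training fold, fall back to add-one smoothing so the
# posterior stays proper, with a warning.
class_priors <- function(y, n_levels = 2L) {
  counts <- tabulate(y, n_levels)
  if (any(counts == 0L)) {
    warning("a training fold lost an entire class; smoothing priors",
            call. = FALSE)
    return((counts + 1) / (sum(counts) + n_levels))
  }
  counts / sum(counts)
}

#' Fit a categorical naive Bayes classifier
#'
#' Standard naive Bayes under the conditional-independence assumption:
#' class priors are empirical class frequencies (unsmoothed), and each
#' feature's class-conditional category probabilities are Laplace-smoothed
#' counts, \eqn{(n_{c,j,v} + \alpha) / (n_c + \alpha m_j)} with \eqn{m_j}
#' the category count of feature j, so no category ever has zero mass.
#' With an empty feature set the posterior equals the prior.
#'
#' @param train A fully observed (imputed) [cohort_table()].
#' @param features Character vector of feature names to use (may be empty).
#' @param laplace_alpha Smoothing pseudo-count, default 1.
#' @return A model of class `nb_model` with a [predict()] method returning
#'   a data frame of `score` (posterior probability of `seizure_free`) and
#'   `label`.
#' @export
fit_naive_bayes <- function(train, features, laplace_alpha = 1) {
  stopifnot(train$n > 0L)
  enc <- encode_cohort(train, features)
  if (anyNA(enc$x)) stop("naive Bayes requires fully observed features",
                         call. = FALSE)
  priors <- class_priors(enc$y)
  cond <- lapply(seq_along(features), function(j) {
    cnt <- vapply(1:2, function(k) {
      tabulate(enc$x[enc$y == k, j], enc$ncat[j])
    }, numeric(enc$ncat[j]))
    cnt <- matrix(cnt, nrow = enc$ncat[j])
    t(t(cnt + laplace_alpha) /
        (colSums(cnt) + laplace_alpha * enc$ncat[j]))
  })
  names(cond) <- features
  structure(list(priors = priors, cond = cond, features = features,
                 schema = train$schema[features],
                 majority = which.max(tabulate(enc$y, 2L))),
            class = "nb_model")
}

#' @export
predict.nb_model <- function(object, newdata, ...) {
  enc <- encode_cohort(newdata, object$features)
  loglik <- matrix(rep(log(object$priors), each = newdata$n), ncol = 2)
  for (j in seq_along(object$features)) {
    tab <- object$cond[[j]]
    if (length(object$features)) {
      loglik <- loglik + log(tab[enc$x[, j, drop = TRUE], , drop = FALSE])
    }
  }
  post <- exp(loglik - apply(loglik, 1, max))
  post <- post / rowSums(post)
  finish_prediction(post[, 1], object$majority)
}

# score = P(seizure_free); exact 0.5 ties go to the training majority class
finish_prediction <- function(score, majority) {
  label <- ifelse(score > 0.5, "seizure_free",
                  ifelse(score < 0.5, "improvement_only",
                         c("seizure_free", "improvement_only")[majority]))
  data.frame(score = score, label = label, stringsAsFactors = FALSE)
}

# One-hot design matrix (intercept + one indicator per category of each
# feature). Full encoding is deliberately redundant; the ridge penalty
# makes the optimum unique and symmetric across categories.
one_hot <- function(enc) {
  n <- nrow(enc$x)
  cols <- list(`(Intercept)` = rep(1, n))
  for (j in seq_len(ncol(enc$x))) {
    for (v in seq_len(enc$ncat[j])) {
      cols[[paste0(colnames(enc$x)[j], "=", v)]] <-
        as.numeric(enc$x[, j] == v)
    }
  }
  do.call(cbind, cols)
}

# Penalised log-likelihood of binary logistic regression; y01 in {0,1}
ridge_logistic_objective <- function(beta, X, y01, lambda) {
  eta <- drop(X %*% beta)
  sum(y01 * eta - log1p(exp(eta))) - lambda / 2 * sum(beta[-1]^2)
}

# Newton maximiser of the penalised likelihood with step halving; column 1
# of X is the unpenalised intercept. A single-class response falls back to
# a smoothed intercept-only fit with a warning.
ridge_newton <- function(X, y01, lambda, tol = 1e-8, max_iter = 200L) {
  p <- ncol(X)
  pen <- c(0, rep(lambda, p - 1L))
  beta <- numeric(p)
  if (length(unique(y01)) < 2L) {
    warning("a training fold lost an entire class; intercept-only fallback",
            call. = FALSE)
    rate <- (sum(y01) + 0.5) / (length(y01) + 1)
    beta[1] <- log(rate / (1 - rate))
    return(list(beta = beta, converged = TRUE))
  }
  converged <- FALSE
  obj <- ridge_logistic_objective(beta, X, y01, lambda)
  for (iter in seq_len(max_iter)) {
    mu <- stats::plogis(drop(X %*% beta))
    grad <- drop(crossprod(X, y01 - mu)) - pen * beta
    if (sqrt(sum(grad^2)) < tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + pen
    step <- solve(H, grad)
    # step halving keeps the objective non-decreasing on hard geometry
    for (h in 0:30) {
      cand <- beta + step / 2^h
      new_obj <- ridge_logistic_objective(cand, X, y01, lambda)
      if (new_obj >= obj - 1e-12) break
    }
    beta <- cand
    obj <- new_obj
  }
  list(beta = beta, converged = converged)
}

#' Fit a ridge-penalised logistic regression on one-hot categories
#'
#' Maximises the penalised Bernoulli log-likelihood
#' \eqn{\ell(\beta) - \frac{\lambda}{2}\lVert\beta_{-0}\rVert^2} (intercept
#' unpenalised) by Newton iterations with step halving, to a gradient-norm
#' tolerance of 1e-8 or at most 200 iterations. Every category of every
#' selected feature receives its own indicator column; the ridge penalty
#' resolves the resulting redundancy. The positive class (`seizure_free`)
#' is coded 1.
#'
#' @param train A fully observed [cohort_table()].
#' @param features Character vector of feature names (may be empty:
#'   intercept-only model).
#' @param ridge_lambda Penalty \eqn{\lambda \ge 0}; default `1e-8`.
#' @return A model of class `ridge_model`; `converged` is `FALSE` (with a
#'   warning at fit time) if the gradient tolerance was not met, which can
#'   occur on separable data at vanishing \eqn{\lambda}.
#' @export
fit_ridge_logistic <- function(train, features, ridge_lambda = 1e-8) {
  enc <- encode_cohort(train, features)
  if (anyNA(enc$x)) stop("logistic regression requires fully observed features",
                         call. = FALSE)
  X <- one_hot(enc)
  y01 <- as.numeric(enc$y == 1L)  # seizure_free = 1
  fit <- ridge_newton(X, y01, ridge_lambda)
  if (!fit$converged) {
    warning("ridge logistic did not reach gradient tolerance ",
            "(separable data at tiny lambda?)", call. = FALSE)
  }
  beta <- stats::setNames(fit$beta, colnames(X))
  structure(list(beta = beta, features = features,
                 converged = fit$converged,
                 schema = train$schema[features],
                 majority = which.max(tabulate(enc$y, 2L))),
            class = "ridge_model")
}

#' @export
predict.ridge_model <- function(object, newdata, ...) {
  enc <- encode_cohort(newdata, object$features)
  X <- one_hot(enc)
  finish_prediction(stats::plogis(drop(X %*% object$beta)), object$majority)
}

#' Build a lazy k-nearest-neighbour model on categorical features
#'
#' Scores a query by the Hamming (mismatch-count) distance over the
#' selected features, takes the `k` nearest training rows — distance ties
#' broken by original row order — and votes; the returned score is the
#' fraction of the k votes for `seizure_free`, and vote ties go to the
#' training-set majority class.
#'
#' @param train A fully observed [cohort_table()].
#' @param features Character vector of feature names.
#' @param k Neighbour count, `1 <= k <= n - 1` at prediction from a
#'   leave-one-out perspective (`k <= n` is enforced at fit).
#' @return A model of class `knn_model`.
#' @export
make_knn <- function(train, features, k = 3) {
  enc <- encode_cohort(train, features)
  if (anyNA(enc$x)) stop("k-NN requires fully observed features",
                         call. = FALSE)
  if (k > train$n) stop("k = ", k, " exceeds training size ", train$n,
                        call. = FALSE)
  structure(list(x = enc$x, y = enc$y, k = as.integer(k),
                 features = features, schema = train$schema[features],
                 majority = which.max(tabulate(enc$y, 2L))),
            class = "knn_model")
}

#' @export
predict.knn_model <- function(object, newdata, ...) {
  enc <- encode_cohort(newdata, object$features)
  ntrain <- nrow(object$x)
  score <- vapply(seq_len(newdata$n), function(i) {
    d <- if (length(object$features)) {
      colSums(t(object$x) != enc$x[i, ])
    } else {
      numeric(ntrain)
    }
    nn <- order(d, seq_len(ntrain))[seq_len(object$k)]
    mean(object$y[nn] == 1L)
  }, numeric(1))
  finish_prediction(score, object$majority)
}
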