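#' Fit a mixture of independent multinomials by EM
#'
#' Soft clustering of categorical profiles: each of the K components owns
#' one category-probability table per feature, features are conditionally
#' independent given the component, and the E-step returns per-case
#' posterior memberships (responsibilities) rather than hard assignments.
#' The M-step adds a small pseudo-count `epsilon` to every category count
#' so no category ever locks at zero probability. EM runs to a relative
#' log-likelihood change below `tol` (or `max_iter`), and the best of
#' `restarts` random initialisations — responsibilities drawn from a
#' symmetric Dirichlet — is returned by final log-likelihood.
#'
#' @param cohort A fully observed (imputed) [cohort_table()].
#' @param K Number of components, `1 <= K <= n`.
#' @param seed Integer seed governing all restarts.
#' @param restarts Number of random initialisations; default 10.
#' @param epsilon M-step smoothing pseudo-count; default 1e-6.
#' @param tol Relative log-likelihood convergence tolerance; default 1e-8.
#' @param max_iter Iteration cap per restart; default 500.
#' @return An object of class `mixture_model`: `K`, `weights`, `theta`
#'   (per feature, a category x component probability matrix),
#'   `responsibilities` (n x K), `loglik`, `loglik_trace` (best restart),
#'   `n_iter`, `converged`.
#' @export
fit_multinomial_mixture <- function(cohort, K = 2L, seed = 1L,
                                    restarts = 10L, epsilon = 1e-6,
                                    tol = 1e-8, max_iter = 500L) {
  stopifnot(K >= 1L)
  if (K > cohort$n) stop("K = ", K, " exceeds n = ", cohort$n, call. = FALSE)
  enc <- encode_cohort(cohort)
  if (anyNA(enc$x)) stop("mixture fitting requires fully observed features",
                         call. = FALSE)
  n <- cohort$n
  p <- ncol(enc$x)
  set.seed(seed)
  best <- NULL
  for (rs in seq_len(restarts)) {
    # symmetric Dirichlet(1) rows: normalised exponentials
    resp <- matrix(stats::rexp(n * K), n, K)
    resp <- resp / rowSums(resp)
    trace <- numeric(0)
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      # M-step
      w <- colMeans(resp)
      if (any(w < 1e-6)) {
        warning("degenerate mixture component (weight < 1e-6); smoothed",
                call. = FALSE)
        w <- (w + 1e-6) / sum(w + 1e-6)
      }
      theta <- lapply(seq_len(p), function(j) {
        tab <- vapply(seq_len(K), function(k) {
          cnt <- vapply(seq_len(enc$ncat[j]), function(v) {
            sum(resp[enc$x[, j] == v, k])
          }, numeric(1))
          (cnt + epsilon) / (sum(cnt) + epsilon * enc$ncat[j])
        }, numeric(enc$ncat[j]))
        matrix(tab, nrow = enc$ncat[j])
      })
      # E-step
      logk <- matrix(rep(log(w), each = n), n, K)
      for (j in seq_len(p)) {
        logk <- logk + log(theta[[j]][enc$x[, j], , drop = FALSE])
      }
      mx <- apply(logk, 1, max)
      lse <- mx + log(rowSums(exp(logk - mx)))
      resp <- exp(logk - lse)
      ll <- sum(lse)
      trace <- c(trace, ll)
      if (iter > 1L &&
          abs(ll - trace[iter - 1L]) <=
            tol * (abs(trace[iter - 1L]) + 1e-12)) {
        converged <- TRUE
        break
      }
    }
    if (is.null(best) || ll > best$loglik) {
      names(theta) <- colnames(enc$x)
      best <- list(K = as.integer(K), weights = w, theta = theta,
                   responsibilities = resp, loglik = ll,
                   loglik_trace = trace, n_iter = length(trace),
                   converged = converged)
    }
  }
  rownames(best$responsibilities) <- cohort$patient_ids
  structure(best, class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("<mixture_model> K=%d  loglik=%.4f  (%d EM iterations%s)\n",
              x$K, x$loglik, x$n_iter,
              if (x$converged) "" else ", not converged"))
  cat("  weights:", sprintf("%.4f", x$weights), "\n")
  invisible(x)
}

#' Agreement between a two-cluster soft assignment and binary labels
#'
#' Hard-assigns each case to its maximum-responsibility cluster (exact
#' 0.5 ties go to cluster 0 and are flagged), chooses the cluster-to-label
#' mapping that maximises matches, and reports the correct count, the
#' per-cluster label composition and the misassigned case ids.
#'
#' @param responsibilities n x 2 matrix (or data frame) of cluster
#'   membership probabilities; rows must sum to 1.
#' @param labels Binary outcome labels, length n.
#' @return An object of class `cluster_agreement`: `n_correct`,
#'   `misassigned` (case ids), `assignment` (0/1 per case), `mapping`
#'   (label assigned to cluster 0 and 1), `composition` (cluster x label
#'   table), `tied` (flagged ids).
#' @export
cluster_agreement <- function(responsibilities, labels) {
  r <- as.matrix(responsibilities)
  stopifnot(ncol(r) == 2L)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(r))
  ids <- rownames(r)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(r)))
  tied <- r[, 1] == r[, 2]
  assign <- ifelse(r[, 1] >= r[, 2], 0L, 1L)  # ties to cluster 0
  lv <- unique(labels)
  stopifnot(length(lv) == 2L)
  match_a <- sum((assign == 0L & labels == lv[1]) |
                   (assign == 1L & labels == lv[2]))
  match_b <- sum((assign == 0L & labels == lv[2]) |
                   (assign == 1L & labels == lv[1]))
  mapping <- if (match_a >= match_b) c(`0` = lv[1], `1` = lv[2]) else
    c(`0` = lv[2], `1` = lv[1])
  correct <- assign == ifelse(labels == mapping[["0"]], 0L, 1L)
  structure(
    list(n_correct = sum(correct),
         n = nrow(r),
         misassigned = ids[!correct],
         assignment = stats::setNames(assign, ids),
         mapping = mapping,
         composition = table(cluster = assign, label = labels),
         tied = ids[tied]),
    class = "cluster_agreement")
}

#' @export
print.cluster_agreement <- function(x, ...) {
  cat("<cluster_agreement> ", x$n_correct, "/", x$n, " correct; ",
      "misassigned: {", paste(x$misassigned, collapse = ", "), "}\n",
      sep = "")
  print(x$composition)
  invisible(x)
}
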