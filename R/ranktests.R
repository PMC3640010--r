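#' @name rank_tests
#' @title Exact tie-aware Wilcoxon tests on ordinal categories
#'
#' @description
#' Clinical categories are coded to ordinal ranks (schema listing order)
#' and compared with rank tests whose null distributions are computed
#' *exactly* in the presence of ties: tied observations receive midranks,
#' and the permutation null is enumerated by dynamic programming over the
#' doubled (hence integer) midranks. The two-sided p-value doubles the
#' smaller tail — including the observed statistic — and is capped at 1,
#' so it can never fall below the point mass of the observed value.
NULL

# distribution of the sum of k values drawn without replacement from r2
# (integer scores): returns counts over sums 0..sum(r2)
choose_sum_counts <- function(r2, k) {
  total <- sum(r2)
  f <- matrix(0, nrow = k + 1L, ncol = total + 1L)
  f[1L, 1L] <- 1
  for (v in r2) {
    for (c in seq.int(k, 1L)) {  # descending: each item used at most once
      f[c + 1L, (v + 1L):(total + 1L)] <-
        f[c + 1L, (v + 1L):(total + 1L)] + f[c, 1L:(total + 1L - v)]
    }
  }
  f[k + 1L, ]
}

# distribution of the sum over all sign subsets of integer scores r2
sign_sum_counts <- function(r2) {
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (v in r2) {
    f[(v + 1L):(total + 1L)] <- f[(v + 1L):(total + 1L)] +
      f[1L:(total + 1L - v)]
  }
  f
}

rank_test_result <- function(statistic, p, method, n1, n2, m = NULL) {
  structure(list(statistic = statistic, p_two_sided = p, method = method,
                 n1 = n1, n2 = n2, m = m),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("<rank_test_result> W=%.1f  p=%.4g  (%s, n1=%d, n2=%d)\n",
              x$statistic, x$p_two_sided, x$method, x$n1, x$n2))
  invisible(x)
}

#' Exact two-sample Wilcoxon rank-sum test with midranks
#'
#' Tests whether two groups of ordinal values come from a distribution
#' with the same median. Ties across the pooled sample receive midranks;
#' the statistic is the rank sum of the smaller group (first group on
#' equal sizes), and its exact permutation null is enumerated by dynamic
#' programming over tie-group compositions whenever the total sample size
#' is at most `exact_limit`, falling back to the tie-corrected normal
#' approximation above it.
#'
#' @param group_a,group_b Non-empty numeric vectors of ordinal ranks.
#' @param exact_limit Largest pooled n for which the exact null is
#'   enumerated; default 25.
#' @return A `rank_test_result` with fields `statistic`, `p_two_sided`,
#'   `method` (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @export
#' @examples
#' exact_rank_sum_test(c(1, 2), c(3))  # p = 2/3 by 3-way enumeration
exact_rank_sum_test <- function(group_a, group_b, exact_limit = 25L) {
  n1 <- length(group_a)
  n2 <- length(group_b)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty",
                                 call. = FALSE)
  pooled <- c(group_a, group_b)
  n <- n1 + n2
  r <- rank(pooled)
  # statistic group: the smaller one (group_a on ties)
  if (n2 < n1) {
    k <- n2
    W <- sum(r[(n1 + 1L):n])
  } else {
    k <- n1
    W <- sum(r[seq_len(n1)])
  }
  r2 <- as.integer(round(2 * r))
  W2 <- as.integer(round(2 * W))
  if (n <= exact_limit) {
    f <- choose_sum_counts(r2, k)
    tot <- choose(n, k)
    p_le <- sum(f[seq_len(W2 + 1L)]) / tot
    p_ge <- sum(f[(W2 + 1L):length(f)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- k * (n + 1) / 2
    ties <- table(pooled)
    sig2 <- k * (n - k) / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (W - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  rank_test_result(W, p, method, n1, n2)
}

#' Exact Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are discarded (Wilcoxon's original convention);
#' absolute differences receive midranks, and the statistic is the sum of
#' the ranks of the positive differences. The exact null enumerates all
#' \eqn{2^m} sign assignments (by dynamic programming) when the nonzero
#' count m is at most `exact_limit`, otherwise a tie-corrected normal
#' approximation is used. Two-sided p by tail doubling, capped at 1.
#'
#' @param deltas Numeric vector of paired differences (post minus pre, on
#'   ordinal ranks).
#' @param exact_limit Largest m enumerated exactly; default 20.
#' @return A `rank_test_result`; `m` is the nonzero count (`m = 0`, all
#'   ties, yields p = 1).
#' @export
#' @examples
#' exact_signed_rank_test(c(1, 2, 3))  # p = 2/8
exact_signed_rank_test <- function(deltas, exact_limit = 20L) {
  d <- deltas[deltas != 0]
  m <- length(d)
  if (m == 0L) {
    return(rank_test_result(0, 1, "exact", length(deltas), length(deltas),
                            m = 0L))
  }
  r <- rank(abs(d))
  Wpos <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))
  W2 <- as.integer(round(2 * Wpos))
  if (m <= exact_limit) {
    f <- sign_sum_counts(r2)
    tot <- 2^m
    p_le <- sum(f[seq_len(W2 + 1L)]) / tot
    p_ge <- sum(f[(W2 + 1L):length(f)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(abs(d))
    sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (Wpos - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  rank_test_result(Wpos, p, method, length(deltas), length(deltas), m = m)
}

#' Class-stratified contingency of a categorical feature
#'
#' @param cohort A fully observed (imputed) [cohort_table()].
#' @param feature Feature name.
#' @param groups Optional grouping factor overriding the outcome (e.g. a
#'   cluster assignment); must have two levels.
#' @return Data frame with one row per category: `category` plus one count
#'   column per group level.
#' @export
stratified_contingency <- function(cohort, feature, groups = NULL) {
  if (!feature %in% feature_names(cohort)) {
    stop("unknown feature '", feature, "'", call. = FALSE)
  }
  col <- cohort$features[[feature]]
  if (anyNA(col)) {
    stop("feature '", feature, "' has missing cells; impute first",
         call. = FALSE)
  }
  g <- if (is.null(groups)) cohort$outcome else as.factor(groups)
  tab <- table(factor(col, levels = cohort$schema[[feature]]$categories), g)
  out <- data.frame(category = rownames(tab), stringsAsFactors = FALSE)
  for (lv in colnames(tab)) out[[lv]] <- as.integer(tab[, lv])
  out
}

# ordinal codes of a feature column (schema listing order)
ordinal_codes <- function(cohort, feature) {
  match(cohort$features[[feature]], cohort$schema[[feature]]$categories)
}

#' Per-feature rank-sum tests against the outcome
#'
#' Codes every feature to its ordinal ranks, runs the exact tie-aware
#' rank-sum test between the two outcome groups (or an alternative
#' two-level grouping such as a cluster assignment), and reports features
#' in order of increasing p-value with a significance flag. No
#' multiple-testing correction is applied by default, matching the
#' original analysis across 19 features; set `p_adjust` to a
#' [stats::p.adjust()] method to correct.
#'
#' @param cohort A fully observed [cohort_table()].
#' @param features Features to test (default all).
#' @param alpha Significance level for the flag; default 0.05.
#' @param p_adjust Multiple-testing correction method, default `"none"`.
#' @param groups Optional two-level grouping factor; default the outcome.
#' @return Data frame: `feature`, `statistic`, `p`, `significant`, sorted
#'   by ascending p (stable in the input feature order).
#' @export
rank_table <- function(cohort, features = feature_names(cohort),
                       alpha = 0.05, p_adjust = "none", groups = NULL) {
  g <- if (is.null(groups)) cohort$outcome else as.factor(groups)
  stopifnot(nlevels(droplevels(g)) == 2L)
  lv <- levels(droplevels(g))
  rows <- lapply(features, function(nm) {
    v <- ordinal_codes(cohort, nm)
    if (anyNA(v)) stop("feature '", nm, "' has missing cells; impute first",
                       call. = FALSE)
    tst <- exact_rank_sum_test(v[g == lv[1L]], v[g == lv[2L]])
    data.frame(feature = nm, statistic = tst$statistic,
               p = tst$p_two_sided, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = p_adjust)
  out$significant <- out$p_adjusted < alpha
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
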