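# in-code fixtures shared across the suite

# quick schema: one entry per feature, categories given as character vectors
make_schema <- function(...) {
  cols <- list(...)
  out <- lapply(names(cols), function(nm) {
    feature_schema(nm, cols[[nm]], ordinal = TRUE)
  })
  stats::setNames(out, names(cols))
}

# cohort from plain columns; outcome defaults to an alternating 2-class label
make_cohort <- function(..., outcome = NULL, ids = NULL) {
  cols <- list(...)
  n <- length(cols[[1]])
  if (is.null(outcome)) {
    outcome <- rep(c("seizure_free", "improvement_only"), length.out = n)
  }
  if (is.null(ids)) ids <- sprintf("p%03d", seq_len(n))
  sch <- lapply(names(cols), function(nm) {
    feature_schema(nm, sort(unique(cols[[nm]][!is.na(cols[[nm]])])),
                   ordinal = TRUE)
  })
  cohort_table(ids, as.data.frame(cols, stringsAsFactors = FALSE),
               outcome, stats::setNames(sch, names(cols)))
}

# 14 seizure_free / 5 improvement_only cohort with a constant feature
baseline_cohort_14_5 <- function() {
  make_cohort(f = rep("A", 19),
              outcome = rep(c("seizure_free", "improvement_only"),
                            c(14, 5)))
}

# cohort in which `sep` copies the outcome and the rest is iid noise
separable_cohort <- function(n = 20, noise = 3, seed = 1) {
  set.seed(seed)
  outcome <- rep(c("seizure_free", "improvement_only"), length.out = n)
  cols <- list(sep = ifelse(outcome == "seizure_free", "A", "B"))
  for (j in seq_len(noise)) {
    cols[[paste0("noise", j)]] <- sample(c("A", "B"), n, replace = TRUE)
  }
  sch <- stats::setNames(
    lapply(names(cols), function(nm) feature_schema(nm, c("A", "B"))),
    names(cols))
  cohort_table(sprintf("p%03d", seq_len(n)),
               as.data.frame(cols, stringsAsFactors = FALSE), outcome, sch)
}

# enumeration oracle for the exact tie-aware two-sample test: all C(n, k)
# assignments of the pooled values to the statistic group
enumerate_rank_sum_p <- function(group_a, group_b) {
  pooled <- c(group_a, group_b)
  n <- length(pooled)
  r <- rank(pooled)
  n1 <- length(group_a)
  n2 <- length(group_b)
  if (n2 < n1) {
    k <- n2
    W <- sum(r[(n1 + 1):n])
  } else {
    k <- n1
    W <- sum(r[seq_len(n1)])
  }
  sums <- colSums(matrix(r[utils::combn(n, k)], nrow = k))
  p_le <- mean(sums <= W + 1e-9)
  p_ge <- mean(sums >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# trapezoidal integration of the empirical ROC curve (AUC oracle)
trapezoid_auc <- function(scores, labels, positive = "seizure_free") {
  pos <- as.character(labels) == positive
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[!pos] >= t), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
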