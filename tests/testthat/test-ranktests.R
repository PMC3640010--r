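test_that("small-sample rank-sum cases match hand enumeration", {
  expect_equal(exact_rank_sum_test(c(2, 2, 2), c(2, 2))$p_two_sided, 1)
  expect_equal(exact_rank_sum_test(c(1, 2), c(3))$p_two_sided, 2 / 3,
               tolerance = 1e-12)
  expect_error(exact_rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("the exact tie-aware rank-sum distribution equals full
           enumeration on random tied datasets", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    n1 <- sample(2:(n - 2), 1)
    vals <- sample(1:4, n, replace = TRUE)  # heavy ties
    a <- vals[seq_len(n1)]
    b <- vals[(n1 + 1):n]
    expect_equal(exact_rank_sum_test(a, b)$p_two_sided,
                 enumerate_rank_sum_p(a, b), tolerance = 1e-12)
  }
})

test_that("without ties the exact rank-sum p matches the reference
           implementation at boundary sizes", {
  set.seed(7)
  for (sizes in list(c(3, 5), c(4, 4))) {
    vals <- sample(seq_len(sum(sizes)))  # distinct ranks, no ties
    a <- vals[seq_len(sizes[1])]
    b <- vals[-seq_len(sizes[1])]
    ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(exact_rank_sum_test(a, b)$p_two_sided, ref,
                 tolerance = 1e-12)
  }
})

test_that("rank-sum p is invariant under monotone recoding and never below
           the observed point mass", {
  set.seed(5)
  for (rep in 1:10) {
    a <- sample(1:3, 6, replace = TRUE)
    b <- sample(1:3, 4, replace = TRUE)
    p <- exact_rank_sum_test(a, b)$p_two_sided
    # strictly increasing recode 1,2,3 -> 2, 10, 11
    recode <- c(2, 10, 11)
    expect_equal(exact_rank_sum_test(recode[a], recode[b])$p_two_sided, p,
                 tolerance = 1e-12)
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("signed-rank enumeration handles zeros, ties and symmetry", {
  all_zero <- exact_signed_rank_test(c(0, 0, 0))
  expect_equal(all_zero$p_two_sided, 1)
  expect_equal(all_zero$m, 0L)
  expect_equal(exact_signed_rank_test(c(1, 2, 3))$p_two_sided, 0.25,
               tolerance = 1e-12)
  expect_equal(exact_signed_rank_test(c(1, -1))$p_two_sided, 1,
               tolerance = 1e-12)
  # no ties: agree with the reference exact implementation
  set.seed(9)
  d <- sample(c(-1, 1), 8, TRUE) * sample(seq(1, 8))
  ref <- stats::wilcox.test(d, exact = TRUE)$p.value
  expect_equal(exact_signed_rank_test(d)$p_two_sided, ref,
               tolerance = 1e-12)
})

test_that("stratified contingencies count categories by class", {
  g <- contingency_groups(reported_contingencies()$Side)
  co <- make_cohort(Side = c("Left", "Right")[c(g$seizure_free,
                                                g$improvement_only)],
                    outcome = rep(c("seizure_free", "improvement_only"),
                                  c(14, 5)))
  tab <- stratified_contingency(co, "Side")
  expect_equal(tab$seizure_free, c(5L, 9L))
  expect_equal(tab$improvement_only, c(5L, 0L))
  expect_equal(sum(tab$seizure_free) + sum(tab$improvement_only), 19)

  one <- make_cohort(f = rep("A", 19),
                     outcome = rep(c("seizure_free", "improvement_only"),
                                   c(14, 5)))
  tab1 <- stratified_contingency(one, "f")
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$seizure_free, 14L)
  expect_error(stratified_contingency(one, "nope"), "unknown feature")
})

test_that("the rank table flags the three separating features and orders by
           p-value", {
  cont <- reported_contingencies()
  cols <- lapply(cont, function(tab) {
    g <- contingency_groups(tab)
    tab$category[c(g$seizure_free, g$improvement_only)]
  })
  sch <- list(
    Side = feature_schema("Side", cont$Side$category),
    PStyle = feature_schema("PStyle", cont$PStyle$category, ordinal = TRUE),
    PIQ = feature_schema("PIQ", cont$PIQ$category, ordinal = TRUE))
  co <- cohort_table(sprintf("p%02d", 1:19),
                     as.data.frame(cols, check.names = FALSE,
                                   stringsAsFactors = FALSE),
                     rep(c("seizure_free", "improvement_only"), c(14, 5)),
                     sch)
  rt <- rank_table(co)
  expect_equal(rt$feature, c("PStyle", "Side", "PIQ"))  # increasing p
  expect_true(all(rt$significant))
  expect_equal(nrow(rank_table(co, features = "Side")), 1L)
  # Holm correction is available but off by default
  rt_holm <- rank_table(co, p_adjust = "holm")
  expect_true(all(rt_holm$p_adjusted >= rt$p))
})

test_that("pure-noise features are flagged at roughly the nominal rate", {
  set.seed(77)
  flags <- 0L
  total <- 0L
  for (sim in 1:40) {
    cols <- lapply(1:5, function(j) sample(letters[1:3], 60, TRUE))
    names(cols) <- paste0("f", 1:5)
    co <- do.call(make_cohort, c(cols, list(
      outcome = sample(rep(c("seizure_free", "improvement_only"),
                           c(40, 20))))))
    rt <- rank_table(co)
    flags <- flags + sum(rt$significant)
    total <- total + nrow(rt)
  }
  rate <- flags / total  # 200 tests; binomial se ~ 0.015
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / total))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
})
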