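test_that("a single-component mixture reduces to empirical category
           frequencies", {
  co <- make_cohort(f = c("A", "A", "B", "A"), g = c("B", "B", "B", "A"))
  mm <- fit_multinomial_mixture(co, K = 1, seed = 2, restarts = 2)
  expect_equal(unname(mm$responsibilities[, 1]), rep(1, 4))
  expect_equal(mm$theta$f[, 1], c(3, 1) / 4, tolerance = 1e-5)
  expect_equal(mm$theta$g[, 1], c(1, 3) / 4, tolerance = 1e-5)
  expect_error(fit_multinomial_mixture(co, K = 5), "exceeds")
})

test_that("EM separates two disjoint deterministic profiles perfectly", {
  profile <- rep(c("A", "B"), each = 10)
  co <- make_cohort(f = profile, g = profile, h = profile,
                    outcome = rep(c("seizure_free", "improvement_only"),
                                  each = 10))
  mm <- fit_multinomial_mixture(co, K = 2, seed = 4, restarts = 5)
  hard <- apply(mm$responsibilities, 1, which.max)
  expect_equal(length(unique(hard[1:10])), 1L)
  expect_equal(length(unique(hard[11:20])), 1L)
  expect_true(hard[1] != hard[20])
  expect_true(all(pmax(mm$responsibilities[, 1],
                       mm$responsibilities[, 2]) > 1 - 1e-6))
  ag <- cluster_agreement(mm$responsibilities, co$outcome)
  expect_equal(ag$n_correct, 20L)
})

test_that("every EM fit has a monotone log-likelihood and normalised
           responsibilities", {
  set.seed(15)
  for (rep in 1:4) {
    cols <- lapply(1:4, function(j) sample(letters[1:3], 25, TRUE))
    names(cols) <- paste0("f", 1:4)
    co <- do.call(make_cohort, cols)
    mm <- fit_multinomial_mixture(co, K = sample(2:3, 1), seed = rep,
                                  restarts = 3)
    expect_true(all(diff(mm$loglik_trace) >= -1e-10))
    expect_equal(unname(rowSums(mm$responsibilities)), rep(1, 25),
                 tolerance = 1e-12)
    expect_equal(sum(mm$weights), 1, tolerance = 1e-12)
    for (th in mm$theta) {
      expect_equal(unname(colSums(th)), rep(1, mm$K), tolerance = 1e-12)
    }
  }
})

test_that("the fit is invariant to case order up to component relabelling", {
  set.seed(33)
  # well-separated blocks so the optimum is sharp and unique up to label
  block <- rep(c("A", "B"), each = 12)
  noisy <- function(x) ifelse(runif(24) < 0.1,
                              ifelse(x == "A", "B", "A"), x)
  co <- make_cohort(f = block, g = noisy(block), h = noisy(block))
  perm <- sample(24)
  co_perm <- subset_cohort(co, patients = perm)
  m1 <- fit_multinomial_mixture(co, K = 2, seed = 6, restarts = 8)
  m2 <- fit_multinomial_mixture(co_perm, K = 2, seed = 6, restarts = 8)
  expect_equal(m1$loglik, m2$loglik, tolerance = 1e-6)
  r1 <- m1$responsibilities[co_perm$patient_ids, ]
  r2 <- m2$responsibilities
  direct <- max(abs(r1 - r2))
  swapped <- max(abs(r1 - r2[, 2:1]))
  expect_lt(min(direct, swapped), 1e-3)
})

test_that("theta is recovered within 0.05 total variation on separable
           two-component data", {
  set.seed(8)
  n <- 300
  truth <- list(
    f = cbind(c(0.92, 0.05, 0.03), c(0.03, 0.07, 0.9)),
    g = cbind(c(0.95, 0.05), c(0.1, 0.9)),
    h = cbind(c(0.05, 0.9, 0.05), c(0.85, 0.05, 0.1)))
  comp <- sample(1:2, n, replace = TRUE, prob = c(0.55, 0.45))
  cols <- lapply(truth, function(th) {
    vapply(comp, function(k) {
      sample(letters[seq_len(nrow(th))], 1, prob = th[, k])
    }, character(1))
  })
  co <- do.call(make_cohort, cols)
  mm <- fit_multinomial_mixture(co, K = 2, seed = 19, restarts = 10)
  # align components by the f-table and measure per-feature TV distance
  flip <- sum(abs(mm$theta$f[, 1] - truth$f[, 2])) <
    sum(abs(mm$theta$f[, 1] - truth$f[, 1]))
  for (nm in names(truth)) {
    est <- if (flip) mm$theta[[nm]][, 2:1] else mm$theta[[nm]]
    tv <- max(colSums(abs(est - truth[[nm]])) / 2)
    expect_lt(tv, 0.05)
  }
})

test_that("cluster agreement reproduces identity, tie and chance-level
           behaviour", {
  # one-hot responsibilities agree with the labels everywhere
  resp <- cbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  lab <- rep(c("seizure_free", "improvement_only"), 2)
  ag <- cluster_agreement(resp, lab)
  expect_equal(ag$n_correct, 4L)
  expect_length(ag$misassigned, 0L)

  # an exact 0.5 tie goes to cluster 0 and is flagged
  ag_tie <- cluster_agreement(rbind(c(0.5, 0.5), c(0.1, 0.9)),
                              c("seizure_free", "improvement_only"))
  expect_equal(unname(ag_tie$assignment[1]), 0L)
  expect_equal(ag_tie$tied, "1")
  expect_equal(ag_tie$n_correct, 2L)

  # responsibilities independent of labels -> agreement near the majority
  set.seed(55)
  r <- runif(100)
  ag_null <- cluster_agreement(cbind(r, 1 - r),
                               sample(rep(c("seizure_free",
                                            "improvement_only"),
                                          c(60, 40))))
  expect_gte(ag_null$n_correct / 100, 0.5)
  expect_lte(ag_null$n_correct / 100, 0.75)
})
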