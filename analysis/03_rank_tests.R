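#!/usr/bin/env Rscript

# Hypothesis tests on the pre-surgical features. The class-stratified
# contingencies of the three separating features (Side, PStyle, PIQ) are
# reconstructed from the published stratified percentages; the exact
# tie-aware rank-sum test on them reproduces the published p-values. A
# full per-feature rank table is then shown on a study-like synthetic
# cohort, where only the planted features should reach significance.

suppressPackageStartupMessages(library(episelect))
dir.create("results", showWarnings = FALSE)

cont <- reported_contingencies()
cat("Reconstructed 19-patient contingencies and exact p-values:\n")
rows <- lapply(names(cont), function(nm) {
  g <- contingency_groups(cont[[nm]])
  tst <- exact_rank_sum_test(g$seizure_free, g$improvement_only)
  cat(sprintf("  %-7s W = %5.1f  p = %.4f (%s)\n", nm, tst$statistic,
              tst$p_two_sided, tst$method))
  data.frame(feature = nm, statistic = tst$statistic,
             p = tst$p_two_sided)
})
reconstructed <- do.call(rbind, rows)

cohort <- generate_cohort(study_like_config(n = 19, seed = 20130430))
cohort <- impute_class_conditional_mode(cohort)
cat("\nPer-feature exact rank-sum tests, synthetic study-like cohort",
    "(n = 19):\n")
rt <- rank_table(cohort)
print(rt, row.names = FALSE, digits = 4)
cat(sprintf("\n%d of %d features significant at 0.05 (planted: Side,",
            sum(rt$significant), nrow(rt)), "PStyle, PIQ)\n")

jsonlite::write_json(
  list(reconstructed = reconstructed, synthetic_rank_table = rt),
  "results/rank_tests.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("wrote results/rank_tests.json\n")
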