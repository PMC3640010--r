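test_that("the packaged cohort loads, validates and round-trips", {
  raw <- clinical_records()
  expect_equal(nrow(raw), 23L)
  expect_equal(sum(raw$sex == "m"), 10L)
  expect_equal(as.vector(table(factor(raw$engel, c("I", "II", "III")))),
               c(17L, 2L, 4L))

  co <- clinical_cohort()
  expect_s3_class(co, "cohort_table")
  expect_equal(co$n, 23L)
  expect_equal(sum(co$outcome == "seizure_free"), 17L)

  # canonical-dialect round trip is byte identical
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f1)
  co2 <- load_cohort(f1, co$schema)
  write_cohort(co2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(co2$features, co$features)
})

test_that("schema violations and malformed cohorts are rejected by name", {
  sch <- make_schema(PStyle = c("EB1", "EB2", "EB3"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,PStyle,outcome", "a,EB5,seizure_free"), f)
  expect_error(load_cohort(f, sch), "EB5.*PStyle|PStyle.*EB5")

  writeLines(c("patient_id,PStyle,outcome",
               "a,EB1,seizure_free", "a,EB2,improvement_only"), f)
  expect_error(load_cohort(f, sch), "duplicate")

  # empty data section under a valid header is a valid empty cohort
  writeLines("patient_id,PStyle,outcome", f)
  expect_equal(load_cohort(f, sch)$n, 0L)

  expect_error(cohort_table("a", data.frame(PStyle = "EB1"), NA, sch),
               "outcome")
  expect_error(feature_schema("x", c("A", "A")), "unique")
  expect_error(feature_schema("x", "A", missing_token = "A"), "collides")
})

test_that("Engel grades collapse to the binary outcome", {
  expect_equal(engel_to_binary(c("I", "II", "III")),
               c("seizure_free", "improvement_only", "improvement_only"))
  expect_error(engel_to_binary("IV"), "unsupported")
})

test_that("clinical discretisation covers the published bins and edges", {
  raw <- data.frame(age = c(32, 33, 17), sex = c("m", "f", "f"),
                    side = c("L", "R", "L"),
                    onset_age = c(1.8, 0.7, 2), duration_years = c(40, 4, 14),
                    seizure_type = c("gen", "PC", "PC, gen"),
                    seizure_freq = c("weekly", "Not regular", "0-3 weekly"))
  d <- discretize_clinical(raw)
  expect_equal(d$SurgeryAge, c("17-32", "33-54", "17-32"))
  expect_equal(d$OnsetAge, c("0-1", "0-1", "2-10"))
  expect_equal(d$ElapsedTime, c("20-39", "7-13", "14-19"))
  expect_equal(d$SeizureType, c("Generalized", "PartialComplex", "Both"))
  expect_equal(d$SeizureFreq, c("Weekly", "Other", "3-Weekly"))
  expect_error(discretize_clinical(transform(raw, seizure_freq = "hourly")),
               "unrecognised")
  # every packaged record maps into the vocabulary
  expect_false(anyNA(as.matrix(clinical_cohort()$features)))
})

test_that("class-conditional mode imputation follows the class, the schema
           tie order, and is idempotent", {
  co <- make_cohort(
    f = c("A", "A", "A", "B", NA, "B", "B", "A", NA, "B"),
    outcome = rep(c("seizure_free", "improvement_only"), each = 5))
  imp <- impute_class_conditional_mode(co)
  # seizure_free observed {A:3, B:1} -> A; improvement_only {B:3, A:1} -> B
  expect_equal(imp$features$f[5], "A")
  expect_equal(imp$features$f[9], "B")
  expect_false(anyNA(imp$features$f))
  # observed cells, ids and outcome untouched
  obs <- !is.na(co$features$f)
  expect_equal(imp$features$f[obs], co$features$f[obs])
  expect_identical(imp$patient_ids, co$patient_ids)
  expect_identical(imp$outcome, co$outcome)
  expect_identical(impute_class_conditional_mode(imp), imp)

  # within-class tie {A:2, B:2} breaks to the first schema category
  tie <- make_cohort(f = c("A", "A", "B", "B", NA),
                     outcome = rep("seizure_free", 5))
  tie$outcome <- factor(rep(c("seizure_free", "improvement_only"),
                            c(5, 0)),
                        levels = c("seizure_free", "improvement_only"))
  expect_equal(impute_class_conditional_mode(tie)$features$f[5], "A")

  # feature entirely missing within one class falls back with a warning
  gap <- make_cohort(f = c("A", "A", NA, NA),
                     outcome = rep(c("seizure_free", "improvement_only"),
                                   each = 2))
  expect_warning(out <- impute_class_conditional_mode(gap), "overall mode")
  expect_equal(out$features$f, rep("A", 4))
})

test_that("a study-vocabulary cohort with the published missingness imputes
           to zero missing cells", {
  cfg <- study_like_config(n = 19, seed = 5)
  co <- generate_cohort(cfg)
  expect_gt(sum(is.na(as.matrix(co$features))), 0L)
  imp <- impute_class_conditional_mode(co)
  expect_equal(sum(is.na(as.matrix(imp$features))), 0L)
})

test_that("the synthetic analysis subset satisfies the derivable constraints", {
  keep <- analysis_subset_synthetic()
  expect_length(keep, 19L)
  raw <- clinical_records()
  dropped <- raw[!(raw$patient_id %in% keep), ]
  expect_equal(nrow(dropped), 4L)
  expect_true(all(dropped$sex == "f"))
  expect_equal(sum(dropped$engel == "I"), 3L)
  expect_equal(sum(dropped$engel != "I"), 1L)
  # resulting 19-patient split is 14 seizure-free / 5 improvement-only
  sub <- subset_cohort(clinical_cohort(), patients = keep)
  expect_equal(as.vector(table(sub$outcome)), c(14L, 5L))
})
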