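# Domain types, validation rules and dossier file I/O.

test_that("bundled fixtures load with the expected annotations", {
  len <- read_dossier(evita_fixture("lenalidomide_mm"))
  expect_s3_class(len, "evita_dossier")
  expect_equal(len$context$therapeutic_aim, "treatment")
  expect_equal(len$context$disease_category, "I")
  expect_length(len$trials, 2)
  expect_equal(len$trials[[1]]$nnt, 2.6)

  pio <- read_dossier(evita_fixture("pioglitazone_dm2_2001"))
  expect_equal(pio$context$therapeutic_aim, "prevention")
  expect_equal(pio$options$rounding, "half_up_integer")

  zol <- read_dossier(evita_fixture("zoledronic_pmo"))
  expect_true(length(zol$context$established_therapies) > 0)
  expect_true(all(vapply(zol$trials, `[[`, character(1),
                         "comparator_kind") == "placebo_only"))
})

test_that("a dossier with no trials is valid", {
  d <- quick_dossier(trials = list())
  expect_s3_class(d, "evita_dossier")
  expect_length(d$trials, 0)
})

test_that("validation names the offending field and the admissible values", {
  expect_error(quick_context(aim = "cure"),
               "therapeutic_aim.*prevention, treatment",
               class = "evita_validation_error")
  expect_error(quick_arm(interaction = "unknown"),
               "interaction_class.*frequent_or_serious",
               class = "evita_validation_error")
  expect_error(quick_arm(g3 = 120), "grade_3_freq",
               class = "evita_validation_error")
  expect_error(
    therapeutic_context("d", "i", "treatment", "I",
                        established_therapies = c("a", "a")),
    "duplicate", class = "evita_validation_error")
})

test_that("inconsistent NNT and ARR are rejected, consistent pairs pass", {
  # 1/0.9 = 1.11 vs nnt 2.0: relative gap ~44%, far beyond the 5% tolerance
  expect_error(quick_trial(nnt = 2.0, arr = 0.9), "nnt.*arr",
               class = "evita_validation_error")
  expect_s3_class(quick_trial(nnt = 10, arr = 0.1), "evita_trial")
  expect_s3_class(quick_trial(nnt = 10, arr = 0.0962), "evita_trial") # ~4% off
})

test_that("Jadad items are coupled to the mentioned flags", {
  expect_error(jadad_items(FALSE, "appropriate"),
               "randomization", class = "evita_validation_error")
  expect_error(jadad_items(TRUE, "appropriate", FALSE, "inappropriate"),
               "blinding", class = "evita_validation_error")
  expect_s3_class(jadad_items(FALSE), "evita_jadad")
})

test_that("frequency classes in dossier files convert to canonical percents", {
  a <- quick_arm(g45 = "below_0.1", g3 = "1_to_10", g12 = "10_plus")
  expect_equal(frequency_class(a$grade_4_5_freq), "below_0.1")
  expect_equal(frequency_class(a$grade_3_freq), "1_to_10")
  expect_equal(frequency_class(a$grade_1_2_freq), "10_plus")
  # exact zero is preserved, distinct from "below 0.1%"
  expect_identical(quick_arm(g45 = "zero")$grade_4_5_freq, 0)
})

test_that("fixtures and random dossiers round-trip through YAML and JSON", {
  paths <- vapply(evita_fixture(), evita_fixture, character(1))
  dossiers <- lapply(paths, read_dossier)
  for (s in 1:25) dossiers <- c(dossiers, list(synthetic_dossier(s, 3)))
  for (d in dossiers) {
    fy <- withr::local_tempfile(fileext = ".yaml")
    fj <- withr::local_tempfile(fileext = ".json")
    write_dossier(d, fy)
    write_dossier(d, fj)
    expect_equal(read_dossier(fy), d)
    expect_equal(read_dossier(fj), d)
  }
})

test_that("reading rejects wrong schema tags and malformed documents", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("schema: something_else\nschema_version: 1", f)
  expect_error(read_dossier(f), "schema", class = "evita_validation_error")
  writeLines("schema: evita_dossier\nschema_version: 99", f)
  expect_error(read_dossier(f), "schema_version",
               class = "evita_validation_error")
  expect_error(read_dossier(file.path(tempdir(), "no-such-file.yaml")),
               "not found")
})

test_that("synthetic dossiers are deterministic per seed and valid", {
  d1 <- synthetic_dossier(seed = 1, n_trials = 3)
  d2 <- synthetic_dossier(seed = 1, n_trials = 3)
  expect_identical(d1, d2)
  expect_length(d1$trials, 3)
  expect_false(identical(d1, synthetic_dossier(seed = 2, n_trials = 3)))
  expect_error(synthetic_dossier(seed = 1, n_trials = -1), "n_trials")
  # zero trials force the not-assessable verdict
  expect_equal(evita(synthetic_dossier(seed = 2, n_trials = 0))$band,
               "not_assessable")
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(42)
  a <- runif(1)
  set.seed(42)
  invisible(synthetic_dossier(seed = 7, n_trials = 2))
  expect_identical(runif(1), a)
})

test_that("the generator covers every enum literal across seeds", {
  seen <- list(result = character(), comparator = character(),
               level = character(), interaction = character(),
               aim = character(), category = character(),
               freq = character(), rounding = character())
  for (s in 1:400) {
    d <- synthetic_dossier(s, n_trials = 3)
    seen$aim <- union(seen$aim, d$context$therapeutic_aim)
    seen$category <- union(seen$category, d$context$disease_category)
    seen$rounding <- union(seen$rounding, d$options$rounding)
    seen$interaction <- union(seen$interaction,
                              c(d$drug_risk$interaction_class,
                                d$comparator_risk$interaction_class))
    seen$freq <- union(seen$freq, vapply(
      c(d$drug_risk[c("grade_4_5_freq", "grade_3_freq", "grade_1_2_freq")],
        d$comparator_risk[c("grade_4_5_freq", "grade_3_freq", "grade_1_2_freq")]),
      frequency_class, character(1)))
    for (tr in d$trials) {
      seen$result <- union(seen$result, tr$result)
      seen$comparator <- union(seen$comparator, tr$comparator_kind)
      seen$level <- union(seen$level, tr$outcome_level)
    }
  }
  expect_setequal(seen$aim, c("prevention", "treatment"))
  expect_setequal(seen$category, c("I", "II", "III", "IV"))
  expect_setequal(seen$rounding, c("none", "half_up_integer"))
  expect_setequal(seen$interaction, interaction_classes)
  expect_setequal(seen$freq, freq_classes)
  expect_setequal(seen$result,
                  c("superiority", "non_inferiority_or_equivalence",
                    "inferiority", "no_significant_difference"))
  expect_setequal(seen$comparator,
                  c("head_to_head", "placebo_add_on", "placebo_only"))
  expect_setequal(seen$level, c("patient_relevant", "surrogate"))
})
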