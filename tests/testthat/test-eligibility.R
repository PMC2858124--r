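# Jadad scoring, trial screening rules and trial-setting classification.

test_that("Jadad score matches an exhaustive item-wise oracle", {
  appropriateness <- c("appropriate", "inappropriate", "not_described")
  pts <- c(appropriate = 1L, inappropriate = -1L, not_described = 0L)
  for (rm in c(TRUE, FALSE)) for (bm in c(TRUE, FALSE))
    for (ra in if (rm) appropriateness else "not_described")
      for (ba in if (bm) appropriateness else "not_described")
        for (wd in c(TRUE, FALSE)) {
          expected <- max(0L, rm + pts[[ra]] + bm + pts[[ba]] + wd)
          expect_identical(
            compute_jadad(jadad_items(rm, ra, bm, ba, wd)), expected,
            info = sprintf("rm=%s ra=%s bm=%s ba=%s wd=%s", rm, ra, bm, ba, wd))
        }
})

test_that("Jadad extremes: all favorable is 5, nothing described is 0", {
  expect_identical(compute_jadad(
    jadad_items(TRUE, "appropriate", TRUE, "appropriate", TRUE)), 5L)
  expect_identical(compute_jadad(jadad_items(FALSE)), 0L)
  # mentioned+appropriate randomization, inappropriate blinding, withdrawals
  expect_identical(compute_jadad(
    jadad_items(TRUE, "appropriate", TRUE, "inappropriate", TRUE)), 3L)
})

test_that("trials below the Jadad cut-off are excluded for quality", {
  trials <- list(quick_trial("good", jadad = 3L),
                 quick_trial("bad", jadad = 2L),
                 quick_trial("items-bad",
                             jadad = jadad_items(TRUE, "not_described",
                                                 FALSE, withdrawals_described = TRUE)))
  res <- filter_trials(trials, quick_context())
  expect_equal(vapply(res$included, `[[`, character(1), "trial_id"), "good")
  expect_setequal(vapply(res$excluded, `[[`, character(1), "trial_id"),
                  c("bad", "items-bad"))
  expect_true(all(vapply(res$excluded, `[[`, character(1), "reason") == "quality"))
})

test_that("pure placebo comparisons are excluded when a therapy is established", {
  zol <- read_dossier(evita_fixture("zoledronic_pmo"))
  res <- filter_trials(zol$trials, zol$context)
  expect_length(res$included, 0)
  expect_length(res$excluded, 2)
  expect_true(all(vapply(res$excluded, `[[`, character(1), "reason") ==
                    "placebo despite established therapy"))
  # without an established therapy the same trials become admissible; the
  # patient-relevant trial then supersedes the surrogate one
  res2 <- filter_trials(zol$trials, quick_context(established = character()))
  expect_equal(vapply(res2$included, `[[`, character(1), "trial_id"),
               "HORIZON-PFT")
  expect_equal(res2$excluded[[1]]$reason,
               "superseded by patient-relevant evidence")
})

test_that("placebo add-on designs are admissible despite established therapy", {
  tr <- quick_trial(comparator = "placebo_add_on")
  res <- filter_trials(list(tr), quick_context())
  expect_length(res$included, 1)
})

test_that("twin-protocol trials collapse into one logical trial", {
  len <- read_dossier(evita_fixture("lenalidomide_mm"))
  res <- filter_trials(len$trials, len$context)
  expect_length(res$included, 1)
  expect_equal(res$included[[1]]$trial_id, "MM-009")
  expect_equal(res$excluded[[1]]$trial_id, "MM-010")
  expect_equal(res$excluded[[1]]$reason, "duplicate protocol")
})

test_that("patient-relevant evidence supersedes surrogate trials", {
  pio <- read_dossier(evita_fixture("pioglitazone_dm2_2005"))
  res <- filter_trials(pio$trials, pio$context)
  expect_equal(vapply(res$included, `[[`, character(1), "trial_id"),
               "PROACTIVE")
  expect_setequal(vapply(res$excluded, `[[`, character(1), "reason"),
                  "superseded by patient-relevant evidence")
})

test_that("an assessor exclusion note excludes the trial with that reason", {
  tr <- quick_trial("old", exclusion_note = "not GCP conforming")
  res <- filter_trials(list(tr), quick_context())
  expect_length(res$included, 0)
  expect_equal(res$excluded[[1]]$reason, "not GCP conforming")
})

test_that("screening partitions the input trials (property)", {
  for (s in 1:50) {
    d <- synthetic_dossier(s, n_trials = 5)
    res <- filter_trials(d$trials, d$context)
    ids_in <- vapply(res$included, `[[`, character(1), "trial_id")
    ids_ex <- vapply(res$excluded, `[[`, character(1), "trial_id")
    expect_length(intersect(ids_in, ids_ex), 0)
    expect_setequal(c(ids_in, ids_ex),
                    vapply(d$trials, `[[`, character(1), "trial_id"))
  }
})

test_that("trial settings classify per the decision tree", {
  ctx <- quick_context()
  # patient-relevant placebo add-on -> A2 (lenalidomide situation)
  expect_equal(classify_trial_setting(
    list(quick_trial(comparator = "placebo_add_on")), ctx)$value, "A2")
  # surrogate head-to-head -> B1 (bupropion situation)
  expect_equal(classify_trial_setting(
    list(quick_trial(level = "surrogate")), ctx)$value, "B1")
  # surrogate placebo add-on -> B2
  expect_equal(classify_trial_setting(
    list(quick_trial(comparator = "placebo_add_on", level = "surrogate")),
    ctx)$value, "B2")
  # patient-relevant head-to-head -> A1
  expect_equal(classify_trial_setting(list(quick_trial()), ctx)$value, "A1")
  # nothing included -> NA
  s <- classify_trial_setting(list(), ctx)
  expect_equal(s$value, "NA")
  expect_length(s$included_trials, 0)
})

test_that("head-to-head dominates the comparison digit at the defining tier", {
  ctx <- quick_context()
  trials <- list(quick_trial("h2h"),
                 quick_trial("addon", comparator = "placebo_add_on"))
  expect_equal(classify_trial_setting(trials, ctx)$value, "A1")
  # a surrogate head-to-head must not pull an A2 setting to A1
  trials2 <- list(quick_trial("pr", comparator = "placebo_add_on"),
                  quick_trial("sur-h2h", level = "surrogate"))
  expect_equal(classify_trial_setting(trials2, ctx)$value, "A2")
})

test_that("adding a trial never demotes the setting from A to B (property)", {
  ctx <- quick_context()
  set.seed(99)
  for (s in 1:40) {
    d <- synthetic_dossier(s, n_trials = 3)
    base <- filter_trials(d$trials, d$context)
    before <- classify_trial_setting(base$included, d$context)$value
    extra <- quick_trial("EXTRA", comparator = "placebo_add_on",
                         level = sample(c("patient_relevant", "surrogate"), 1))
    after_f <- filter_trials(c(d$trials, list(extra)), d$context)
    after <- classify_trial_setting(after_f$included, d$context)$value
    if (startsWith(before, "A")) expect_true(startsWith(after, "A"))
  }
})
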