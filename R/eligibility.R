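# Trial eligibility: Jadad quality scoring, inclusion/exclusion rules, twin-
# protocol collapsing, and classification of the evidence into a trial
# setting (A1/A2/B1/B2 or NA).

#' Jadad quality score of a randomized trial
#'
#' Scores the five-item Jadad instrument: one point each for mentioning
#' randomization, mentioning blinding and describing withdrawals/dropouts;
#' one additional point each for an appropriate randomization or blinding
#' method, and one point deducted for an inappropriate one. The result is
#' clamped at 0. Trials need a score of at least 3 to be eligible for
#' scoring.
#'
#' @param items An [jadad_items()] object.
#' @return Integer score between 0 and 5.
#' @export
#' @examples
#' compute_jadad(jadad_items(TRUE, "appropriate", TRUE, "appropriate", TRUE))
compute_jadad <- function(items) {
  stopifnot(inherits(items, "evita_jadad"))
  appropriateness_pts <- c(appropriate = 1L, inappropriate = -1L,
                           not_described = 0L)
  score <- as.integer(items$randomization_mentioned) +
    appropriateness_pts[[items$randomization_appropriate]] +
    as.integer(items$blinding_mentioned) +
    appropriateness_pts[[items$blinding_appropriate]] +
    as.integer(items$withdrawals_described)
  max(0L, score)
}

trial_jadad <- function(trial) {
  if (inherits(trial$jadad, "evita_jadad")) compute_jadad(trial$jadad)
  else trial$jadad
}

exclusion <- function(trial, reason)
  list(trial = trial, trial_id = trial$trial_id, reason = reason)

#' Apply the trial inclusion and exclusion rules
#'
#' Screens the candidate RCTs of a dossier in four steps, recording a reason
#' for every exclusion:
#'
#' 1. *Quality*: trials with a Jadad score below 3 are excluded
#'    (reason `"quality"`).
#' 2. *Comparator*: trials comparing against placebo alone are excluded when
#'    an established therapy exists for the indication (reason
#'    `"placebo despite established therapy"`); placebo add-on designs are
#'    always admissible.
#' 3. *Twin protocols*: trials sharing a `duplicate_protocol_key` are
#'    collapsed into one logical trial — the first record is kept, the rest
#'    are excluded (reason `"duplicate protocol"`).
#' 4. *Supersession*: once any included trial reports a patient-relevant
#'    outcome, surrogate-outcome trials no longer count towards the
#'    efficiency score (reason `"superseded by patient-relevant evidence"`).
#'
#' Trials carrying an assessor `exclusion_note` (e.g. GCP concerns) are
#' excluded with that note as the reason before any rule is applied.
#'
#' @param trials List of [trial_record()] objects.
#' @param context The [therapeutic_context()] (supplies the established-
#'   therapy list).
#' @return A list with elements `included` (list of trials) and `excluded`
#'   (list of `list(trial, trial_id, reason)`), a disjoint partition of the
#'   input.
#' @export
filter_trials <- function(trials, context) {
  stopifnot(is.list(trials), inherits(context, "evita_context"))
  included <- list()
  excluded <- list()
  has_established <- length(context$established_therapies) > 0L

  for (trial in trials) {
    if (!is.null(trial$exclusion_note)) {
      excluded[[length(excluded) + 1L]] <- exclusion(trial, trial$exclusion_note)
    } else if (trial_jadad(trial) < 3L) {
      excluded[[length(excluded) + 1L]] <- exclusion(trial, "quality")
    } else if (trial$comparator_kind == "placebo_only" && has_established) {
      excluded[[length(excluded) + 1L]] <-
        exclusion(trial, "placebo despite established therapy")
    } else {
      included[[length(included) + 1L]] <- trial
    }
  }

  # collapse twin-protocol trials: keep the first record of each key
  seen_keys <- character()
  kept <- list()
  for (trial in included) {
    key <- trial$duplicate_protocol_key
    if (!is.null(key) && key %in% seen_keys) {
      excluded[[length(excluded) + 1L]] <- exclusion(trial, "duplicate protocol")
    } else {
      if (!is.null(key)) seen_keys <- c(seen_keys, key)
      kept[[length(kept) + 1L]] <- trial
    }
  }
  included <- kept

  # patient-relevant evidence supersedes surrogate trials for efficiency
  levels <- vapply(included, `[[`, character(1), "outcome_level")
  if (any(levels == "patient_relevant") && any(levels == "surrogate")) {
    for (trial in included[levels == "surrogate"])
      excluded[[length(excluded) + 1L]] <-
        exclusion(trial, "superseded by patient-relevant evidence")
    included <- included[levels == "patient_relevant"]
  }

  list(included = included, excluded = excluded)
}

#' Classify the evidence into a trial setting
#'
#' Assigns the trial setting from the trials that survived [filter_trials()]:
#' the letter is **A** when any included trial reports a patient-relevant
#' outcome (mortality, events, functionality, symptoms, quality of life) and
#' **B** when only surrogate outcomes are available; the digit is **1** when
#' any trial at that outcome level is a head-to-head comparison against
#' established therapy and **2** when the comparison is against placebo
#' (either directly in the absence of an established therapy, or in an add-on
#' design). With no included trial the setting is **NA**: the assessment is
#' not available, which is itself an explicit verdict.
#'
#' @param included List of included [trial_record()]s (already filtered).
#' @param context The [therapeutic_context()].
#' @param excluded Optional exclusion audit trail from [filter_trials()],
#'   carried along for reporting.
#' @return An object of class `evita_setting` with fields `value` (one of
#'   `"A1"`, `"A2"`, `"B1"`, `"B2"`, `"NA"`), `included_trials` (ids) and
#'   `excluded_trials` (data.frame of id and reason).
#' @export
classify_trial_setting <- function(included, context, excluded = list()) {
  stopifnot(is.list(included), inherits(context, "evita_context"))
  excluded_df <- if (length(excluded)) {
    data.frame(trial_id = vapply(excluded, `[[`, character(1), "trial_id"),
               reason = vapply(excluded, `[[`, character(1), "reason"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(trial_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  if (length(included) == 0L) {
    return(structure(list(value = "NA", included_trials = character(),
                          excluded_trials = excluded_df),
                     class = "evita_setting"))
  }
  levels <- vapply(included, `[[`, character(1), "outcome_level")
  tier <- if (any(levels == "patient_relevant")) "A" else "B"
  tier_level <- if (tier == "A") "patient_relevant" else "surrogate"
  defining <- included[levels == tier_level]
  comparators <- vapply(defining, `[[`, character(1), "comparator_kind")
  digit <- if (any(comparators == "head_to_head")) "1" else "2"
  structure(
    list(value = paste0(tier, digit),
         included_trials = vapply(included, `[[`, character(1), "trial_id"),
         excluded_trials = excluded_df),
    class = "evita_setting")
}

#' @export
print.evita_setting <- function(x, ...) {
  cat("Trial setting:", x$value, "\n")
  if (length(x$included_trials))
    cat("  included:", paste(x$included_trials, collapse = ", "), "\n")
  if (nrow(x$excluded_trials))
    for (i in seq_len(nrow(x$excluded_trials)))
      cat(sprintf("  excluded: %s (%s)\n", x$excluded_trials$trial_id[i],
                  x$excluded_trials$reason[i]))
  invisible(x)
}
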