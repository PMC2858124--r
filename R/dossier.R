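# Domain types for an assessment dossier: the structured record of one
# drug-indication pair (therapeutic context, RCT evidence, two arm-level risk
# profiles, scoring options). All constructors validate eagerly and signal
# classed conditions so callers (and the CLI) can distinguish validation
# failures from I/O failures.

DOSSIER_SCHEMA <- "evita_dossier"
DOSSIER_SCHEMA_VERSION <- 1L

.enums <- list(
  therapeutic_aim  = c("prevention", "treatment"),
  disease_category = c("I", "II", "III", "IV"),
  comparator_kind  = c("head_to_head", "placebo_add_on", "placebo_only"),
  outcome_level    = c("patient_relevant", "surrogate"),
  result           = c("superiority", "non_inferiority_or_equivalence",
                       "inferiority", "no_significant_difference"),
  appropriateness  = c("appropriate", "inappropriate", "not_described"),
  interaction_class = c("frequent_or_serious", "occasional_or_clinical",
                        "dose_change", "unlikely_or_none", "no_information"),
  frequency_class  = c("zero", "below_0.1", "0.1_to_1", "1_to_10", "10_plus"),
  rounding         = c("none", "half_up_integer")
)

# representative percent used when a dossier file states a frequency class
# rather than a percent; each anchor falls strictly inside its class
.class_anchor_percent <- c(
  zero = 0, `below_0.1` = 0.05, `0.1_to_1` = 0.5, `1_to_10` = 5, `10_plus` = 30
)

abort_validation <- function(msg, field = NULL) {
  if (!is.null(field)) msg <- sprintf("[%s] %s", field, msg)
  stop(structure(
    class = c("evita_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_enum <- function(value, what, field) {
  choices <- .enums[[what]]
  if (!(is.character(value) && length(value) == 1L && value %in% choices)) {
    abort_validation(
      sprintf("'%s' is not one of: %s",
              paste(value, collapse = ","), paste(choices, collapse = ", ")),
      field = field)
  }
  value
}

check_flag <- function(value, field) {
  if (!(is.logical(value) && length(value) == 1L && !is.na(value)))
    abort_validation("must be TRUE or FALSE", field = field)
  value
}

check_scalar_number <- function(value, field, lower = -Inf, upper = Inf,
                                lower_open = FALSE) {
  if (!(is.numeric(value) && length(value) == 1L && is.finite(value)))
    abort_validation("must be a single finite number", field = field)
  ok <- if (lower_open) value > lower else value >= lower
  if (!ok || value > upper)
    abort_validation(sprintf("must lie in %s%s, %s]",
                             if (lower_open) "(" else "[", lower, upper),
                     field = field)
  as.numeric(value)
}

check_string <- function(value, field, allow_empty = FALSE) {
  if (!(is.character(value) && length(value) == 1L && !is.na(value)))
    abort_validation("must be a single string", field = field)
  if (!allow_empty && !nzchar(value))
    abort_validation("must be non-empty", field = field)
  value
}

#' Therapeutic context of an assessment
#'
#' Identifies the drug-indication pair under evaluation and carries the two
#' annotations every assessment is labelled with: the therapeutic aim
#' (prevention vs treatment, which selects the NNT modifier table) and the
#' disease severity category I-IV (documented on the report but never part of
#' the score arithmetic). The list of established therapies decides whether
#' pure placebo comparisons are admissible evidence.
#'
#' @param drug_name Name of the investigational drug.
#' @param indication Free-text indication, optionally with an ICD-10 code.
#' @param therapeutic_aim `"prevention"` or `"treatment"`.
#' @param disease_category Severity category `"I"`, `"II"`, `"III"` or `"IV"`
#'   (I = acute life-threatening or severe chronic disease, II =
#'   rehabilitation, III = less severe disease, IV = use outside a treatment
#'   context).
#' @param established_therapies Character vector of accepted established
#'   therapies for the indication; may be empty. Duplicates are rejected.
#' @param atc_code Optional ATC classification code.
#' @return An object of class `evita_context`.
#' @export
therapeutic_context <- function(drug_name, indication, therapeutic_aim,
                                disease_category,
                                established_therapies = character(),
                                atc_code = NULL) {
  check_string(drug_name, "drug_name")
  check_string(indication, "indication")
  check_enum(therapeutic_aim, "therapeutic_aim", "therapeutic_aim")
  check_enum(disease_category, "disease_category", "disease_category")
  if (!is.null(atc_code)) check_string(atc_code, "atc_code")
  if (is.null(established_therapies)) established_therapies <- character()
  if (!is.character(established_therapies))
    abort_validation("must be a character vector", "established_therapies")
  established_therapies <- as.character(established_therapies)
  if (anyDuplicated(established_therapies))
    abort_validation("contains duplicate entries", "established_therapies")
  structure(
    list(drug_name = drug_name, atc_code = atc_code, indication = indication,
         therapeutic_aim = therapeutic_aim,
         disease_category = disease_category,
         established_therapies = established_therapies),
    class = "evita_context")
}

#' Jadad quality items for one randomized trial
#'
#' The five-item Jadad instrument: randomization and blinding each score one
#' point for being mentioned, one more if the method is appropriate and minus
#' one if it is inappropriate; describing withdrawals/dropouts scores one
#' point. An item whose method cannot be judged because the feature was never
#' mentioned must be recorded as `"not_described"`.
#'
#' @param randomization_mentioned,blinding_mentioned Logical flags.
#' @param randomization_appropriate,blinding_appropriate One of
#'   `"appropriate"`, `"inappropriate"`, `"not_described"`; must be
#'   `"not_described"` when the corresponding feature is not mentioned.
#' @param withdrawals_described Logical flag.
#' @return An object of class `evita_jadad`.
#' @seealso [compute_jadad()]
#' @export
jadad_items <- function(randomization_mentioned,
                        randomization_appropriate = "not_described",
                        blinding_mentioned = FALSE,
                        blinding_appropriate = "not_described",
                        withdrawals_described = FALSE) {
  check_flag(randomization_mentioned, "randomization_mentioned")
  check_flag(blinding_mentioned, "blinding_mentioned")
  check_flag(withdrawals_described, "withdrawals_described")
  check_enum(randomization_appropriate, "appropriateness",
             "randomization_appropriate")
  check_enum(blinding_appropriate, "appropriateness", "blinding_appropriate")
  if (!randomization_mentioned && randomization_appropriate != "not_described")
    abort_validation(
      "must be 'not_described' when randomization is not mentioned",
      "randomization_appropriate")
  if (!blinding_mentioned && blinding_appropriate != "not_described")
    abort_validation("must be 'not_described' when blinding is not mentioned",
                     "blinding_appropriate")
  structure(
    list(randomization_mentioned = randomization_mentioned,
         randomization_appropriate = randomization_appropriate,
         blinding_mentioned = blinding_mentioned,
         blinding_appropriate = blinding_appropriate,
         withdrawals_described = withdrawals_described),
    class = "evita_jadad")
}

#' One randomized controlled trial record
#'
#' Captures the fields the scoring algorithm needs from one RCT: the kind of
#' comparator, whether the primary outcome is patient-relevant or a surrogate,
#' the result direction, trial quality (Jadad items or a precomputed 0-5
#' score), and optionally the strength-of-effect data (NNT or ARR with the
#' trial duration used to annualize it). Two publications that ran the
#' identical protocol are tied together with a shared `duplicate_protocol_key`
#' so they count as one logical trial.
#'
#' @param trial_id Identifier (registry id, acronym, citation key).
#' @param comparator_kind `"head_to_head"` (vs established therapy),
#'   `"placebo_add_on"` (placebo on top of established therapy in both arms),
#'   or `"placebo_only"`.
#' @param outcome_level `"patient_relevant"` or `"surrogate"`.
#' @param result `"superiority"`, `"non_inferiority_or_equivalence"`,
#'   `"inferiority"`, or `"no_significant_difference"` (a superiority trial
#'   that failed; contributes no efficiency points).
#' @param jadad Either an [jadad_items()] object or an integer score 0-5.
#' @param duration_years Trial duration in years; required to annualize `nnt`.
#' @param nnt Number needed to treat over the trial duration (>= 1).
#' @param arr Absolute risk reduction in (0, 1]. If both `nnt` and `arr` are
#'   given they must agree within 5% relative to `nnt` (they are reciprocals).
#' @param duplicate_protocol_key Optional key shared by twin-protocol trials.
#' @param exclusion_note Optional assessor note (e.g. GCP concerns) recorded
#'   in the audit trail.
#' @return An object of class `evita_trial`.
#' @export
trial_record <- function(trial_id, comparator_kind, outcome_level, result,
                         jadad, duration_years = NULL, nnt = NULL, arr = NULL,
                         duplicate_protocol_key = NULL,
                         exclusion_note = NULL) {
  check_string(trial_id, "trial_id")
  check_enum(comparator_kind, "comparator_kind", "comparator_kind")
  check_enum(outcome_level, "outcome_level", "outcome_level")
  check_enum(result, "result", "result")
  if (inherits(jadad, "evita_jadad")) {
    # fine as is
  } else if (is.numeric(jadad) && length(jadad) == 1L && !is.na(jadad) &&
             jadad == as.integer(jadad) && jadad >= 0 && jadad <= 5) {
    jadad <- as.integer(jadad)
  } else {
    abort_validation("must be jadad_items() or an integer 0-5", "jadad")
  }
  if (!is.null(duration_years))
    check_scalar_number(duration_years, "duration_years", lower = 0,
                        lower_open = TRUE)
  if (!is.null(nnt)) check_scalar_number(nnt, "nnt", lower = 1)
  if (!is.null(arr))
    check_scalar_number(arr, "arr", lower = 0, upper = 1, lower_open = TRUE)
  if (!is.null(nnt) && !is.null(arr)) {
    if (abs(nnt - 1 / arr) / nnt > 0.05)
      abort_validation(
        sprintf("nnt (%g) and arr (%g) disagree: 1/arr = %g differs by more than 5%%",
                nnt, arr, 1 / arr), "nnt/arr")
  }
  if (!is.null(duplicate_protocol_key))
    check_string(duplicate_protocol_key, "duplicate_protocol_key")
  if (!is.null(exclusion_note)) check_string(exclusion_note, "exclusion_note")
  structure(
    list(trial_id = trial_id, comparator_kind = comparator_kind,
         outcome_level = outcome_level, result = result, jadad = jadad,
         duration_years = duration_years, nnt = nnt, arr = arr,
         duplicate_protocol_key = duplicate_protocol_key,
         exclusion_note = exclusion_note),
    class = "evita_trial")
}

#' Arm-level adverse-event risk profile
#'
#' For one treatment arm, the highest single-adverse-event frequency observed
#' within each CTCAE severity group (grades 4+5 life-threatening/disabling/
#' fatal, grade 3 severe, grades 1+2 mild/moderate), plus the drug-interaction
#' class taken from the product label. Frequencies are percentages in
#' \[0, 100\]; a named frequency class (`"zero"`, `"below_0.1"`, `"0.1_to_1"`,
#' `"1_to_10"`, `"10_plus"`) is also accepted and converted to a
#' representative percent. An exact 0 means the adverse-event group was not
#' observed at all and is distinct from "below 0.1%".
#'
#' @param arm_label Label for the arm (drug or comparator).
#' @param grade_4_5_freq,grade_3_freq,grade_1_2_freq Highest single-AE
#'   frequency in the group, as percent or class name.
#' @param interaction_class One of `"frequent_or_serious"`,
#'   `"occasional_or_clinical"`, `"dose_change"`, `"unlikely_or_none"`,
#'   `"no_information"`.
#' @return An object of class `evita_arm`.
#' @export
arm_risk_profile <- function(arm_label, grade_4_5_freq, grade_3_freq,
                             grade_1_2_freq, interaction_class) {
  check_string(arm_label, "arm_label")
  coerce_freq <- function(x, field) {
    if (is.character(x)) {
      check_enum(x, "frequency_class", field)
      return(unname(.class_anchor_percent[[x]]))
    }
    check_scalar_number(x, field, lower = 0, upper = 100)
  }
  check_enum(interaction_class, "interaction_class", "interaction_class")
  structure(
    list(arm_label = arm_label,
         grade_4_5_freq = coerce_freq(grade_4_5_freq, "grade_4_5_freq"),
         grade_3_freq = coerce_freq(grade_3_freq, "grade_3_freq"),
         grade_1_2_freq = coerce_freq(grade_1_2_freq, "grade_1_2_freq"),
         interaction_class = interaction_class),
    class = "evita_arm")
}

#' Assemble an assessment dossier
#'
#' Bundles everything needed to score one drug-indication pair: the
#' therapeutic context, the list of candidate RCTs (possibly empty, which
#' forces a "not assessable" verdict), the drug and comparator risk profiles,
#' and the scoring options. Drug and comparator profiles are expected to be
#' drawn from the same evidence base (the scored trials, or the product label
#' when trial AE reporting is insufficient); that correspondence is the
#' assessor's responsibility.
#'
#' @param context An [therapeutic_context()].
#' @param trials A list of [trial_record()] objects (may be empty).
#' @param drug_risk,comparator_risk [arm_risk_profile()] objects.
#' @param options List of scoring options: `rounding` (`"none"` or
#'   `"half_up_integer"`, applied to the efficiency score) and
#'   `yellow_half_width` (half-width of the yellow color band, default 2).
#' @return An object of class `evita_dossier`.
#' @export
assessment_dossier <- function(context, trials, drug_risk, comparator_risk,
                               options = list()) {
  if (!inherits(context, "evita_context"))
    abort_validation("must be a therapeutic_context()", "context")
  if (!is.list(trials) ||
      !all(vapply(trials, inherits, logical(1), "evita_trial")))
    abort_validation("must be a list of trial_record() objects", "trials")
  ids <- vapply(trials, `[[`, character(1), "trial_id")
  if (anyDuplicated(ids))
    abort_validation("trial_id values must be unique", "trials")
  if (!inherits(drug_risk, "evita_arm"))
    abort_validation("must be an arm_risk_profile()", "drug_risk")
  if (!inherits(comparator_risk, "evita_arm"))
    abort_validation("must be an arm_risk_profile()", "comparator_risk")
  opts <- list(rounding = "none", yellow_half_width = 2)
  if (!is.list(options)) abort_validation("must be a list", "options")
  unknown <- setdiff(names(options), names(opts))
  if (length(unknown))
    abort_validation(paste("unknown option(s):", paste(unknown, collapse = ", ")),
                     "options")
  opts[names(options)] <- options
  check_enum(opts$rounding, "rounding", "options$rounding")
  check_scalar_number(opts$yellow_half_width, "options$yellow_half_width",
                      lower = 0)
  structure(
    list(schema = DOSSIER_SCHEMA, schema_version = DOSSIER_SCHEMA_VERSION,
         context = context, trials = trials, drug_risk = drug_risk,
         comparator_risk = comparator_risk, options = opts),
    class = "evita_dossier")
}

#' @export
print.evita_dossier <- function(x, ...) {
  cat(sprintf("EVITA assessment dossier: %s - %s\n",
              x$context$drug_name, x$context$indication))
  cat(sprintf("  aim: %s, disease category: %s, established therapies: %d\n",
              x$context$therapeutic_aim, x$context$disease_category,
              length(x$context$established_therapies)))
  cat(sprintf("  trials: %d\n", length(x$trials)))
  invisible(x)
}
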