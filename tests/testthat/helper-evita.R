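# Shorthand builders used across the suite.

quick_trial <- function(id = "T1", comparator = "head_to_head",
                        level = "patient_relevant", result = "superiority",
                        jadad = 5L, ...) {
  trial_record(trial_id = id, comparator_kind = comparator,
               outcome_level = level, result = result, jadad = jadad, ...)
}

quick_context <- function(aim = "treatment", established = c("std therapy")) {
  therapeutic_context(drug_name = "drug X", indication = "indication Y",
                      therapeutic_aim = aim, disease_category = "I",
                      established_therapies = established)
}

quick_arm <- function(label = "arm", g45 = 0, g3 = 0, g12 = 0,
                      interaction = "unlikely_or_none") {
  arm_risk_profile(arm_label = label, grade_4_5_freq = g45,
                   grade_3_freq = g3, grade_1_2_freq = g12,
                   interaction_class = interaction)
}

quick_dossier <- function(trials = list(quick_trial()),
                          context = quick_context(), ...) {
  assessment_dossier(context = context, trials = trials,
                     drug_risk = quick_arm("drug"),
                     comparator_risk = quick_arm("comparator"), ...)
}

freq_classes <- c("zero", "below_0.1", "0.1_to_1", "1_to_10", "10_plus")
interaction_classes <- c("frequent_or_serious", "occasional_or_clinical",
                         "dose_change", "unlikely_or_none", "no_information")

# a percent strictly inside each frequency class, for grid enumeration
class_percent <- c(zero = 0, below_0.1 = 0.05, `0.1_to_1` = 0.5,
                   `1_to_10` = 5, `10_plus` = 50)

arm_from_classes <- function(g45, g3, g12, interaction, label = "arm") {
  quick_arm(label, g45 = class_percent[[g45]], g3 = class_percent[[g3]],
            g12 = class_percent[[g12]], interaction = interaction)
}
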