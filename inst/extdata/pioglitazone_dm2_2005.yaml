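# Pioglitazone in type-2 diabetes, re-evaluated in 2005 after the large
# macrovascular outcome trial (patient-relevant composite endpoint) failed to
# show superiority over placebo add-on. The patient-relevant trial supersedes
# the two earlier surrogate (HbA1c) trials, so the efficiency score drops to
# zero; the arm-vs-arm risk reconciliation is unchanged at -1.0.
schema: evita_dossier
schema_version: 1
context:
  drug_name: pioglitazone
  atc_code: A10BG03
  indication: "Diabetes mellitus type 2 (ICD-10: E10-E14)"
  therapeutic_aim: prevention
  disease_category: I
  established_therapies:
  - metformin
  - sulphonylureas
trials:
- trial_id: PROACTIVE
  comparator_kind: placebo_add_on
  outcome_level: patient_relevant
  result: no_significant_difference
  jadad:
    randomization_mentioned: true
    randomization_appropriate: appropriate
    blinding_mentioned: true
    blinding_appropriate: appropriate
    withdrawals_described: true
  duration_years: 2.9
- trial_id: PIO-ADDON-MET
  comparator_kind: placebo_add_on
  outcome_level: surrogate
  result: superiority
  jadad:
    randomization_mentioned: true
    randomization_appropriate: appropriate
    blinding_mentioned: true
    blinding_appropriate: appropriate
    withdrawals_described: true
- trial_id: PIO-ADDON-SU
  comparator_kind: placebo_add_on
  outcome_level: surrogate
  result: superiority
  jadad:
    randomization_mentioned: true
    randomization_appropriate: appropriate
    blinding_mentioned: true
    blinding_appropriate: appropriate
    withdrawals_described: true
# Individual arm risk profiles extracted from the outcome trial (-7.5 points
# for the drug arm including the dose-change interaction penalty); identical
# adverse-event frequency classes in both arms, so the reconciliation stays
# at the interaction difference of -1.0.
drug_risk:
  arm_label: pioglitazone add-on
  grade_4_5_freq: 2.0
  grade_3_freq: 6.0
  grade_1_2_freq: 25.0
  interaction_class: dose_change
comparator_risk:
  arm_label: placebo add-on
  grade_4_5_freq: 2.0
  grade_3_freq: 6.0
  grade_1_2_freq: 25.0
  interaction_class: unlikely_or_none
options:
  rounding: half_up_integer
  yellow_half_width: 2.0
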