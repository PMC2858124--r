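# Zoledronic acid (5 mg annually) in postmenopausal osteoporosis. Both
# published trials compared against placebo alone although established
# therapies (oral bisphosphonates, raloxifene, estrogens) exist, so neither
# qualifies: the verdict is N/A (calculation not available). Risk profiles
# are recorded for completeness but are never scored.
schema: evita_dossier
schema_version: 1
context:
  drug_name: zoledronic acid
  atc_code: M05BA08
  indication: "Postmenopausal osteoporosis at high fracture risk (ICD-10: M81)"
  therapeutic_aim: treatment
  disease_category: I
  established_therapies:
  - alendronic acid
  - risedronic acid
  - raloxifene
  - estrogens
trials:
- trial_id: ZOL-BMD-DOSE
  comparator_kind: placebo_only
  outcome_level: surrogate
  result: superiority
  jadad:
    randomization_mentioned: true
    randomization_appropriate: appropriate
    blinding_mentioned: true
    blinding_appropriate: appropriate
    withdrawals_described: true
- trial_id: HORIZON-PFT
  comparator_kind: placebo_only
  outcome_level: patient_relevant
  result: superiority
  jadad:
    randomization_mentioned: true
    randomization_appropriate: appropriate
    blinding_mentioned: true
    blinding_appropriate: appropriate
    withdrawals_described: true
  duration_years: 3.0
drug_risk:
  arm_label: zoledronic acid 5 mg/y
  grade_4_5_freq: 0.5
  grade_3_freq: 5.0
  grade_1_2_freq: 30.0
  interaction_class: dose_change
comparator_risk:
  arm_label: placebo
  grade_4_5_freq: 0.5
  grade_3_freq: 5.0
  grade_1_2_freq: 25.0
  interaction_class: unlikely_or_none
options:
  rounding: none
  yellow_half_width: 2.0
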