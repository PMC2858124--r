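# Bupropion in episodes of major depression. Three head-to-head trials
# against established antidepressants (paroxetine, venlafaxine) on depression
# scale scores (surrogate outcomes): inferiority in one, equivalence in two.
# Adverse-event and interaction profiles (from the product labels, as the
# trials were incompletely published) are identical for drug and comparators,
# so the net risk is zero.
schema: evita_dossier
schema_version: 1
context:
  drug_name: bupropion
  atc_code: N06AX12
  indication: "Major depression (ICD-10: F32-F39)"
  therapeutic_aim: treatment
  disease_category: I
  established_therapies:
  - paroxetine
  - venlafaxine
trials:
- trial_id: BUP-PAROX-HAMD
  comparator_kind: head_to_head
  outcome_level: surrogate
  result: non_inferiority_or_equivalence
  jadad:
    randomization_mentioned: true
    randomization_appropriate: appropriate
    blinding_mentioned: true
    blinding_appropriate: appropriate
    withdrawals_described: true
- trial_id: GSK-MADRS-1
  comparator_kind: head_to_head
  outcome_level: surrogate
  result: non_inferiority_or_equivalence
  jadad:
    randomization_mentioned: true
    randomization_appropriate: appropriate
    blinding_mentioned: true
    blinding_appropriate: not_described
    withdrawals_described: true
- trial_id: GSK-MADRS-2
  comparator_kind: head_to_head
  outcome_level: surrogate
  result: inferiority
  jadad:
    randomization_mentioned: true
    randomization_appropriate: appropriate
    blinding_mentioned: true
    blinding_appropriate: not_described
    withdrawals_described: true
# Mild/moderate AEs very common, severe AEs very common, life-threatening AEs
# less common; interactions occur occasionally with clinical consequences —
# for bupropion and its comparators alike: both arm sums are -7.5.
drug_risk:
  arm_label: bupropion
  grade_4_5_freq: 0.5
  grade_3_freq: 15.0
  grade_1_2_freq: 40.0
  interaction_class: occasional_or_clinical
comparator_risk:
  arm_label: venlafaxine / paroxetine
  grade_4_5_freq: 0.5
  grade_3_freq: 15.0
  grade_1_2_freq: 40.0
  interaction_class: occasional_or_clinical
options:
  rounding: none
  yellow_half_width: 2.0
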