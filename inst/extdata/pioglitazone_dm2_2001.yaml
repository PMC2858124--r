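# Pioglitazone in type-2 diabetes, evaluated on the evidence available in
# 2001 (shortly after approval): two placebo add-on trials on top of
# established oral antidiabetics, HbA1c (surrogate) as primary outcome, no
# NNT derivable. Efficiency 2 x +... rounds half-up to an integer, as the
# published evaluation reported it.
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
# Both severe and mild/moderate adverse effects occurred in under 10% of
# patients in both arms (no grade 4/5 events reported); gemfibrozil and
# rifampicin interactions may require pioglitazone dose changes, while the
# placebo comparator is assumed free of interaction potential.
drug_risk:
  arm_label: pioglitazone add-on
  grade_4_5_freq: 0.0
  grade_3_freq: 5.0
  grade_1_2_freq: 8.0
  interaction_class: dose_change
comparator_risk:
  arm_label: placebo add-on
  grade_4_5_freq: 0.0
  grade_3_freq: 5.0
  grade_1_2_freq: 8.0
  interaction_class: unlikely_or_none
options:
  rounding: half_up_integer
  yellow_half_width: 2.0
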