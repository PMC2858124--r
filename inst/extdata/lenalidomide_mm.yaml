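# Lenalidomide (add-on to high-dose dexamethasone) in refractory or relapsing
# multiple myeloma. Two twin-protocol registration trials collapse into one
# logical patient-relevant superiority trial; NNT 2.6 over 1.5 years.
schema: evita_dossier
schema_version: 1
context:
  drug_name: lenalidomide
  atc_code: L04AX04
  indication: "Refractory or relapsing multiple myeloma (ICD-10: C90)"
  therapeutic_aim: treatment
  disease_category: I
  established_therapies:
  - high-dose dexamethasone
  - anthracycline-based chemotherapy
  - bendamustine
  - cyclophosphamide
  - bortezomib
  - autologous stem cell retransplantation
trials:
- trial_id: MM-009
  comparator_kind: placebo_add_on
  outcome_level: patient_relevant
  result: superiority
  jadad:
    randomization_mentioned: true
    randomization_appropriate: appropriate
    blinding_mentioned: true
    blinding_appropriate: appropriate
    withdrawals_described: true
  duration_years: 1.5
  nnt: 2.6
  duplicate_protocol_key: mm009-mm010
- trial_id: MM-010
  comparator_kind: placebo_add_on
  outcome_level: patient_relevant
  result: superiority
  jadad:
    randomization_mentioned: true
    randomization_appropriate: appropriate
    blinding_mentioned: true
    blinding_appropriate: appropriate
    withdrawals_described: true
  duration_years: 1.5
  nnt: 2.6
  duplicate_protocol_key: mm009-mm010
# Very similar adverse-event frequencies in both arms (grade 3 events were
# slightly less frequent under placebo but within the same frequency class);
# lenalidomide carries a clinically relevant interaction risk, placebo none.
drug_risk:
  arm_label: lenalidomide + dexamethasone
  grade_4_5_freq: 5.0
  grade_3_freq: 50.0
  grade_1_2_freq: 70.0
  interaction_class: occasional_or_clinical
comparator_risk:
  arm_label: placebo + dexamethasone
  grade_4_5_freq: 5.0
  grade_3_freq: 45.0
  grade_1_2_freq: 70.0
  interaction_class: unlikely_or_none
options:
  rounding: none
  yellow_half_width: 2.0
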