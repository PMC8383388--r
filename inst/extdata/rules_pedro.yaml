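# PEDro scale rule table.  Item 1 (eligibility criteria) is recorded but
# unscored; the total counts satisfied items 2-11.  Each item lists the
# conditions (all must hold) on coding items; a missing or non-matching
# coding leaves the item unsatisfied (conservative).
index: pedro
max_total: 10
items:
  - key: eligibility_criteria_specified
    number: 1
    scored: false
    all_of:
      - {item: eligibility_criteria, any_of: [specified]}
  - key: random_allocation
    number: 2
    scored: true
    all_of:
      - {item: design, any_of: [randomized_controlled_trial, crossover_trial]}
  - key: concealed_allocation
    number: 3
    scored: true
    all_of:
      - {item: allocation_concealment, any_of: [concealed]}
  - key: baseline_comparability
    number: 4
    scored: true
    all_of:
      - {item: baseline_comparability, any_of: [similar]}
  - key: blinding_participants
    number: 5
    scored: true
    all_of:
      - {item: blinding_participants, any_of: [blinded]}
  - key: blinding_therapists
    number: 6
    scored: true
    all_of:
      - {item: blinding_personnel, any_of: [blinded]}
  - key: blinding_assessors
    number: 7
    scored: true
    all_of:
      - {item: blinding_assessors, any_of: [blinded]}
  - key: adequate_followup
    number: 8
    scored: true
    all_of:
      - {item: retention_rate, any_of: [over_85_percent]}
  - key: intention_to_treat
    number: 9
    scored: true
    all_of:
      - {item: intention_to_treat, any_of: [intention_to_treat]}
  - key: between_group_comparison
    number: 10
    scored: true
    all_of:
      - {item: between_group_comparison, any_of: [reported]}
  - key: point_and_variability
    number: 11
    scored: true
    all_of:
      - {item: point_and_variability_reported, any_of: [reported]}
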