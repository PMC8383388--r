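# Cochrane Risk of Bias rule table.  Each domain is rated low when all
# low_when conditions hold, high when ANY high_when condition holds
# (high takes precedence), and unclear otherwise.
index: rob
domains:
  - key: sequence_generation
    low_when:
      - {item: design, any_of: [randomized_controlled_trial, crossover_trial]}
      - {item: randomization_method, any_of: [computer_generated, random_number_table, coin_toss]}
    high_when:
      - {item: randomization_method, any_of: [alternation, date_of_birth]}
      - {item: design, any_of: [non_randomized_controlled_trial]}
  - key: allocation_concealment
    low_when:
      - {item: allocation_concealment, any_of: [concealed]}
    high_when:
      - {item: allocation_concealment, any_of: [not_concealed]}
  - key: blinding_participants_personnel
    low_when:
      - {item: blinding_participants, any_of: [blinded]}
      - {item: blinding_personnel, any_of: [blinded]}
    high_when:
      - {item: blinding_participants, any_of: [not_blinded]}
      - {item: blinding_personnel, any_of: [not_blinded]}
  - key: blinding_outcome_assessment
    low_when:
      - {item: blinding_assessors, any_of: [blinded]}
    high_when:
      - {item: blinding_assessors, any_of: [not_blinded]}
  - key: incomplete_outcome_data
    low_when:
      - {item: incomplete_outcome_data, any_of: [addressed]}
    high_when:
      - {item: incomplete_outcome_data, any_of: [not_addressed]}
  - key: selective_reporting
    low_when:
      - {item: selective_reporting, any_of: [all_prespecified_reported]}
    high_when:
      - {item: selective_reporting, any_of: [outcomes_missing]}
  - key: other
    low_when:
      - {item: other_bias, any_of: [none_apparent]}
    high_when:
      - {item: other_bias, any_of: [present]}
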