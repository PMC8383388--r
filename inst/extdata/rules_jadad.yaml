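# Jadad rule table (0-5): randomization mentioned / appropriate method,
# blinding mentioned / appropriate, withdrawals described.  Items combine
# several coded responses where the scale definition requires it.
index: jadad
max_total: 5
items:
  - key: randomization_mentioned
    scored: true
    all_of:
      - {item: design, any_of: [randomized_controlled_trial, crossover_trial]}
  - key: randomization_appropriate
    scored: true
    all_of:
      - {item: design, any_of: [randomized_controlled_trial, crossover_trial]}
      - {item: randomization_method, any_of: [computer_generated, random_number_table, coin_toss]}
  - key: blinding_mentioned
    scored: true
    all_of:
      - {item: double_blind_described, any_of: [described]}
  - key: blinding_appropriate
    scored: true
    all_of:
      - {item: double_blind_described, any_of: [described]}
      - {item: blinding_participants, any_of: [blinded]}
      - {item: blinding_assessors, any_of: [blinded]}
  - key: withdrawals_described
    scored: true
    all_of:
      - {item: withdrawals_described, any_of: [described]}
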