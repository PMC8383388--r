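# Coding item catalogue: the controlled vocabularies coders choose from.
# Administrators extend this file (new items, new response alternatives)
# without touching package code.  `multi: true` items accept several codes.
schema_version: 1
items:
  design:
    label: Study design
    required: true
    multi: false
    vocabulary:
      - randomized_controlled_trial
      - non_randomized_controlled_trial
      - crossover_trial
  population:
    label: Populations and sub-populations included
    required: true
    multi: true
    vocabulary:
      - healthy_older_adults
      - subjective_cognitive_decline
      - mild_cognitive_impairment
      - dementia
      - mixed_population
  intervention_type:
    label: Nature of the intervention
    required: true
    multi: true
    vocabulary:
      - cognitive_training
      - cognitive_stimulation
      - cognitive_rehabilitation
      - combined_cognitive_intervention
  setting:
    label: Setting of the study
    required: false
    multi: true
    vocabulary:
      - community
      - residential_care
      - outpatient_clinic
      - home_based
      - online
  eligibility_criteria:
    label: Eligibility criteria and source of participants
    required: false
    multi: false
    vocabulary: [specified, not_specified]
  randomization_method:
    label: Method used to generate the allocation sequence
    required: false
    multi: false
    vocabulary:
      - computer_generated
      - random_number_table
      - coin_toss
      - alternation
      - date_of_birth
      - not_reported
  allocation_concealment:
    label: Concealment of the allocation sequence
    required: false
    multi: false
    vocabulary: [concealed, not_concealed, not_reported]
  baseline_comparability:
    label: Baseline similarity of groups on prognostic indicators
    required: false
    multi: false
    vocabulary: [similar, different, not_reported]
  blinding_participants:
    label: Blinding of participants
    required: false
    multi: false
    vocabulary: [blinded, not_blinded, not_reported]
  blinding_personnel:
    label: Blinding of therapists / personnel delivering the intervention
    required: false
    multi: false
    vocabulary: [blinded, not_blinded, not_reported]
  blinding_assessors:
    label: Blinding of outcome assessors
    required: false
    multi: false
    vocabulary: [blinded, not_blinded, not_reported]
  double_blind_described:
    label: Study described as double blind
    required: false
    multi: false
    vocabulary: [described, not_described]
  retention_rate:
    label: Proportion of randomized participants providing the key outcome
    required: false
    multi: false
    vocabulary: [over_85_percent, under_85_percent, not_reported]
  intention_to_treat:
    label: Analysis population
    required: false
    multi: false
    vocabulary: [intention_to_treat, per_protocol, not_reported]
  between_group_comparison:
    label: Between-group statistical comparison reported
    required: false
    multi: false
    vocabulary: [reported, not_reported]
  point_and_variability_reported:
    label: Point measures and measures of variability reported
    required: false
    multi: false
    vocabulary: [reported, not_reported]
  withdrawals_described:
    label: Withdrawals and dropouts described per group
    required: false
    multi: false
    vocabulary: [described, not_described]
  incomplete_outcome_data:
    label: Handling of incomplete outcome data
    required: false
    multi: false
    vocabulary: [addressed, not_addressed, not_reported]
  selective_reporting:
    label: Outcome reporting relative to protocol / methods
    required: false
    multi: false
    vocabulary: [all_prespecified_reported, outcomes_missing, not_reported]
  other_bias:
    label: Other sources of bias
    required: false
    multi: false
    vocabulary: [none_apparent, present, not_reported]
  statistical_analyses:
    label: Statistical analyses done
    required: false
    multi: true
    vocabulary:
      - ancova
      - anova
      - mixed_models
      - t_tests
      - nonparametric_tests
      - other
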