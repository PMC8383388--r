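# Editable boilerplate and sentence templates used by the report builder.
overview: >
  Cognition-oriented treatments (COTs) are non-pharmacological interventions
  - such as cognitive training, cognitive stimulation, and cognitive
  rehabilitation - that engage people in structured or unstructured
  activities with the aim of maintaining or improving cognitive and daily
  function.  This report synthesizes the controlled-trial evidence currently
  held in the repository for the outcomes and populations selected below.
disclaimer: >
  This evidence repository is under active development: studies are being
  entered and verified on a rolling basis, and the set of trials
  contributing to any synthesis may change as coding progresses.  Results
  should therefore be interpreted with caution.
interpretation_sentence: >
  The treatment effect found suggests that {u3}% of the treatment will be
  above the mean of the control group, {overlap}% of the two groups will
  overlap, and there is a {prob_superiority}% chance that a person randomly
  picked from the treatment group will have a higher score on all specific
  outcomes than a person randomly picked from the control group.
statistical_information: >
  Pooled effects are standardized mean differences (Hedges' g) combined
  under a random-effects model with the restricted maximum likelihood (REML)
  estimator of the between-study variance and Hartung-Knapp-Sidik-Jonkman
  confidence intervals.  Heterogeneity is tested with the Q statistic
  (p < 0.10 flagged as significant), quantified with I-squared, and
  summarized with a 95% prediction interval.  Correlated outcomes within a
  study are combined as a composite assuming a between-measure correlation
  of r = 0.50 unless otherwise specified.
no_eligible_outcomes: >
  No outcome met the minimum criteria for pooling (at least 3 studies with
  usable means and standard deviations); no meta-analytic results are shown.
recommendation_phrases:
  strong_for: "a strong recommendation in favor of the intervention"
  modest_for: "a modest recommendation in favor of the intervention"
  none: "no recommendation"
  modest_against: "a modest recommendation against the intervention"
  strong_against: "a strong recommendation against the intervention"
narrative: >
  For {outcome} in {population}, the pooled effect was g = {g} (95% CI
  {ci_low} to {ci_high}) across {k} studies ({n_total} participants), a
  {magnitude} effect.  The certainty of this evidence was rated {certainty},
  leading to {recommendation_phrase}.
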