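# Certainty-grading configuration.  Three components (mean methodological
# quality, between-study heterogeneity, precision as total participants)
# are each banded favorable / intermediate / unfavorable; the certainty
# level is a pure function of the three bands.  All thresholds editable.
quality_index: pedro            # which index feeds mean methodological quality
quality:                        # on the chosen index's total scale
  favorable_min: 7              # mean total >= 7 -> favorable
  intermediate_min: 4           # 4 <= mean < 7 -> intermediate; else unfavorable
heterogeneity:                  # on the I2 (%) scale; lower is better
  favorable_max: 30             # I2 < 30 -> favorable
  intermediate_max: 60          # 30 <= I2 <= 60 -> intermediate; else unfavorable
precision:                      # total participants across contributing studies
  favorable_min: 400
  intermediate_min: 100
level_rule:
  high: all_favorable           # high iff every band favorable
  low_if_unfavorable_count: 2   # low iff >= 2 bands unfavorable ...
  low_if_quality_unfavorable: true  # ... or the quality band alone is unfavorable
magnitude_bands:                # |g| cut points for narrative wording
  trivial_max: 0.2
  small_max: 0.5
  moderate_max: 0.8
prediction_interval_df: k_minus_2   # alternative: k_minus_1
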