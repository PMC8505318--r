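# Modified Zemek 12-point PPCS risk score.
# Nine predictors, each contributing 0-2 points; maximum total 12.
# The published rule covers ages 5-18; this cohort extends to 24, so
# ages above 18 score 0 on the age predictor (the "modified" extension).
# PCSS-item predictors count as present when the item score is at least
# `item_present_min`.
item_present_min: 1
points:
  female: 2
  age_8_12: 1
  age_13_18: 2
  age_over_18: 0
  prior_concussion_symptoms_ge_1wk: 1
  migraine_history: 1
  feeling_slowed_down: 1
  balance_problems: 1
  headache: 1
  sensitivity_to_noise: 1
  fatigue: 2
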