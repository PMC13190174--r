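# Clinical default weight configuration.
# Feature weights prioritise age, gender and ethnicity; aggregation mixes
# coverage 60% / completeness 40%.
feature_weights:
  AGE_GROUP: 0.30
  GENDER: 0.25
  ETHNICITY: 0.20
  WEIGHT_GROUP: 0.10
  RELIGION: 0.05
  LANGUAGE: 0.05
  MARITAL_STATUS: 0.05
coverage_weight: 0.60
completeness_weight: 0.40
epsilon: 1.0e-10
log_base: 2
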