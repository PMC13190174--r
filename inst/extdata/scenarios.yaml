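# Robustness scenarios: feature-weight perturbations (aggregation fixed at
# 60/40) and aggregation-weight perturbations (features fixed at clinical).
clinical:
  coverage_weight: 0.60
  completeness_weight: 0.40
equal_weights:
  feature_weights:
    AGE_GROUP: 0.142857142857143
    GENDER: 0.142857142857143
    ETHNICITY: 0.142857142857143
    WEIGHT_GROUP: 0.142857142857143
    RELIGION: 0.142857142857143
    LANGUAGE: 0.142857142857143
    MARITAL_STATUS: 0.142857142857142
age_dominant:
  feature_weights:
    AGE_GROUP: 0.50
    GENDER: 0.178571428571429
    ETHNICITY: 0.142857142857143
    WEIGHT_GROUP: 0.0714285714285714
    RELIGION: 0.0357142857142857
    LANGUAGE: 0.0357142857142857
    MARITAL_STATUS: 0.0357142857142857
aggregation_70_30:
  coverage_weight: 0.70
  completeness_weight: 0.30
aggregation_60_40:
  coverage_weight: 0.60
  completeness_weight: 0.40
aggregation_50_50:
  coverage_weight: 0.50
  completeness_weight: 0.50
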