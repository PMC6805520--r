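{
  "hierarchy": "hierarchy.json",
  "dependency": "dependency_criteria.csv",
  "subjective_weights": "case_study",
  "objective_weights": "case_study",
  "probit_mode": "legacy_percent_table",
  "grade_thresholds": [4, 6]
}
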