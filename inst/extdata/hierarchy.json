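{
  "criteria_matrix": "table1_criteria.csv",
  "criteria": [
    {
      "name": "ES",
      "children": ["E1", "E2", "E3", "E4"],
      "local_weights": [0.4667, 0.2979, 0.0849, 0.1504]
    },
    {
      "name": "IS",
      "children": ["I1", "I2", "I3"],
      "local_weights": [0.122, 0.5584, 0.3196]
    },
    {
      "name": "TS",
      "children": ["T1", "T2", "T3", "T4"],
      "local_weights": [0.4554, 0.1409, 0.1409, 0.2628]
    }
  ]
}
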