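{
  "labels": {
    "criteria": ["ES", "IS", "TS"],
    "subcriteria": ["E1", "E2", "E3", "E4", "I1", "I2", "I3", "T1", "T2", "T3", "T4"]
  },
  "table1": {
    "provenance": "case study Table 1 (criterion pairwise comparisons)",
    "labels": ["ES", "IS", "TS"],
    "matrix": [
      ["1", "3", "2"],
      ["1/3", "1", "1/2"],
      ["1/2", "2", "1"]
    ],
    "weights": [0.5396, 0.1634, 0.297],
    "cr": 0.0079
  },
  "dependency": {
    "provenance": "case study section 3.1 (criterion dependency matrix omega2)",
    "labels": ["ES", "IS", "TS"],
    "matrix": [
      [0, 0.25, 0.25],
      [0.5, 0, 0.75],
      [0.5, 0.75, 0]
    ]
  },
  "omega3": {
    "provenance": "case study section 3.1 (interdependent criterion weights)",
    "values": [0.1151, 0.4926, 0.3924]
  },
  "table2": {
    "provenance": "case study Table 2 (sub-criterion local and global weights)",
    "criteria_weights": {
      "ES": 0.1151,
      "IS": 0.4926,
      "TS": 0.3924
    },
    "locals": {
      "ES": {
        "E1": 0.4667,
        "E2": 0.2979,
        "E3": 0.0849,
        "E4": 0.1504
      },
      "IS": {
        "I1": 0.122,
        "I2": 0.5584,
        "I3": 0.3196
      },
      "TS": {
        "T1": 0.4554,
        "T2": 0.1409,
        "T3": 0.1409,
        "T4": 0.2628
      }
    },
    "globals": {
      "E1": 0.0537,
      "E2": 0.0343,
      "E3": 0.0098,
      "E4": 0.0173,
      "I1": 0.0601,
      "I2": 0.275,
      "I3": 0.1574,
      "T1": 0.1787,
      "T2": 0.0553,
      "T3": 0.0553,
      "T4": 0.1031
    }
  },
  "omega_y": {
    "provenance": "case study section 3.1 (subjective sub-criterion weights after supermatrix)",
    "values": {
      "E1": 0.0615,
      "E2": 0.0587,
      "E3": 0.005,
      "E4": 0.0089,
      "I1": 0.052,
      "I2": 0.3409,
      "I3": 0.2052,
      "T1": 0.0955,
      "T2": 0.0318,
      "T3": 0.0346,
      "T4": 0.1058
    }
  },
  "sigma": {
    "provenance": "case study section 3.2 (contrast intensities; calibration range only)",
    "values": {
      "E1": 0.3093,
      "E2": 0.3162,
      "E3": 0.2624,
      "E4": 0.2674,
      "I1": 0.2992,
      "I2": 0.3302,
      "I3": 0.3037,
      "T1": 0.3004,
      "T2": 0.2788,
      "T3": 0.2766,
      "T4": 0.2839
    }
  },
  "information": {
    "provenance": "case study section 3.2 (information content C, 2 dp)",
    "values": {
      "E1": 2.78,
      "E2": 3.14,
      "E3": 2.12,
      "E4": 2.2,
      "I1": 2.79,
      "I2": 3.74,
      "I3": 2.75,
      "T1": 3.1,
      "T2": 3.06,
      "T3": 3.14,
      "T4": 2.3
    }
  },
  "omega_c": {
    "provenance": "case study section 3.2 (objective CRITIC weights)",
    "values": {
      "E1": 0.0894,
      "E2": 0.1009,
      "E3": 0.0681,
      "E4": 0.0708,
      "I1": 0.0898,
      "I2": 0.1201,
      "I3": 0.0884,
      "T1": 0.0996,
      "T2": 0.0983,
      "T3": 0.1009,
      "T4": 0.0739
    }
  },
  "table3": {
    "provenance": "case study Table 3 (fused comprehensive weights, descending)",
    "rows": [
      {
        "indicator": "I2",
        "subjective": 0.3409,
        "objective": 0.1201,
        "comprehensive": 0.2305
      },
      {
        "indicator": "I3",
        "subjective": 0.2052,
        "objective": 0.0884,
        "comprehensive": 0.1468
      },
      {
        "indicator": "T1",
        "subjective": 0.0955,
        "objective": 0.0996,
        "comprehensive": 0.0975
      },
      {
        "indicator": "T4",
        "subjective": 0.1058,
        "objective": 0.0739,
        "comprehensive": 0.0899
      },
      {
        "indicator": "E2",
        "subjective": 0.0587,
        "objective": 0.1009,
        "comprehensive": 0.0798
      },
      {
        "indicator": "E1",
        "subjective": 0.0615,
        "objective": 0.0894,
        "comprehensive": 0.0755
      },
      {
        "indicator": "I1",
        "subjective": 0.052,
        "objective": 0.0898,
        "comprehensive": 0.0709
      },
      {
        "indicator": "T3",
        "subjective": 0.0346,
        "objective": 0.1009,
        "comprehensive": 0.0677
      },
      {
        "indicator": "T2",
        "subjective": 0.0318,
        "objective": 0.0983,
        "comprehensive": 0.0651
      },
      {
        "indicator": "E4",
        "subjective": 0.0089,
        "objective": 0.0708,
        "comprehensive": 0.0398
      },
      {
        "indicator": "E3",
        "subjective": 0.005,
        "objective": 0.0681,
        "comprehensive": 0.0366
      }
    ]
  },
  "table4": {
    "provenance": "case study Table 4 (RSR distribution, legacy percent-table probits)",
    "rows": [
      {
        "indicator": "E3",
        "rsr": 0.0366,
        "f": 1,
        "f_cum": 1,
        "rank": 1,
        "mean_rank": 1,
        "p": 9.09,
        "y": 3.6592
      },
      {
        "indicator": "E4",
        "rsr": 0.0398,
        "f": 1,
        "f_cum": 2,
        "rank": 2,
        "mean_rank": 2,
        "p": 18.18,
        "y": 4.0846
      },
      {
        "indicator": "T2",
        "rsr": 0.0651,
        "f": 1,
        "f_cum": 3,
        "rank": 3,
        "mean_rank": 3,
        "p": 27.27,
        "y": 4.3872
      },
      {
        "indicator": "T3",
        "rsr": 0.0677,
        "f": 1,
        "f_cum": 4,
        "rank": 4,
        "mean_rank": 4,
        "p": 36.36,
        "y": 4.6415
      },
      {
        "indicator": "I1",
        "rsr": 0.0709,
        "f": 1,
        "f_cum": 5,
        "rank": 5,
        "mean_rank": 5,
        "p": 45.45,
        "y": 4.8743
      },
      {
        "indicator": "E1",
        "rsr": 0.0755,
        "f": 1,
        "f_cum": 6,
        "rank": 6,
        "mean_rank": 6,
        "p": 54.55,
        "y": 5.1004
      },
      {
        "indicator": "E2",
        "rsr": 0.0798,
        "f": 1,
        "f_cum": 7,
        "rank": 7,
        "mean_rank": 7,
        "p": 63.64,
        "y": 5.3319
      },
      {
        "indicator": "T4",
        "rsr": 0.0899,
        "f": 1,
        "f_cum": 8,
        "rank": 8,
        "mean_rank": 8,
        "p": 72.73,
        "y": 5.5828
      },
      {
        "indicator": "T1",
        "rsr": 0.0975,
        "f": 1,
        "f_cum": 9,
        "rank": 9,
        "mean_rank": 9,
        "p": 81.82,
        "y": 5.8779
      },
      {
        "indicator": "I3",
        "rsr": 0.1468,
        "f": 1,
        "f_cum": 10,
        "rank": 10,
        "mean_rank": 10,
        "p": 90.91,
        "y": 6.2816
      },
      {
        "indicator": "I2",
        "rsr": 0.2305,
        "f": 1,
        "f_cum": 11,
        "rank": 11,
        "mean_rank": 11,
        "p": 97.73,
        "y": 6.8808
      }
    ]
  },
  "table5": {
    "provenance": "case study Table 5 (three-grade classification)",
    "grade_1": [
      "E3"
    ],
    "grade_2": [
      "E4",
      "T2",
      "T3",
      "I1",
      "E1",
      "E2",
      "T4",
      "T1"
    ],
    "grade_3": [
      "I3",
      "I2"
    ]
  },
  "fig5": {
    "provenance": "case study Fig. 5 / section 3.3 (criterion shares of fused weights, %)",
    "es_share": 23.17,
    "ts_share": 32.02
  }
}
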