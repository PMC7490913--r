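[
  {
    "id": "D1",
    "rubric_weights": {
      "glucose": 1,
      "lactate": 1,
      "ph": 1,
      "potassium": 1,
      "po2": 1
    },
    "threshold_shift": {
      "glucose": 0.96,
      "lactate": 0.04,
      "ph": 0.0032,
      "potassium": 0.04,
      "po2": 0.96
    },
    "score_ceiling": 4,
    "intra_noise": 0.08
  },
  {
    "id": "D2",
    "rubric_weights": {
      "glucose": 1,
      "lactate": 1,
      "ph": 1,
      "potassium": 1,
      "po2": 1
    },
    "threshold_shift": {
      "glucose": 0,
      "lactate": 0,
      "ph": 0,
      "potassium": 0,
      "po2": 0
    },
    "score_ceiling": 4,
    "intra_noise": 0.08
  },
  {
    "id": "D3",
    "rubric_weights": {
      "glucose": 1,
      "lactate": 1,
      "ph": 1,
      "potassium": 1,
      "po2": 1
    },
    "threshold_shift": {
      "glucose": -0.96,
      "lactate": -0.04,
      "ph": -0.0032,
      "potassium": -0.04,
      "po2": -0.96
    },
    "score_ceiling": 4,
    "intra_noise": 0.08
  },
  {
    "id": "D4",
    "rubric_weights": {
      "glucose": 1,
      "lactate": 1,
      "ph": 1,
      "potassium": 1,
      "po2": 1
    },
    "threshold_shift": {
      "glucose": 0.48,
      "lactate": 0.016,
      "ph": 0.0016,
      "potassium": 0.016,
      "po2": 0.48
    },
    "score_ceiling": 3,
    "intra_noise": 0.08
  },
  {
    "id": "D5",
    "rubric_weights": {
      "glucose": 1,
      "lactate": 1,
      "ph": 1,
      "potassium": 1,
      "po2": 1
    },
    "threshold_shift": {
      "glucose": -0.48,
      "lactate": -0.016,
      "ph": -0.0016,
      "potassium": -0.016,
      "po2": -0.48
    },
    "score_ceiling": 4,
    "intra_noise": 0.08
  }
]
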