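{
  "0": {
    "glucose": [
      [70, 99]
    ],
    "lactate": [
      [0.5, 2]
    ],
    "ph": [
      [7.35, 7.45]
    ],
    "po2": [
      [100, 120]
    ]
  },
  "1": {
    "glucose": [
      [70, 99]
    ],
    "lactate": [
      [2, 3]
    ],
    "ph": [
      [7.35, 7.45]
    ],
    "po2": [
      [100, 120]
    ]
  },
  "2": {
    "glucose": [
      [55, 70],
      [99, 180]
    ],
    "lactate": [
      [2.5, 4]
    ],
    "ph": [
      [7.3, 7.4]
    ],
    "po2": [
      [100, 120]
    ]
  },
  "3": {
    "glucose": [
      [30, 60],
      [180, 300]
    ],
    "lactate": [
      [3.5, 8]
    ],
    "ph": [
      [7.2, 7.35]
    ],
    "po2": [
      [70, 100]
    ]
  },
  "4": {
    "glucose": [
      [25, 60],
      [200, 350]
    ],
    "lactate": [
      [4, 12]
    ],
    "ph": [
      [7, 7.25]
    ],
    "po2": [
      [40, 70]
    ]
  }
}
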