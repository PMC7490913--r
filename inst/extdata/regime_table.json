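{
  "glucose": {
    "low_max": 70,
    "normal": [70, 99],
    "high_min": 99,
    "unit": "mg/dL"
  },
  "lactate": {
    "low_max": 0.5,
    "normal": [0.5, 2],
    "high_min": 2,
    "unit": "mmol/L"
  },
  "ph": {
    "low_max": 7.35,
    "normal": [7.35, 7.45],
    "high_min": 7.45,
    "unit": "pH"
  },
  "potassium": {
    "low_max": 3.5,
    "normal": [3.5, 5.5],
    "high_min": 5.5,
    "unit": "mmol/L"
  },
  "po2": {
    "low_max": 100,
    "normal": [100, 120],
    "high_min": 120,
    "unit": "mmHg"
  }
}
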