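{
  "noise": {
    "area_cv": 0.005,
    "baseline_sd": 0.02,
    "seed": 42
  },
  "detection": {
    "tolerance": 0.15
  },
  "calibration": {
    "through_origin": true,
    "sigma_mode": "slope_sd"
  }
}
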