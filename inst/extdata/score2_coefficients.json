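{
  "name": "score2-2021",
  "description": "SCORE2 10-year CVD risk model: sex-specific Fine-Gray log-subdistribution-hazard coefficients on centred/scaled predictors, 10-year baseline survival, and the four European risk-region recalibration scale pairs. Transcribed from the published SCORE2 model supplementary material; shipped as data, not code.",
  "version": "1.0",
  "horizon_years": 10,
  "male": {
    "s0_10": 0.9605,
    "terms": [
      {"name": "age",     "center": 60,  "scale": 5,   "interacts_with_age": false, "beta":  0.3742},
      {"name": "smoking", "center": 0,   "scale": 1,   "interacts_with_age": false, "beta":  0.6012},
      {"name": "sbp",     "center": 120, "scale": 20,  "interacts_with_age": false, "beta":  0.2777},
      {"name": "tchol",   "center": 6,   "scale": 1,   "interacts_with_age": false, "beta":  0.1458},
      {"name": "hdl",     "center": 1.3, "scale": 0.5, "interacts_with_age": false, "beta": -0.2698},
      {"name": "smoking", "center": 0,   "scale": 1,   "interacts_with_age": true,  "beta": -0.0755},
      {"name": "sbp",     "center": 120, "scale": 20,  "interacts_with_age": true,  "beta": -0.0255},
      {"name": "tchol",   "center": 6,   "scale": 1,   "interacts_with_age": true,  "beta": -0.0281},
      {"name": "hdl",     "center": 1.3, "scale": 0.5, "interacts_with_age": true,  "beta":  0.0426}
    ],
    "scales": {
      "low":       [-0.5699, 0.7476],
      "moderate":  [-0.1565, 0.8009],
      "high":      [ 0.3207, 0.9360],
      "very_high": [ 0.5836, 0.8294]
    }
  },
  "female": {
    "s0_10": 0.9776,
    "terms": [
      {"name": "age",     "center": 60,  "scale": 5,   "interacts_with_age": false, "beta":  0.4648},
      {"name": "smoking", "center": 0,   "scale": 1,   "interacts_with_age": false, "beta":  0.7744},
      {"name": "sbp",     "center": 120, "scale": 20,  "interacts_with_age": false, "beta":  0.3131},
      {"name": "tchol",   "center": 6,   "scale": 1,   "interacts_with_age": false, "beta":  0.1002},
      {"name": "hdl",     "center": 1.3, "scale": 0.5, "interacts_with_age": false, "beta": -0.2606},
      {"name": "smoking", "center": 0,   "scale": 1,   "interacts_with_age": true,  "beta": -0.1088},
      {"name": "sbp",     "center": 120, "scale": 20,  "interacts_with_age": true,  "beta": -0.0277},
      {"name": "tchol",   "center": 6,   "scale": 1,   "interacts_with_age": true,  "beta": -0.0226},
      {"name": "hdl",     "center": 1.3, "scale": 0.5, "interacts_with_age": true,  "beta":  0.0613}
    ],
    "scales": {
      "low":       [-0.7380, 0.7019],
      "moderate":  [-0.3143, 0.7701],
      "high":      [ 0.5710, 0.9369],
      "very_high": [ 0.9412, 0.8329]
    }
  }
}
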