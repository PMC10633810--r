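{
  "instrument": {
    "magnetic_field": 12,
    "mz_max": 3000,
    "mz_min_frag": 250,
    "delta_t1": 3e-06,
    "n_t1": 512,
    "n_t2": 4096,
    "t2_duration": 0.00128,
    "detection_harmonic": 2
  },
  "calibration": {
    "coeff_b": 0
  },
  "simulation": {
    "seed": 1,
    "fixture": "ubiquitin",
    "occupancy": [0.7, 0.8, 0.35, 0.4, 0.45, 0.6, 0.9, 0.95],
    "charge_states": [8, 9],
    "n_mods": [4, 5],
    "isotopes": false,
    "noise": {
      "thermal_sigma": 0.02,
      "scintillation_cv": 0,
      "leakage_1w": 0,
      "harmonic_weights": [0.2, 0.05]
    }
  },
  "processing": {
    "beta": 6,
    "zerofill": 1,
    "rank": null,
    "snr_threshold": 5,
    "rank_seed": 1
  },
  "quantification": {
    "tol_ppm": 400,
    "series": ["c", "z"],
    "n_adjacent": 5,
    "snr_threshold": 5
  }
}
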