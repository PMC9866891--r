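{
  "version": "1.0",
  "units": "kcal/mol",
  "note": "Frozen standardized-space MLR equations and Endocrine-Disruptome-style class thresholds for five nuclear hormone receptors. Coefficients act on standard-scaled descriptors; thresholds are ordered T1 < T2 < T3 (T1 most negative).",
  "receptors": {
    "PPARA": {
      "name": "PPAR alpha",
      "pdb": "3KDU",
      "n_train": 29,
      "descriptors": ["icr", "pw2"],
      "intercept": -7.499,
      "se_intercept": 0.067,
      "coefficients": {"icr": -0.947, "pw2": -0.394},
      "se_coefficients": {"icr": 0.070, "pw2": 0.070},
      "thresholds": {"t1": -10.0, "t2": -9.4, "t3": -8.9}
    },
    "PPARB": {
      "name": "PPAR beta",
      "pdb": "3GZ9",
      "n_train": 29,
      "descriptors": ["icr", "x_percent"],
      "intercept": -8.248,
      "se_intercept": 0.069,
      "coefficients": {"icr": -1.059, "x_percent": -0.409},
      "se_coefficients": {"icr": 0.071, "x_percent": 0.071},
      "thresholds": {"t1": -10.5, "t2": -10.1, "t3": -9.6}
    },
    "PPARG": {
      "name": "PPAR gamma",
      "pdb": "3ET3",
      "n_train": 33,
      "descriptors": ["icr", "x_percent"],
      "intercept": -7.727,
      "se_intercept": 0.052,
      "coefficients": {"icr": -1.099, "x_percent": -0.398},
      "se_coefficients": {"icr": 0.053, "x_percent": 0.053},
      "thresholds": {"t1": -10.3, "t2": -9.6, "t3": -8.9}
    },
    "TRA": {
      "name": "TR alpha",
      "pdb": "3ILZ",
      "n_train": 33,
      "descriptors": ["x_percent", "icr"],
      "intercept": -8.230,
      "se_intercept": 0.070,
      "coefficients": {"x_percent": -0.454, "icr": -1.189},
      "se_coefficients": {"x_percent": 0.071, "icr": 0.071},
      "thresholds": {"t1": -10.2, "t2": -9.2, "t3": -7.2}
    },
    "TRB": {
      "name": "TR beta",
      "pdb": "3IMY",
      "n_train": 29,
      "descriptors": ["x_percent", "tpc"],
      "intercept": -8.724,
      "se_intercept": 0.054,
      "coefficients": {"x_percent": -0.137, "tpc": -1.509},
      "se_coefficients": {"x_percent": 0.061, "tpc": 0.061},
      "thresholds": {"t1": -10.5, "t2": -9.4, "t3": -7.8}
    }
  }
}
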