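{
  "quinidine": {
    "class": "Ia",
    "scheme": "OPEN_STATE",
    "kon": 0.0046884592022,
    "koff": 0.0001,
    "beta1_affinity_factor": 1,
    "max_block": 1,
    "concentrations": [
      3,
      10,
      30
    ],
    "calibration": {
      "preset": "NAV15",
      "conc_uM": 30,
      "target_block": 0.65
    }
  },
  "ajmaline": {
    "class": "Ia",
    "scheme": "OPEN_STATE",
    "kon": 0.0155279032426,
    "koff": 0.0001,
    "beta1_affinity_factor": 1,
    "max_block": 1,
    "concentrations": [
      3,
      10,
      30
    ],
    "calibration": {
      "preset": "NAV15",
      "conc_uM": 10,
      "target_block": 0.67
    }
  },
  "lidocaine": {
    "class": "Ib",
    "scheme": "INACTIVATED_STATE",
    "kon": 0.00143462432401,
    "koff": 0.005,
    "beta1_affinity_factor": 2.9,
    "max_block": 0.9,
    "concentrations": [
      3,
      10,
      30,
      100,
      300,
      1000
    ],
    "calibration": {
      "preset": "NAV15",
      "conc_uM": 30,
      "target_block": 0.56
    }
  },
  "phenytoin": {
    "class": "Ib",
    "scheme": "INACTIVATED_STATE",
    "kon": 0.000723381675295,
    "koff": 0.005,
    "beta1_affinity_factor": 2.0,
    "max_block": 0.75,
    "concentrations": [
      3,
      10,
      30,
      100,
      300
    ],
    "calibration": {
      "preset": "NAV15",
      "conc_uM": 30,
      "target_block": 0.4
    }
  },
  "flecainide": {
    "class": "Ic",
    "scheme": "OPEN_STATE",
    "kon": 0.00180762442278,
    "koff": 1e-05,
    "beta1_affinity_factor": 1,
    "max_block": 1,
    "concentrations": [
      3,
      10,
      30
    ],
    "calibration": {
      "preset": "NAV15",
      "conc_uM": 10,
      "target_block": 0.73
    }
  }
}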