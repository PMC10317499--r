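{
  "version": "1.0",
  "RT_kcal_mol": 0.59,
  "temperature_C": 23,
  "reference_concentration_M": 1.0,
  "L0": {
    "hyperpolarized": {
      "value": 7.4e-07,
      "voltage_mV": -100,
      "note": "wild-type unliganded gating constant at -100 mV"
    },
    "depolarized_eS450W": {
      "value": 5.2e-07,
      "voltage_mV": 70,
      "note": "effective unliganded gating constant at +70 mV with the eS450W compensating background; also quoted at -70 mV without it"
    }
  },
  "e_fold_mV": 60,
  "fold_table": {
    "eS450W": 1.0,
    "eL269F": 179,
    "eE181W": 5.5,
    "dV269A": 250
  },
  "ACh_reference": {
    "KdC_M": 1.74e-04,
    "KdO_M": 2.9e-08
  },
  "dead_time_ms": 0.025,
  "tcrit_ms": 20,
  "delta_LL_stop": 10,
  "eta_class_means": [0.32, 0.41, 0.45, 0.51, 0.55],
  "eta_class_sds": [0.035, 0.005, 0.014, 0.008, 0.015]
}
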