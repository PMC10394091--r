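{
  "name": "stemcell-ref",
  "description": "Reference parameterisation of the six-compartment cancer stem-cell model used for sensitivity analysis.",
  "k": {
    "k1": 0.35, "k2": 0.2, "k3": 0.1, "k4": 0.1, "k5": 0.2,
    "k6": 0.1, "k7": 0.1, "k8": 0.05, "k9": 0.1, "k10": 0.1,
    "k11": 1.0, "k12": 0.1, "k13": 0.1, "k14": 0.1
  },
  "k_note": "k13 and k14 are package defaults (0.1); they are absent from the printed reference list",
  "alpha": 0.8,
  "init": { "C0": 100, "Pk0": 0, "S0": 100, "E0": 0, "Nk0": 10, "Ik0": 0 },
  "grid": { "t0": 0, "t_final": 30, "h": 0.015625 }
}
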