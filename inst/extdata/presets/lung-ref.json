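{
  "name": "lung-ref",
  "description": "Reference parameterisation of the tumor-immune-metastasis model and its therapy extension, as used by the package simulations.",
  "base": {
    "lam": 0.3, "K": 10000, "mu": 0.01, "gamma": 0.07, "delta": 0.001,
    "beta1": 0.01, "beta2": 0.01, "beta3": 0.04,
    "phi1": 0.03, "phi2": 0.04, "phi3": 0.01,
    "I_baseline": 90
  },
  "therapy": {
    "eps1": 0.5, "eps2": 0.5, "eps3": 0.5, "eps4": 0.5, "tau": 5,
    "eps_note": "efficacies are package defaults, not part of the printed reference list"
  },
  "phi_control": {
    "phi1": 0.9, "phi2": 0.458, "phi3": 0.8, "phi4": 0.45, "phi5": 0.5,
    "phi6": 0.6, "phi7": 0.5, "phi8": 0.6, "phi9": 0.9, "phi10": 0.5
  },
  "theta_scalar": 0.5,
  "eta": 0.7,
  "alpha_control": 0.3,
  "alphas": [0.5, 0.7, 0.9],
  "init": { "N0": 3000, "I0": 90, "P0": 20, "T0": 0, "W0": 100, "V0": 50 },
  "grid": { "t0": 0, "t_final": 400, "h": 0.015625 },
  "control_grid": { "t0": 0, "t_final": 30, "h": 0.1 }
}
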