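{
  "schema": "piptazpk-parameters",
  "version": "1.0",
  "reference_covariates": { "ce": 108.25, "wt": 61.7, "lbm": 50.08 },
  "drugs": {
    "piperacillin": {
      "theta": {
        "cl": 11.2,
        "cl_ce": 1.16,
        "v1": 6.24,
        "q": 4.32,
        "q_lbm": 2.50,
        "v2": 2.59,
        "v2_wt": 0.0288
      },
      "fixed": ["q"],
      "omega": { "cl": 0.0717, "v1": 0.184 },
      "sigma": 0.134,
      "fu": 0.7
    },
    "tazobactam": {
      "theta": {
        "cl": 12.4,
        "cl_ce": 0.857,
        "v1": 9.03,
        "q": 4.39,
        "v2": 3.21,
        "v2_wt": 0.0145
      },
      "fixed": ["q"],
      "omega": { "cl": 0.0695 },
      "sigma": 0.135,
      "fu": null
    }
  }
}
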