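{
  "schema": "piptazpk-population",
  "version": "1.0",
  "comment": "Sex-specific normal distributions for adult demographics. Means are the study cohort medians; SDs place the observed min-max at the central 95% (SD = range/3.92); bounds truncate to physiological adult values.",
  "male": {
    "age":    { "mean": 39.0,  "sd": 4.592,  "lower": 19.0,  "upper": 55.0 },
    "height": { "mean": 171.0, "sd": 5.612,  "lower": 140.0, "upper": 210.0 },
    "weight": { "mean": 69.1,  "sd": 8.673,  "lower": 35.0,  "upper": 130.0 },
    "cr":     { "mean": 0.965, "sd": 0.0714, "lower": 0.30,  "upper": 2.00 },
    "cc":     { "mean": 0.830, "sd": 0.0893, "lower": 0.30,  "upper": 2.50 }
  },
  "female": {
    "age":    { "mean": 29.5,  "sd": 2.551,  "lower": 19.0,  "upper": 55.0 },
    "height": { "mean": 163.0, "sd": 2.296,  "lower": 140.0, "upper": 210.0 },
    "weight": { "mean": 56.1,  "sd": 3.495,  "lower": 35.0,  "upper": 130.0 },
    "cr":     { "mean": 0.690, "sd": 0.0408, "lower": 0.30,  "upper": 2.00 },
    "cc":     { "mean": 0.700, "sd": 0.0306, "lower": 0.30,  "upper": 2.50 }
  }
}
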