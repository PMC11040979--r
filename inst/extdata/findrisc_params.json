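{
  "model": "FINDRISC concise logistic model (10-year T2D risk)",
  "note": "Point estimates transcribed from the published concise drug-treated-diabetes risk model; standard errors are synthetic plausible values used only for probabilistic sensitivity analysis.",
  "intercept": {"estimate": -5.514, "se": 0.30},
  "coefficients": {
    "age_45_54":            {"estimate": 0.628, "se": 0.15},
    "age_55_64":            {"estimate": 0.892, "se": 0.15},
    "bmi_25to30":           {"estimate": 0.165, "se": 0.12},
    "bmi_gt30":             {"estimate": 0.857, "se": 0.15},
    "waist_mid":            {"estimate": 0.857, "se": 0.18},
    "waist_high":           {"estimate": 1.350, "se": 0.18},
    "bp_medication":        {"estimate": 0.711, "se": 0.17},
    "high_glucose_history": {"estimate": 2.139, "se": 0.25}
  }
}
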