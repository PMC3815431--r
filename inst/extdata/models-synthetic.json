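[
  {"_comment": "SYNTHETIC PLACEHOLDER COEFFICIENTS for demonstration and testing only. They were not estimated from any claims dataset; replace this file with externally supplied coefficients before clinical use. Outcome: probability that the 1-year MPR falls below 0.8, from age (years) and the running MPR at the prediction day.",
   "drug_class": "antihyperlipidemics", "prediction_day": 60,
   "intercept": 2.2, "beta_age": -0.012, "beta_mpr": -3.1},
  {"drug_class": "antihyperlipidemics", "prediction_day": 90,
   "intercept": 2.1, "beta_age": -0.012, "beta_mpr": -3.3},
  {"drug_class": "antihyperlipidemics", "prediction_day": 120,
   "intercept": 2.0, "beta_age": -0.012, "beta_mpr": -3.5},
  {"drug_class": "antihypertensives", "prediction_day": 60,
   "intercept": 1.9, "beta_age": -0.010, "beta_mpr": -2.9},
  {"drug_class": "antihypertensives", "prediction_day": 90,
   "intercept": 1.8, "beta_age": -0.010, "beta_mpr": -3.1},
  {"drug_class": "antihypertensives", "prediction_day": 120,
   "intercept": 1.7, "beta_age": -0.010, "beta_mpr": -3.3},
  {"drug_class": "oral_hypoglycemics", "prediction_day": 60,
   "intercept": 2.0, "beta_age": -0.011, "beta_mpr": -3.0},
  {"drug_class": "oral_hypoglycemics", "prediction_day": 90,
   "intercept": 1.9, "beta_age": -0.011, "beta_mpr": -3.2},
  {"drug_class": "oral_hypoglycemics", "prediction_day": 120,
   "intercept": 1.8, "beta_age": -0.011, "beta_mpr": -3.4}
]
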