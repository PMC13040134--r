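{
  "label": "SYNTHETIC stand-in coefficient set for an ADNEX-style multinomial risk model",
  "note": "These are NOT the published ADNEX coefficients. They reproduce the published model's structure (multinomial logit over five outcome classes with benign as reference, with- and without-CA125 variants, log transforms of the marker and size predictors) with sign-correct, realistically scaled synthetic values, so that the calculator's contracts (probability simplex, per-predictor monotonicity, variant behavior) can be exercised and tested. Replace this file with a transcription of the published coefficients before any comparison against clinical data.",
  "classes": ["borderline", "stage_I", "stage_II_IV", "metastatic"],
  "transforms": {
    "age": "identity",
    "ca125": "log",
    "max_lesion_diameter": "log",
    "proportion_solid": "identity",
    "more_than_10_locules": "binary",
    "n_papillary_projections": "identity",
    "acoustic_shadows": "binary",
    "ascites": "binary",
    "oncology_center": "binary"
  },
  "with_ca125": {
    "borderline":  {"intercept": -6.20, "age": 0.012, "ca125": 0.15, "max_lesion_diameter": 0.50, "proportion_solid": 1.00, "more_than_10_locules": 0.45, "n_papillary_projections": 0.50, "acoustic_shadows": -0.80, "ascites": 0.20, "oncology_center": 0.30},
    "stage_I":     {"intercept": -8.17, "age": 0.020, "ca125": 0.35, "max_lesion_diameter": 0.60, "proportion_solid": 2.40, "more_than_10_locules": 0.30, "n_papillary_projections": 0.35, "acoustic_shadows": -1.00, "ascites": 0.50, "oncology_center": 0.40},
    "stage_II_IV": {"intercept": -10.72, "age": 0.040, "ca125": 0.90, "max_lesion_diameter": 0.50, "proportion_solid": 3.20, "more_than_10_locules": 0.20, "n_papillary_projections": 0.25, "acoustic_shadows": -1.20, "ascites": 1.30, "oncology_center": 0.50},
    "metastatic":  {"intercept": -8.90, "age": 0.030, "ca125": 0.45, "max_lesion_diameter": 0.40, "proportion_solid": 2.60, "more_than_10_locules": 0.30, "n_papillary_projections": 0.20, "acoustic_shadows": -1.00, "ascites": 0.90, "oncology_center": 0.40}
  },
  "without_ca125": {
    "borderline":  {"intercept": -5.77, "age": 0.012, "max_lesion_diameter": 0.50, "proportion_solid": 1.00, "more_than_10_locules": 0.45, "n_papillary_projections": 0.50, "acoustic_shadows": -0.80, "ascites": 0.20, "oncology_center": 0.30},
    "stage_I":     {"intercept": -7.16, "age": 0.020, "max_lesion_diameter": 0.60, "proportion_solid": 2.40, "more_than_10_locules": 0.30, "n_papillary_projections": 0.35, "acoustic_shadows": -1.00, "ascites": 0.50, "oncology_center": 0.40},
    "stage_II_IV": {"intercept": -8.11, "age": 0.040, "max_lesion_diameter": 0.50, "proportion_solid": 3.20, "more_than_10_locules": 0.20, "n_papillary_projections": 0.25, "acoustic_shadows": -1.20, "ascites": 1.30, "oncology_center": 0.50},
    "metastatic":  {"intercept": -7.60, "age": 0.030, "max_lesion_diameter": 0.40, "proportion_solid": 2.60, "more_than_10_locules": 0.30, "n_papillary_projections": 0.20, "acoustic_shadows": -1.00, "ascites": 0.90, "oncology_center": 0.40}
  }
}
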