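{
  "version": "1.0",
  "description": "Published rectal dose-reduction linear models for hydrogel spacer decision support (21-patient modelling cohort, 60 Gy / 20 fraction VMAT). Model 1 uses all geometric features; Model 2 only treatment-planning-system volume metrics.",
  "models": {
    "delta_model1": {
      "dependent": "delta_rv55_pct",
      "intercept": {"estimate": -4.26, "se": 4.09},
      "terms": [
        {"term": "norm_rinptv_pct", "estimate": 1.25, "se": 0.18, "rs2": 0.97},
        {"term": "rw_to_ctv_cm", "estimate": 0.23, "se": 0.17, "rs2": 0.38},
        {"term": "rectum_vol_cc", "estimate": -0.0077, "se": 0.0101, "rs2": 0.18}
      ],
      "r_squared": 0.83,
      "predicted_r_squared": 0.63,
      "mae": 1.29,
      "pct_mae": 12.90,
      "p_label": "<0.0001",
      "n": 21,
      "notes": "Evaluating these coefficients at the cohort-mean features does not recover the cohort-mean response; the coefficients are shipped exactly as published and predictions carry a warning."
    },
    "delta_model2": {
      "dependent": "delta_rv55_pct",
      "intercept": {"estimate": 0.73, "se": 0.51},
      "terms": [
        {"term": "norm_rinptv_pct", "estimate": 1.10, "se": 0.12, "rs2": 1.00}
      ],
      "r_squared": 0.81,
      "predicted_r_squared": 0.76,
      "mae": 0.96,
      "pct_mae": 9.60,
      "p_label": "<0.0001",
      "n": 21
    },
    "pre_model1": {
      "dependent": "pre_rv55_pct",
      "intercept": {"estimate": -0.45, "se": 1.10},
      "terms": [
        {"term": "norm_rinptv_pct", "estimate": 1.19, "se": 0.20, "rs2": 0.97},
        {"term": "norm_ctv_pct", "estimate": 0.012, "se": 0.007, "rs2": 0.12},
        {"term": "rw_to_ctv_inv_cubed", "estimate": 13.88, "se": 11.4, "rs2": 0.33}
      ],
      "r_squared": 0.88,
      "predicted_r_squared": 0.76,
      "mae": 1.48,
      "pct_mae": 11.62,
      "p_label": "<0.0001",
      "n": 21
    },
    "pre_model2": {
      "dependent": "pre_rv55_pct",
      "intercept": {"estimate": 0.67, "se": 0.61},
      "terms": [
        {"term": "norm_rinptv_pct", "estimate": 1.37, "se": 0.13, "rs2": 0.98},
        {"term": "norm_ctv_pct", "estimate": 0.009, "se": 0.006, "rs2": 0.12}
      ],
      "r_squared": 0.87,
      "predicted_r_squared": 0.79,
      "mae": 1.35,
      "pct_mae": 10.65,
      "p_label": "<0.0001",
      "n": 21
    }
  },
  "correlations": {
    "delta_rv55_pct": {
      "rectum_vol_cc": -0.38,
      "rw_vol_cc": -0.37,
      "rinptv_cc": 0.68,
      "norm_rinptv_pct": 0.90,
      "ctv_vol_cc": 0.22,
      "norm_ctv_pct": 0.29,
      "rw_to_ctv_cm": -0.56,
      "rw_to_ctv_inv_cubed": 0.33
    },
    "pre_rv55_pct": {
      "rectum_vol_cc": -0.33,
      "rw_vol_cc": -0.32,
      "rinptv_cc": 0.76,
      "norm_rinptv_pct": 0.92,
      "ctv_vol_cc": 0.27,
      "norm_ctv_pct": 0.32,
      "rw_to_ctv_cm": -0.61,
      "rw_to_ctv_inv_cubed": 0.54
    }
  },
  "cohort_summary": {
    "delta_rv55_pct":     {"mean": 4.5,  "sd": 3.0,  "min": 0.8,  "max": 10.8},
    "pre_rv55_pct":       {"mean": 5.9,  "sd": 3.7,  "min": 0.8,  "max": 13.5},
    "rectum_vol_cc":      {"mean": 79.2, "sd": 32.1, "min": 35.5, "max": 149.7},
    "rw_vol_cc":          {"mean": 35.5, "sd": 9.7,  "min": 20.5, "max": 57.8},
    "ctv_vol_cc":         {"mean": 39.9, "sd": 17.2, "min": 24.6, "max": 91.5},
    "norm_ctv_pct":       {"mean": 62.3, "sd": 51.7, "min": 19.6, "max": 257.7},
    "rinptv_cc":          {"mean": 2.4,  "sd": 1.5,  "min": 0.1,  "max": 5.3},
    "norm_rinptv_pct":    {"mean": 3.4,  "sd": 2.4,  "min": 0.2,  "max": 10.4},
    "rw_to_ctv_cm":       {"mean": 2.18, "sd": 0.26, "min": 1.71, "max": 2.63},
    "rw_to_ctv_cubed_cc": {"mean": 10.36, "sd": 4.06, "min": 4.99, "max": 18.21}
  }
}
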