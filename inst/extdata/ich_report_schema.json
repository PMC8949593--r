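{
  "title": "IchReport",
  "description": "Required sections and fields of a serialized ICH-style validation report",
  "required": {
    "method": ["modality", "preprocessing", "calibration_range_w_w", "n_calibration", "n_validation"],
    "specificity": ["lv1_percent_x_variance"],
    "linearity": ["r2_cal", "r2_pred", "calibration_range_w_w"],
    "accuracy": ["rmsec", "rmsecv", "rmsep", "bias"],
    "lv_selection": ["rmsecv_by_nlv", "selected_n_lv", "selection_rule"],
    "score_ellipse": ["alpha", "t2_limit", "lv_pair", "n_cal"]
  }
}
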