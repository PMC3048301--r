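# SCORE risk-equation coefficients, low-risk European region.
# Transcribed from the published low-risk SCORE calibration (Weibull
# baseline survival S0(age) = exp(-exp(alpha) * (age - 20)^p); individual
# log-hazard w = beta_smoker*smoker + beta_sbp*(sbp - 120)
#             + beta_tchol*(tchol - 6)).
# The file is editable so alternative calibrations (e.g. high-risk region
# or later revisions) can be swapped in without a code change.
version: score2003-low
horizon: 10
reference:
  sbp: 120
  tchol: 6
diabetes_multiplier:
  M: 2
  F: 4
endpoints:
  chd:
    M: {alpha: -22.1, p: 4.71, beta_smoker: 0.71, beta_sbp: 0.018, beta_tchol: 0.24}
    F: {alpha: -29.8, p: 6.36, beta_smoker: 0.71, beta_sbp: 0.018, beta_tchol: 0.24}
  non_chd:
    M: {alpha: -26.7, p: 5.64, beta_smoker: 0.63, beta_sbp: 0.022, beta_tchol: 0.02}
    F: {alpha: -31.0, p: 6.62, beta_smoker: 0.63, beta_sbp: 0.022, beta_tchol: 0.02}
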