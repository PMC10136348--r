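# Default cohort simulator configuration: a six-centre mCRPC population of
# radium-223-treated patients. Marginals are moment-matched to the published
# multicentre cohort characteristics; hazard ratios are per-unit effects on
# overall survival (months). `baseline_scale` is calibrated (see
# calibrate_baseline) so the Kaplan-Meier median OS is 13 months under the
# multivariate effect set.

marginals:
  age:            {dist: normal,            mean: 73.6,  sd: 8.1}
  gleason:        {dist: categorical,       values: [5, 6, 7, 8, 9, 10],
                   counts: [2, 18, 105, 83, 98, 7]}
  ecog:           {dist: categorical,       values: [0, 1, 2, 3],
                   counts: [176, 131, 58, 5]}
  prior_radical_treatment: {dist: bernoulli, p: 0.44044}
  lymphadenopathies:       {dist: bernoulli, p: 0.38855}
  prior_chemo:             {dist: bernoulli, p: 0.62162}
  bone_agents:             {dist: bernoulli, p: 0.52162}
  n_prior_treatments: {dist: categorical,   values: [0, 1, 2, 3, 4],
                       counts: [51, 102, 89, 70, 49]}
  hb:             {dist: truncnormal,       mean: 11.9,  sd: 1.6, lower: 6, upper: 18}
  talp:           {dist: lognormal_moments, mean: 251.1, sd: 310.9}
  psa:            {dist: lognormal_moments, mean: 230.7, sd: 580.1}
  bsi:            {dist: gamma_moments,     mean: 2.98,  sd: 2.42}

# Sparse Gaussian-copula correlations (unlisted pairs are 0). Chosen so that
# performance status, age and nodal disease are marginally prognostic but
# conditionally null given the multivariate covariate set.
copula_correlation:
  - {vars: [bsi, talp],  rho: 0.4}
  - {vars: [bsi, hb],    rho: -0.3}
  - {vars: [ecog, bsi],  rho: 0.3}
  - {vars: [age, ecog],  rho: 0.2}

# Per-unit hazard ratios. Univariate set drives MARGINAL mode (single active
# covariate); multivariate set drives MULTIVARIATE mode.
effects_univariate:
  age: 1.011
  prior_radical_treatment: 0.787
  gleason: 1.115
  lymphadenopathies: 1.437
  ecog: 1.580
  hb: 0.706
  talp: 1.001
  psa: 1.001
  bsi: 1.137

effects_multivariate:
  gleason: 1.096
  hb: 0.744
  talp: 1.001
  psa: 1.0005
  bsi: 1.054

# Reference means used to centre covariates in the linear predictor.
reference_means:
  age: 73.6
  gleason: 7.88818
  ecog: 0.70811
  prior_radical_treatment: 0.44044
  lymphadenopathies: 0.38855
  prior_chemo: 0.62162
  bone_agents: 0.52162
  n_prior_treatments: 1.90028
  hb: 11.9
  talp: 251.1
  psa: 230.7
  bsi: 2.98

baseline_shape: 1.3
baseline_scale: 17.865529   # calibrate_baseline(..., 13 months, n_calib = 50000)
target_event_fraction: 0.88108   # 326 / 370
n_centers: 6
frailty_sd: 0.1
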