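# Default synthetic-cohort configuration.
# Cluster 1 is the higher metabolic-deviance cluster. SSPG and leptin
# means/SDs are the published per-cluster statistics; BMI and FPG marginals
# are chosen so the cohort mixture reproduces the published category
# percentages (86% FPG < 100 mg/dL; 13/51/36% normo/over/obese). Remaining
# marginals are realistic defaults for a healthy middle-aged sample.
n_enrolled: 126
n_complete: 104
cluster_sizes: [51, 53]
metabolic:
  variables: [BMI, WC, SSPG, FPI, FPG, leptin, cortisol]
  units: ["kg/m^2", "cm", "mg/dL", "uU/mL", "mg/dL", "ug/L", "a.u."]
  cluster1:
    mean: [29.3, 100.0, 161.63, 13.0, 95.0, 40.36, 12.0]
    sd:   [2.6,    9.0,  65.27,  6.0,  7.0, 29.97,  3.5]
  cluster2:
    mean: [27.8,  93.0, 125.72,  9.0, 90.0, 27.59, 12.0]
    sd:   [2.6,    9.0,  66.81,  4.5,  6.5, 25.58,  3.5]
  # moderate positive correlations among the adiposity / insulin-resistance
  # block; cortisol near-independent of everything else
  correlation:
    - [1.00, 0.75, 0.45, 0.50, 0.35, 0.60, 0.05]
    - [0.75, 1.00, 0.45, 0.50, 0.35, 0.55, 0.05]
    - [0.45, 0.45, 1.00, 0.55, 0.45, 0.40, 0.05]
    - [0.50, 0.50, 0.55, 1.00, 0.40, 0.45, 0.05]
    - [0.35, 0.35, 0.45, 0.40, 1.00, 0.30, 0.05]
    - [0.60, 0.55, 0.40, 0.45, 0.30, 1.00, 0.05]
    - [0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 1.00]
female_fraction: [0.75, 0.45]
age: {mean: 46.0, sd: 12.0}
ethnicity:
  levels: [white, asian, hispanic, other]
  probs: [0.55, 0.20, 0.15, 0.10]
cognitive:
  iq: {mean: 115.0, sd: 11.0}
  memory_pairing: {mean: 55.0, sd: 9.0}
  memory_recall: {mean: 52.0, sd: 9.0}
motion:
  meanlog: -2.526   # log(0.08 mm)
  sdlog: 0.40
  max_excess_meanlog: 0.182   # log(1.2): max = mean * (1 + lognormal excess)
  max_excess_sdlog: 0.40
connectivity:
  rho_within: [0.15, 0.30]
  rho_cross: [0.25, 0.45]
  rho_rsn: 0.30
  hemisphere_cor: 0.50
  rho_logit_sd: 0.50
seed: 42
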