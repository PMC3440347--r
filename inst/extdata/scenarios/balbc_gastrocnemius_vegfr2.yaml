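# Simulation scenario: VEGFR2 on BALB/c gastrocnemius (ex vivo).
# The receptor distribution is given as observed (post-exclusion) median and
# CV; the loader deconvolves these to population parameters by inverting the
# 3-SD single-pass truncation (see calibrate_receptor_lognormal).
name: balbc_gastrocnemius_vegfr2
condition:
  strain: "BALB/c"
  tissue: gastrocnemius
  receptor: VEGFR2
  setting: ex vivo
receptor_distribution:
  family: lognormal
  observed:
    median: 1800
    cv_percent: 480
    exclusion_k: 3
published:
  ensemble_n: 6
  ensemble_mean: 1600
  ensemble_sem: 400
  n_cells: 26065
  median: 1800
  cv_percent: 480
  skewness: 53
  kurtosis: 3500
n_cells: 10000
n_replicates: 6
unlabeled_n: 5000
instrument:
  gain: 2
  noise_cv: 0.15
  autofluor_gm: 600
  autofluor_cv: 0.3
populations:
  contaminant_fraction: 0.10
  debris_fraction: 0.05
  doublet_fraction: 0.05
bead:
  n_per_level: 2000
  noise_cv: 0.05
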