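# Simulation scenario: VEGFR2 on human EC (in vitro).
# The receptor distribution is given as observed (post-exclusion) median and
# CV; the loader deconvolves these to population parameters by inverting the
# 3-SD single-pass truncation (see calibrate_receptor_lognormal).
name: human_ec_vegfr2
condition:
  strain: "human EC"
  receptor: VEGFR2
  setting: in vitro
receptor_distribution:
  family: lognormal
  observed:
    median: 7300
    cv_percent: 485
    exclusion_k: 3
published:
  ensemble_n: 58
  ensemble_mean: 5800
  ensemble_sem: 300
  n_cells: 141513
  median: 7300
  cv_percent: 485
  skewness: 74
  kurtosis: 7800
n_cells: 10000
n_replicates: 58
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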