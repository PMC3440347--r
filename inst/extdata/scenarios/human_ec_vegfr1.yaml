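# Simulation scenario: VEGFR1 on human EC (in vitro).
# The receptor distribution is given as observed (post-exclusion) median and
# CV; the loader deconvolves these to population parameters by inverting the
# 3-SD single-pass truncation (see calibrate_receptor_lognormal).
name: human_ec_vegfr1
condition:
  strain: "human EC"
  receptor: VEGFR1
  setting: in vitro
receptor_distribution:
  family: lognormal
  observed:
    median: 2200
    cv_percent: 709
    exclusion_k: 3
published:
  ensemble_n: 63
  ensemble_mean: 1800
  ensemble_sem: 100
  n_cells: 149124
  median: 2200
  cv_percent: 709
  skewness: 180
  kurtosis: 42000
n_cells: 10000
n_replicates: 63
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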