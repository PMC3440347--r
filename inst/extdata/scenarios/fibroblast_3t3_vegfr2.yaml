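# Simulation scenario: VEGFR2 on 3T3 fibroblast (in vitro).
# The receptor distribution is given as observed (post-exclusion) median and
# CV; the loader deconvolves these to population parameters by inverting the
# 3-SD single-pass truncation (see calibrate_receptor_lognormal).
name: fibroblast_3t3_vegfr2
condition:
  strain: "3T3 fibroblast"
  receptor: VEGFR2
  setting: in vitro
receptor_distribution:
  family: lognormal
  observed:
    median: 2000
    cv_percent: 69
    exclusion_k: 3
published:
  ensemble_n: 9
  ensemble_mean: 700
  ensemble_sem: 100
  n_cells: 90482
  median: 2000
  cv_percent: 69
  skewness: 10
  kurtosis: 180
n_cells: 10000
n_replicates: 9
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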