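# Simulation scenario: unenriched skeletal-muscle cell suspension stained
# with anti-CD34-FITC and anti-VEGFR2-PE. CD34-positive endothelial target
# cells are ~5% of all collected events, the rest being CD34-negative
# contaminants (myocytes, pericytes, immune cells), debris and doublets —
# the pre-enrichment situation the scatter + FL1 gates must resolve.
name: raw_muscle_suspension
condition:
  strain: "C57BL/6"
  tissue: gastrocnemius
  receptor: VEGFR2
  setting: ex vivo (unenriched)
receptor_distribution:
  family: lognormal
  observed:
    median: 1300
    cv_percent: 100
    exclusion_k: 3
published:
  target_fraction_of_total: 0.05
n_cells: 20000
n_replicates: 3
unlabeled_n: 10000
instrument:
  gain: 2
  noise_cv: 0.15
  autofluor_gm: 600
  autofluor_cv: 0.3
populations:
  contaminant_fraction: 0.75
  debris_fraction: 0.12
  doublet_fraction: 0.08
bead:
  n_per_level: 2000
  noise_cv: 0.05
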