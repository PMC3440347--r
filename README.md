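# receptorcensus

Absolute surface-receptor quantification from calibrated flow cytometry,
with a ground-truth forward simulator.

## The problem

How many receptors does a single cell actually carry on its surface?
Systems-biology models of ligand–receptor signaling (for example
VEGF–VEGFR models of angiogenesis) need absolute receptor numbers per
cell, but cytometers report fluorescence in arbitrary units, cells are
heterogeneous, and raw acquisitions mix target cells with contaminants,
debris and doublets. Quantitative cytometry solves this with PE-bead
standards: beads carrying known numbers of phycoerythrin molecules are
acquired under the cells' instrument settings, and a log-log regression of
bead FL2 geometric means on PE molecules/bead,

    log10(FL2) = m · log10(PE) + b,

converts any event's fluorescence into PE molecules — and, with saturating
1:1 PE-antibody labeling, into receptors per cell.

`receptorcensus` implements the full inverse pipeline — singlet scatter
gating, CD34/FL1 positivity gating, bead calibration, per-event conversion
with autofluorescence background subtraction — and both reporting levels
used in practice: the **ensemble** summary (replicate-level estimates,
mean ± SEM) and the **cell-by-cell** analysis (pooling, single-pass 3-SD
outlier exclusion, median / CV / skewness / excess kurtosis, 500-receptor
histograms, two-sample Kolmogorov–Smirnov comparison, ANOVA + Tukey HSD).
A forward simulator generates bead, unlabeled-cell and labeled-cell event
tables with known ground truth, so every stage is testable without an
instrument; packaged scenarios emulate published VEGFR1/VEGFR2 censuses on
mouse skeletal-muscle endothelial cells, human endothelial cells in vitro
and 3T3 fibroblasts. See `vignette("receptor-quantification")` for the
model, parameterization and design decisions.

## Worked example

```r
library(receptorcensus)

res1 <- run_scenario("c57bl6_gastrocnemius_vegfr1", seed = 1)
res2 <- run_scenario("c57bl6_gastrocnemius_vegfr2", seed = 2)
print(res1)
#> Scenario: c57bl6_gastrocnemius_vegfr1
#>   condition: C57BL/6 / gastrocnemius / VEGFR1 / ex vivo
#>   ensemble: 1863 +/- 8 receptors/cell (n = 11 replicates)
#>   cell-by-cell: n = 86093, median = 1811, CV = 110%, skew = 2.20, excess kurtosis = 5.48
#>   clamped to zero: 0.15% of converted events
```

Each run simulates 11 replicates (10,000 collected events each plus
unlabeled reference and beads), fits a fresh bead calibration per
replicate, gates, converts and summarises. The ensemble line says: across
11 simulated mice, the mean surface density is ~1,860 VEGFR1 per
endothelial cell (geometric-mean replicate estimates). The cell-by-cell
line pools ~86,000 gated cells after 3-SD exclusion: median 1,811
receptors/cell with CV 110% — cell-to-cell heterogeneity is large and
right-skewed, far from Gaussian.

```r
build_report(list(res1, res2))
#>   sample                        receptor  n mean  sem n_cells median cv_percent skewness kurtosis
#> 1 c57bl6_gastrocnemius_vegfr1   VEGFR1   11 1900  7.9   86093   1800        110      2.2      5.5
#> 2 c57bl6_gastrocnemius_vegfr2   VEGFR2   11 1300  3.9   86033   1300        101      2.1      4.7

ks_two_sample(res1$pooled, res2$pooled)
#> K-S: D = 0.128, p ~ 0  (n_eff = 43031)
```

The two receptors differ both on average (VEGFR1 above VEGFR2) and as
whole distributions (K-S p ≪ 0.001 at pooled-cell sample sizes).
Compartment arithmetic extends surface counts with literature surface
fractions:

```r
compartment_estimate(2800, surface_fraction = 0.2)
#> surface: 2,800 receptors/cell (20% of total)
#> total: 14,000   intracellular: ~11,000 receptors/cell
```

Lower-level building blocks (`generate_cell_events()`, `gate_singlets()`,
`calibrate_from_beads()`, `receptors_per_cell()`, `pool_and_exclude()`,
`anova_tukey()`, ...) are all exported; `inst/cli/receptorcensus.R` is a
thin command-line wrapper (`list` / `simulate` / `run`).

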