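test_that("receptor draws match the configured population median and CV", {
  dist <- list(family = "lognormal", median = 1800, cv = 1.1)
  r <- draw_receptor_counts(dist, 1e5, seed = 101)
  expect_true(all(r >= 0))
  expect_equal(median(r), 1800, tolerance = 0.02)
  expect_equal(sd(r) / mean(r), 1.1, tolerance = 0.02)
  expect_length(draw_receptor_counts(dist, 0), 0)
  expect_error(draw_receptor_counts(list(family = "gamma", shape = 1), 10),
               "family")
})

test_that("log-normal draws show the closed-form skewness cv^3 + 3 cv", {
  # tight check at moderate cv; loose at cv = 1.1 where the sample skewness
  # estimator converges slowly (the fourth moment is enormous)
  skew <- function(x) { m <- mean(x); mean((x - m)^3) / mean((x - m)^2)^1.5 }
  r1 <- draw_receptor_counts(list(family = "lognormal", median = 100, cv = 0.3),
                             2e5, seed = 7)
  expect_equal(skew(r1), 0.3^3 + 3 * 0.3, tolerance = 0.05)
  r2 <- draw_receptor_counts(list(family = "lognormal", median = 1800, cv = 1.1),
                             1e6, seed = 8)
  expect_equal(skew(r2), 1.1^3 + 3 * 1.1, tolerance = 0.25)
})

test_that("mixture draws honour component weights and medians", {
  dist <- list(family = "lognormal_mixture", components = list(
    list(median = 100, sdlog = 0.1, weight = 0.5),
    list(median = 10000, sdlog = 0.1, weight = 0.5)))
  r <- draw_receptor_counts(dist, 2e4, seed = 9)
  expect_equal(mean(r < 1000), 0.5, tolerance = 0.03)
  expect_equal(median(r[r < 1000]), 100, tolerance = 0.02)
  expect_equal(median(r[r > 1000]), 10000, tolerance = 0.02)
})

test_that("noiseless labeled events carry fl2 equal to true receptor counts", {
  cfg <- noiseless_scenario()
  tab <- generate_cell_events(cfg, labeled = TRUE, seed = 21)
  expect_true(all(tab$population_label == "target"))
  expect_equal(tab$fl2, tab$true_receptors)  # gain 1, eps 1, A 0

  # fl2 scales with gain
  cfg2 <- noiseless_scenario()
  cfg2$instrument$gain <- 0.5
  tab2 <- generate_cell_events(cfg2, labeled = TRUE, seed = 21)
  expect_equal(tab2$fl2, 0.5 * tab2$true_receptors)
})

test_that("unlabeled-cell fl2 is pure autofluorescence, independent of receptors", {
  cfg <- scenario_config(
    receptor_distribution = list(family = "lognormal", median = 5000, cv = 1),
    populations = list(contaminant_fraction = 0, debris_fraction = 0,
                       doublet_fraction = 0),
    instrument = list(noise_cv = 0.1, autofluor_gm = 600, autofluor_cv = 0.3),
    unlabeled_n = 2e4)
  tab <- generate_cell_events(cfg, labeled = FALSE, seed = 31)
  # geometric mean equals the configured autofluorescence GM, nowhere near
  # the receptor-driven signal
  expect_equal(as.numeric(geometric_mean(tab$fl2)), 600, tolerance = 0.02)
  expect_lt(quantile(tab$fl2, 0.99), cfg$instrument$gain * 5000)
})

test_that("bead events form spikes at gain * PE level with unbiased geomeans", {
  cfg <- noiseless_scenario()
  beads <- generate_bead_events(cfg, seed = 41)
  expect_setequal(unique(beads$fl2), c(515, 5956, 26653, 69045))
  cfg$instrument$gain <- 0.1
  beads2 <- generate_bead_events(cfg, seed = 41)
  expect_setequal(round(unique(beads2$fl2), 6),
                  round(0.1 * c(515, 5956, 26653, 69045), 6))

  cfg3 <- noiseless_scenario()
  cfg3$instrument$gain <- 2
  cfg3$bead$noise_cv <- 0.05
  cfg3$bead$n_per_level <- 1e4
  beads3 <- generate_bead_events(cfg3, seed = 42)
  for (k in 1:4) {
    lvl <- as.numeric(bead_level_set())[k]
    v <- beads3$fl2[beads3$population_label == paste0("bead_level_", k)]
    expect_equal(as.numeric(geometric_mean(v)), 2 * lvl, tolerance = 0.01)
  }
})

test_that("generated median/CV pass through the exclusion deconvolution", {
  # population parameters from observed statistics: simulating and
  # re-applying the single-pass 3-SD exclusion recovers the observed values
  for (case in list(c(1800, 1.1), c(3000, 1.2), c(2000, 0.69))) {
    pop <- calibrate_receptor_lognormal(case[1], case[2], k = 3)
    r <- draw_receptor_counts(list(family = "lognormal", median = pop$median,
                                   cv = pop$cv), 2e5, seed = 50 + case[1])
    kept <- pool_and_exclude(r, k = 3)
    expect_equal(median(kept), case[1], tolerance = 0.03)
    expect_equal(sd(kept) / mean(kept), case[2], tolerance = 0.04)
    expect_equal(1 - length(kept) / length(r), 1 - pop$keep_fraction,
                 tolerance = 0.15)
  }
})

test_that("packaged scenarios load and the raw suspension yields ~5% target cells", {
  expect_true("c57bl6_gastrocnemius_vegfr1" %in% list_scenarios())
  cfg <- scenario("raw_muscle_suspension")
  set.seed(61)
  lab <- generate_cell_events(cfg, labeled = TRUE)
  unl <- generate_cell_events(cfg, labeled = FALSE)
  gate <- fit_scatter_gate(lab)
  gated <- gate_fl1_positive(gate_singlets(lab, gate), fl1_threshold(),
                             unlabeled_reference = gate_singlets(unl, gate))
  expect_equal(nrow(gated) / nrow(lab), 0.05, tolerance = 0.3)
  expect_gt(mean(gated$population_label == "target"), 0.98)
})
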