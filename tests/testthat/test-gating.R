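test_that("gating is a pure filter: subset, order preserved, intensities untouched", {
  tab <- random_events(500, seed = 3)
  gate <- scatter_gate(fsc = c(2e4, 8e4), ssc = c(0, 9e4))
  out <- gate_singlets(tab, gate)
  expect_true(nrow(out) < nrow(tab))
  inside <- tab$fsc >= 2e4 & tab$fsc <= 8e4 & tab$ssc <= 9e4
  expect_equal(out$fl2, tab$fl2[inside])

  # full-range gate is the identity; empty table stays empty
  all_gate <- scatter_gate(fsc = c(0, 1e9), ssc = c(0, 1e9))
  expect_equal(nrow(gate_singlets(tab, all_gate)), nrow(tab))
  empty <- event_table(numeric(0), numeric(0), numeric(0), numeric(0))
  expect_equal(nrow(gate_singlets(empty, all_gate)), 0)

  expect_error(scatter_gate(fsc = c(5, 5), ssc = c(0, 1)), "degenerate")
  expect_error(polygon_gate(fsc = c(0, 1, 2), ssc = c(0, 0, 0)), "degenerate")
})

test_that("polygon gates agree with the equivalent rectangle", {
  tab <- random_events(300, seed = 4)
  rect <- scatter_gate(fsc = c(2e4, 7e4), ssc = c(1e4, 6e4))
  poly <- polygon_gate(fsc = c(2e4, 7e4, 7e4, 2e4), ssc = c(1e4, 1e4, 6e4, 6e4))
  expect_equal(nrow(gate_singlets(tab, poly)), nrow(gate_singlets(tab, rect)))
})

test_that("automatic singlet gate isolates the dominant cluster from debris and doublets", {
  cfg <- scenario("c57bl6_gastrocnemius_vegfr1")
  set.seed(5)
  tab <- generate_cell_events(cfg, labeled = TRUE)
  gated <- gate_singlets(tab, fit_scatter_gate(tab))
  labs <- gated$population_label
  expect_gt(mean(labs %in% c("target", "contaminant")), 0.95)
  # most singlet targets are retained
  expect_gt(sum(labs == "target") / sum(tab$population_label == "target"), 0.95)
})

test_that("composing scatter and FL1 gates equals intersecting the two filters", {
  cfg <- scenario("c57bl6_gastrocnemius_vegfr1")
  set.seed(6)
  tab <- generate_cell_events(cfg, labeled = TRUE)
  gate <- fit_scatter_gate(tab)
  thr <- fl1_threshold(1000, rule = "fixed")
  seq_gated <- gate_fl1_positive(gate_singlets(tab, gate), thr)
  in_scatter <- tab$fsc >= gate$fsc[1] & tab$fsc <= gate$fsc[2] &
    tab$ssc >= gate$ssc[1] & tab$ssc <= gate$ssc[2]
  manual <- tab[in_scatter & tab$fl1 > 1000, ]
  expect_equal(seq_gated$fl2, manual$fl2)
})

test_that("FL1 gating resolves its threshold from the unlabeled reference", {
  cfg <- scenario("c57bl6_gastrocnemius_vegfr1")
  set.seed(7)
  lab <- generate_cell_events(cfg, labeled = TRUE)
  unl <- generate_cell_events(cfg, labeled = FALSE)
  # pipeline order: singlet gate first (removes FL1-positive doublets),
  # then the FL1 gate selects CD34+ target cells
  g <- fit_scatter_gate(lab)
  unl_g <- gate_singlets(unl, g)
  out <- gate_fl1_positive(gate_singlets(lab, g), fl1_threshold(),
                           unlabeled_reference = unl_g)
  expect_gt(mean(out$population_label == "target"), 0.99)
  cut <- attr(out, "fl1_threshold")
  expect_equal(cut, quantile(unl_g$fl1, 0.999, names = FALSE))

  # threshold 0 (fixed) keeps every positive-FL1 event
  out0 <- gate_fl1_positive(lab, fl1_threshold(0, rule = "fixed"))
  expect_equal(nrow(out0), sum(lab$fl1 > 0))
  expect_error(gate_fl1_positive(lab, fl1_threshold()), "reference")
})

test_that("bead level assignment is exact when noiseless and near-perfect at 5% CV", {
  cfg <- noiseless_scenario()
  beads <- generate_bead_events(cfg, seed = 8)
  by_level <- identify_bead_levels(beads, bead_level_set())
  for (k in 1:4) {
    expect_true(all(by_level[[k]]$population_label ==
                      paste0("bead_level_", k)))
  }

  cfg$bead$noise_cv <- 0.05
  cfg$bead$n_per_level <- 1e4
  beads2 <- generate_bead_events(cfg, seed = 9)
  by2 <- identify_bead_levels(beads2, bead_level_set())
  correct <- sum(vapply(1:4, function(k) {
    sum(by2[[k]]$population_label == paste0("bead_level_", k))
  }, numeric(1)))
  expect_gte(correct / nrow(beads2), 0.999)

  # fewer events than levels is a calibration-input error
  few <- event_table(fsc = 1:3, ssc = 1:3, fl1 = 1:3, fl2 = c(500, 6000, 27000))
  expect_error(identify_bead_levels(few, bead_level_set()), "fewer")
  # overlapping populations are unresolvable
  set.seed(10)
  blur <- event_table(fsc = runif(400), ssc = runif(400), fl1 = runif(400),
                      fl2 = rlnorm(400, log(1000), 1.5))
  expect_error(identify_bead_levels(blur, bead_level_set()), "overlap|resolvable")
})
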