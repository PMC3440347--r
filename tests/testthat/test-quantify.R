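ident_curve <- function(gain = 1) {
  fit_calibration(gain * as.numeric(bead_level_set()), bead_level_set())
}

test_that("background estimation inverts the autofluorescence model", {
  curve <- ident_curve()
  # zero autofluorescence -> zero background
  unl0 <- event_table(fsc = 1:5, ssc = 1:5, fl1 = 1:5, fl2 = rep(0, 5))
  expect_equal(background_pe(unl0, curve), 0)

  # noiseless 300 PE-equivalents -> exactly 300
  unl1 <- event_table(fsc = 1:5, ssc = 1:5, fl1 = 1:5, fl2 = rep(300, 5))
  expect_equal(background_pe(unl1, curve), 300, tolerance = 1e-9)

  # noisy: GM-preserving log-normal autofluorescence recovers its median
  set.seed(14)
  fl2 <- 300 * rlnorm(1e4, 0, sqrt(log(1 + 0.3^2)))
  unl2 <- event_table(fsc = rep(1, 1e4), ssc = rep(1, 1e4),
                      fl1 = rep(1, 1e4), fl2 = fl2)
  expect_equal(background_pe(unl2, curve), 300, tolerance = 0.03)

  empty <- event_table(numeric(0), numeric(0), numeric(0), numeric(0))
  expect_error(background_pe(empty, curve), "empty")
})

test_that("per-cell conversion subtracts background and clamps at zero", {
  curve <- ident_curve()
  cells <- event_table(fsc = 1:3, ssc = 1:3, fl1 = 1:3,
                       fl2 = c(2300, 100, 300))
  smp <- receptors_per_cell(cells, curve, background = 300)
  expect_equal(smp$per_cell, c(2000, 0, 0))
  expect_equal(smp$n_clamped, 1)   # the 100 goes negative; 300 hits exactly 0
  expect_equal(smp$background_pe, 300)

  # subtraction switch off
  smp2 <- receptors_per_cell(cells, curve, background = 300, subtract = FALSE)
  expect_equal(smp2$per_cell, c(2300, 100, 300))

  expect_warning(
    empty <- receptors_per_cell(
      event_table(numeric(0), numeric(0), numeric(0), numeric(0)), curve),
    "empty")
  expect_length(empty$per_cell, 0)
})

test_that("noiseless forward model inverts exactly through the full pipeline", {
  res <- run_scenario(noiseless_scenario(n_cells = 400, n_replicates = 2),
                      pipeline = wide_open_pipeline(), seed = 15)
  # regenerate the same events to obtain ground truth
  set.seed(15)
  cfg <- noiseless_scenario(n_cells = 400, n_replicates = 2)
  truth <- list()
  for (i in 1:2) {
    invisible(generate_bead_events(cfg))
    invisible(generate_cell_events(cfg, labeled = FALSE))
    truth[[i]] <- generate_cell_events(cfg, labeled = TRUE)$true_receptors
  }
  for (i in 1:2) {
    expect_equal(res$samples[[i]]$per_cell, truth[[i]], tolerance = 1e-9)
  }
  expect_equal(res$clamp_fraction, 0)
})

test_that("ensemble summary computes replicate means and SEM as defined", {
  mk <- function(v) receptor_sample(v)
  # arithmetic location on crafted replicates: means {2, 4, 6}
  samples <- list(mk(c(1, 3)), mk(c(3, 5)), mk(c(5, 7)))
  ens <- ensemble_summary(samples, location = "arithmetic")
  expect_equal(ens$replicate_estimates, c(2, 4, 6))
  expect_equal(ens$mean, 4)
  expect_equal(ens$sem, 2 / sqrt(3), tolerance = 1e-12)

  # identical replicates -> SEM 0; replicate order is irrelevant
  same <- list(mk(c(2, 2)), mk(c(2, 2)))
  expect_equal(ensemble_summary(same)$sem, 0)
  expect_equal(ensemble_summary(rev(samples), "arithmetic")$mean, ens$mean)

  # geometric location equals the GM of per-cell values
  g <- ensemble_summary(list(mk(c(2, 8, 32))))
  expect_equal(g$mean, 8)
})

test_that("condition compilation reproduces replicate-weighted averages", {
  expect_equal(compile_conditions(c(5), n = c(7)), 5)
  v1 <- compile_conditions(c(2600, 3700, 2000, 3200), n = c(6, 6, 11, 10))
  expect_equal(v1, 91800 / 33, tolerance = 1e-12)
  v2 <- compile_conditions(c(1600, 2000, 1300, 1700), n = c(6, 6, 11, 10))
  expect_equal(v2, 52900 / 33, tolerance = 1e-12)
  # equal weights reduce to the plain average
  expect_equal(compile_conditions(c(1, 2, 6), n = c(4, 4, 4)), 3)
})

test_that("compartment arithmetic follows the surface-fraction identities", {
  ce <- compartment_estimate(2800, surface_fraction = 0.2)
  expect_equal(ce$total, 14000)
  expect_equal(ce$intracellular, 11200)
  ce2 <- compartment_estimate(1600, surface_fraction = 0.6,
                              recycled_fraction = 0.5)
  expect_equal(ce2$intracellular, 1600 / 0.6 - 1600, tolerance = 1e-12)
  expect_equal(ce2$recycled, 0.5 * ce2$intracellular, tolerance = 1e-12)
  expect_equal(compartment_estimate(500, 1)$intracellular, 0)
  expect_error(compartment_estimate(500, 0), "surface_fraction")
  expect_error(compartment_estimate(500, -0.2), "surface_fraction")
})
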