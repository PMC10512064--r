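test_that("the generator is deterministic under a seed and restores RNG state", {
  truth <- default_ground_truth()
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  d1 <- generate_kinetics_dataset(truth, seed = 9)
  after <- stats::runif(1)
  d2 <- generate_kinetics_dataset(truth, seed = 9)
  d3 <- generate_kinetics_dataset(truth, seed = 10)
  expect_identical(d1, d2)
  expect_false(identical(d1$amount_nmol, d3$amount_nmol))
  expect_identical(before, after)  # caller's RNG stream untouched
  expect_error(generate_kinetics_dataset(truth), "seed")
})

test_that("zero kinetic noise reproduces the model output exactly", {
  truth <- noise_free_truth()
  ds <- generate_kinetics_dataset(truth, seed = 1)
  scen <- standard_scenarios(1)
  for (i in sample(nrow(ds), 10)) {
    sc <- kinetox:::rescale_scenario(scen[[ds$scenario_label[i]]],
                                     ds$nominal_uM[i], assay_setup())
    tr <- solve_piecewise_exact(truth$params, sc, ds$time_h[i])
    comp <- paste0(ds$compartment[i], "_nmol")
    expect_equal(ds$amount_nmol[i], tr[[comp]][1], tolerance = 1e-10)
  }
})

test_that("replicate means converge to the model value (lognormal unit mean)", {
  truth <- default_ground_truth(replicates = 1000,
                                sampling_times = c(6, 24), nominal_set = 1)
  ds <- generate_kinetics_dataset(truth, seed = 21)
  mu <- generate_kinetics_dataset(noise_free_truth(replicates = 1,
                                                   sampling_times = c(6, 24),
                                                   nominal_set = 1), seed = 1)
  agg <- stats::aggregate(amount_nmol ~ scenario_label + compartment + time_h,
                          ds, mean)
  key <- function(d) paste(d$scenario_label, d$compartment, d$time_h)
  m <- mu$amount_nmol[match(key(agg), key(mu))]
  expect_true(all(abs(agg$amount_nmol - m) / m < 0.02))
})

test_that("the default design mirrors the destructive-sampling study", {
  design <- default_kinetics_design()
  expect_setequal(unique(design$time_h[design$scenario_label == "48 h"]),
                  c(1, 3, 6, 24, 48))
  expect_setequal(unique(design$time_h[design$scenario_label == "7 dW"]),
                  c(168, 336))
  expect_setequal(unique(design$nominal_uM), c(1, 2))
  ds <- generate_kinetics_dataset(default_ground_truth(), seed = 2)
  expect_equal(nrow(ds), (5 * 2 * 3 + 2 * 3) * 3)  # rows x compartments...
  ds_cf <- generate_kinetics_dataset(default_ground_truth(),
                                     with_cells = FALSE, seed = 2)
  expect_false(any(ds_cf$compartment == "cells"))
  expect_true(all(ds_cf$system == "cell_free"))
})

test_that("ground-truth kinetics reproduce the study's qualitative anchors", {
  a <- ground_truth_anchors()
  expect_gt(a$cell_fraction_24h, a$cell_fraction_1h)     # slow cell uptake
  expect_gt(a$plastic_fraction_1h, a$cell_fraction_1h)   # plastic is quicker
  expect_gt(a$recovery_24h, a$recovery_48h)              # slow abiotic loss
})

test_that("viability responds to the cell-associated Cmax", {
  truth <- default_ground_truth()
  scen <- standard_scenarios(1)
  via <- generate_viability_dataset(truth, c(0, 1, 50), scen, seed = 14)
  top <- truth$viability_truth$top
  ctrl <- via$percent_control[via$nominal_uM == 0]
  expect_lt(abs(mean(ctrl) - top), 5)
  high <- via$percent_control[via$nominal_uM == 50]
  expect_lt(abs(mean(high) - truth$viability_truth$bottom), 5)
  expect_true(all(via$percent_control >= -5 & via$percent_control <= 120))
  # 7 d and 7 dW share their cell-associated Cmax, so their viability is
  # generated from the same mean response
  mt <- dose_metric_table(truth$params, 1, scen)
  expect_equal(mt$cmax_cells_nmol_per_1e5[mt$scenario_label == "7 d"],
               mt$cmax_cells_nmol_per_1e5[mt$scenario_label == "7 dW"],
               tolerance = 1e-9)
})

test_that("noise-free re-expression recovers the true IC50 within 5%", {
  truth <- noise_free_truth()
  scen <- standard_scenarios(1)
  nom <- c(0, 0.625, 1.25, 1.9, 2.5, 3.75, 5, 10, 15)
  mt <- dose_metric_table(truth$params, nom, scen)
  via <- generate_viability_dataset(truth, nom, scen, seed = 5, metrics = mt)
  re <- reexpress_dose_response(via, mt, "cmax_cells")
  ic50_true <- 10^truth$viability_truth$log_ic50
  expect_true(all(abs(re$table$ic50 - ic50_true) / ic50_true < 0.05))
})

test_that("a mock study round-trips through the CSV readers", {
  dir <- tempfile("mock")
  write_mock_study(dir, seed = 3)
  wc <- read_kinetic_csv(file.path(dir, "kinetics_with_cells.csv"))
  cf <- read_kinetic_csv(file.path(dir, "kinetics_cell_free.csv"))
  via <- read_viability_csv(file.path(dir, "viability.csv"))
  expect_true(all(wc$system == "with_cells"))
  expect_true(all(cf$system == "cell_free"))
  expect_true(all(is.finite(via$percent_control)))
  unlink(dir, recursive = TRUE)
})
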