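scen <- standard_scenarios(1)

test_that("the objective is zero when predictions equal observations", {
  ds <- generate_kinetics_dataset(noise_free_truth(), seed = 1)
  obj <- kinetic_objective(default_ground_truth()$params, ds, scen)
  expect_lt(as.numeric(obj), 1e-18)
})

test_that("a single 2x misprediction scores exactly 1", {
  # pure degradation: prediction at t is known in closed form; observe half
  k <- 0.2
  pred <- 2 * exp(-k * 6)
  ds <- data.frame(system = "with_cells", scenario_label = "24 h",
                   nominal_uM = 1, compartment = "medium", time_h = 6,
                   replicate = 1, amount_nmol = pred / 2)
  obj <- kinetic_objective(rate_parameters(kdeg = k), ds, scen)
  expect_equal(as.numeric(obj), 1, tolerance = 1e-12)
})

test_that("the objective is invariant under uniform rescaling of the system", {
  # doubling the nominal dose doubles every prediction (linear kinetics);
  # doubling the observations too must leave relative residuals unchanged
  truth <- noise_free_truth()
  ds1 <- generate_kinetics_dataset(truth, seed = 1)
  ds1$amount_nmol <- ds1$amount_nmol * 1.17  # some systematic misfit
  ds2 <- ds1
  ds2$nominal_uM <- ds2$nominal_uM * 2
  ds2$amount_nmol <- ds2$amount_nmol * 2
  o1 <- kinetic_objective(truth$params, ds1, scen)
  o2 <- kinetic_objective(truth$params, ds2, scen)
  expect_equal(as.numeric(o1), as.numeric(o2), tolerance = 1e-12)
})

test_that("time points carry equal total weight in the objective", {
  # two time points, unbalanced replication: 4 observations at 1 h and 1 at
  # 24 h, all mispredicted by the same relative factor, must contribute
  # equally -> objective = 2 * rel_err^2
  k <- 0.1
  times <- c(1, 1, 1, 1, 24)
  pred <- 2 * exp(-k * times)
  ds <- data.frame(system = "with_cells", scenario_label = "24 h",
                   nominal_uM = 1, compartment = "medium", time_h = times,
                   replicate = seq_along(times), amount_nmol = pred / 1.5)
  obj <- kinetic_objective(rate_parameters(kdeg = k), ds, scen)
  expect_equal(as.numeric(obj), 2 * 0.5^2, tolerance = 1e-12)
})

test_that("observations below the quantification floor are excluded", {
  ds <- generate_kinetics_dataset(noise_free_truth(), seed = 1)
  ds$amount_nmol[1:3] <- 1e-5
  obj <- kinetic_objective(default_ground_truth()$params, ds, scen)
  expect_equal(attr(obj, "n_excluded"), 3L)
  ds$amount_nmol <- 1e-9
  expect_error(kinetic_objective(default_ground_truth()$params, ds, scen),
               "floor")
})

test_that("noise-free two-stage calibration recovers the truth within 1%", {
  truth <- noise_free_truth()
  cf <- generate_kinetics_dataset(truth, with_cells = FALSE, seed = 1)
  wc <- generate_kinetics_dataset(truth, with_cells = TRUE, seed = 2)
  fit <- fit_two_stage(cf, wc, scen, n_starts = 3, seed = 5)
  est <- coef(fit)
  rel <- abs(est - unclass(truth$params)) / unclass(truth$params)
  expect_true(all(rel < 0.01))
  # the objective at the truth cannot beat the fitted optimum
  obj_truth <- as.numeric(kinetic_objective(truth$params, wc, scen))
  expect_lte(fit$with_cells$objective_value, obj_truth + 1e-9)
})

test_that("identical data and seed give bitwise-identical fits", {
  truth <- default_ground_truth()
  ds <- generate_kinetics_dataset(truth, with_cells = FALSE, seed = 3)
  f1 <- fit_cell_free(ds, scen, n_starts = 3, seed = 11)
  f2 <- fit_cell_free(ds, scen, n_starts = 3, seed = 11)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$objective_value, f2$objective_value)
  expect_identical(f1$starts, f2$starts)
})

test_that("fold errors are 1 on perfect predictions and track mispredictions", {
  truth <- noise_free_truth()
  ds <- generate_kinetics_dataset(truth, seed = 4)
  cf <- generate_kinetics_dataset(truth, with_cells = FALSE, seed = 5)
  fit <- fit_two_stage(cf, ds, scen, n_starts = 2, seed = 1)
  fe <- predict_fold_errors(fit, ds)
  expect_equal(attr(fe, "max"), 1, tolerance = 1e-4)
  # one observation at a third of its prediction -> max fold error 3
  ds2 <- ds
  ds2$amount_nmol[10] <- fe$predicted_nmol[10] / 3
  fe2 <- predict_fold_errors(fit, ds2)
  expect_equal(attr(fe2, "max"), 3, tolerance = 1e-3)
})

test_that("stage preconditions and fixed-parameter validation hold", {
  truth <- default_ground_truth()
  wc <- generate_kinetics_dataset(truth, with_cells = TRUE, seed = 1)
  cf <- generate_kinetics_dataset(truth, with_cells = FALSE, seed = 2)
  expect_error(fit_cell_free(wc, scen), "cell-free")
  expect_error(fit_with_cells(cf, scen), "with-cells")
  expect_error(fit_kinetics(wc, scen, fixed = c(kdeg = -1)), ">= 0")
  expect_error(fit_kinetics(wc, scen, fixed = c(bogus = 1)), "named")
  all_fixed <- stats::setNames(rep(0, 5),
                               c("ka_cell", "kd_cell", "ka_plastic",
                                 "kd_plastic", "kdeg"))
  expect_error(fit_kinetics(wc, scen, fixed = all_fixed),
               "no free parameters")
})

test_that("prediction handles unknown scenario labels with a clear error", {
  ds <- generate_kinetics_dataset(default_ground_truth(), seed = 1)
  ds$scenario_label[1] <- "mystery"
  expect_error(kinetic_objective(toy_params(), ds, scen), "mystery")
})
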