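test_that("plate normalization is the blank-anchored linear rescale", {
  raw <- data.frame(
    scenario_label = "24 h",
    nominal_uM = c(0, 0, 0, 1, 2),
    replicate = c(1, 1, 2, 1, 1),
    fluorescence = c(100, 1100, 1100, 600, 1100),
    well_type = c("blank", "control", "control", "sample", "sample"))
  out <- normalize_viability(raw)
  expect_equal(out$percent_control, c(50, 100))
  raw2 <- raw
  raw2$fluorescence[4] <- 100  # at blank level -> 0%
  expect_equal(normalize_viability(raw2)$percent_control[1], 0)
})

test_that("uninterpretable plates are rejected", {
  raw <- data.frame(scenario_label = "24 h", nominal_uM = c(0, 0, 1),
                    replicate = 1, fluorescence = c(1000, 900, 500),
                    well_type = c("blank", "control", "sample"))
  expect_error(normalize_viability(raw), "uninterpretable")
  raw$well_type <- c("control", "control", "sample")
  expect_error(normalize_viability(raw), "blank")
})

test_that("an exact 4PL curve is recovered to 0.1%", {
  x <- c(0.625, 1.25, 1.9, 2.5, 3.75, 5, 10, 15)
  truth <- c(top = 98, bottom = 4, hill_slope = -3.2, log_ic50 = log10(2.2))
  y <- fourpl_curve(x, truth["top"], truth["bottom"], truth["hill_slope"],
                    truth["log_ic50"])
  fit <- fit_4pl(x, y)
  expect_false(fit$ambiguous)
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-3)
  expect_lt(fit$rss, 1e-12)
  # midpoint identity: the curve passes through (ic50, midpoint)
  expect_equal(predict(fit, fit$ic50), (98 + 4) / 2, tolerance = 1e-6)
})

test_that("a flat response yields an ambiguous fit without a CI", {
  x <- c(0.625, 1.25, 1.9, 2.5, 3.75, 5, 10, 15)
  y <- rep(100, length(x))
  fit <- fit_4pl(x, y)
  expect_true(fit$ambiguous)
  expect_null(fit$ci95)
  expect_error(compute_icx(fit, 50), "ambiguous")
})

test_that("fewer than four distinct doses are rejected", {
  expect_error(fit_4pl(c(1, 2, 4, 1, 2, 4), c(90, 50, 10, 91, 52, 9)),
               "at least 4 distinct")
})

test_that("ICx inversion matches the closed forms of the logistic", {
  x <- c(0.2, 0.5, 1, 2, 4, 8, 16, 32)
  y <- fourpl_curve(x, 100, 0, -1, log10(2))
  fit <- fit_4pl(x, y)
  icx <- compute_icx(fit, c(10, 50, 90))
  expect_equal(unname(icx["IC50"]), 2, tolerance = 1e-6)
  # unit slope magnitude: IC10 = IC50/9, IC90 = 9 IC50
  expect_equal(unname(icx["IC10"]), 2 / 9, tolerance = 1e-6)
  expect_equal(unname(icx["IC90"]), 2 * 9, tolerance = 1e-6)
  # symmetry on the log axis for any slope
  y2 <- fourpl_curve(x, 100, 0, -2.7, log10(3))
  fit2 <- fit_4pl(x, y2)
  icx2 <- compute_icx(fit2, c(10, 50, 90))
  expect_equal(log10(icx2[["IC50"]]) - log10(icx2[["IC10"]]),
               log10(icx2[["IC90"]]) - log10(icx2[["IC50"]]),
               tolerance = 1e-8)
  # absolute mode coincides with relative mode when top = 100, bottom = 0
  expect_equal(compute_icx(fit, 20, mode = "absolute"),
               compute_icx(fit, 20, mode = "relative"), tolerance = 1e-8)
  expect_error(compute_icx(fit, 120), "between 0 and 100")
})

test_that("fixing the top constrains the fitted curve", {
  x <- c(0.5, 1, 2, 4, 8, 16)
  y <- fourpl_curve(x, 100, 0, -2, log10(3)) + c(2, -2, 1, -1, 2, -2)
  fit <- fit_4pl(x, y, fixed = c(top = 100))
  expect_equal(coef(fit)[["top"]], 100)
})

test_that("re-expression on the nominal metric reproduces the plain fits", {
  truth <- default_ground_truth(noise_sd_viability = 0)
  scen <- standard_scenarios(1)
  nom <- c(0, 0.625, 1.25, 1.9, 2.5, 3.75, 5, 10, 15)
  mt <- dose_metric_table(truth$params, nom, scen)
  via <- generate_viability_dataset(truth, nom, scen, seed = 8)
  re <- reexpress_dose_response(via, mt, "nominal")
  d <- via[via$scenario_label == "24 h" & via$nominal_uM > 0, ]
  direct <- fit_4pl(d$nominal_uM, d$percent_control)
  expect_equal(re$fits[["24 h"]]$ic50, direct$ic50, tolerance = 1e-9)
  expect_equal(nrow(re$table), 4)
})

test_that("missing dose-metric pairs are reported by name", {
  truth <- default_ground_truth()
  scen <- standard_scenarios(1)
  mt <- dose_metric_table(truth$params, c(1, 2), scen)
  via <- generate_viability_dataset(truth, c(0, 1, 2, 5, 10), scen, seed = 3)
  expect_error(reexpress_dose_response(via, mt, "cmax_cells"), "24 h 5")
})

test_that("re-expression with a monotone metric preserves response ranking", {
  truth <- default_ground_truth(noise_sd_viability = 0)
  scen <- standard_scenarios(1)
  nom <- c(0, 0.625, 1.25, 2.5, 5, 10)
  mt <- dose_metric_table(truth$params, nom, scen)
  via <- generate_viability_dataset(truth, nom, scen, seed = 2)
  d <- via[via$scenario_label == "7 d" & via$nominal_uM > 0 &
             via$replicate == 1, ]
  x_nom <- d$nominal_uM
  x_met <- mt$auc_cells_nmolh[match(paste("7 d", d$nominal_uM),
                                    paste(mt$scenario_label, mt$nominal_uM))]
  expect_equal(order(x_nom), order(x_met))
  expect_equal(d$percent_control[order(x_nom)],
               d$percent_control[order(x_met)])
})
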