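# Default ground-truth rate constants (1/h).  Calibrated by least squares
# (scripts/calibrate_ground_truth.R) so that a 1 uM single dose reproduces
# the study's printed kinetic anchors: ~12% of the dosed mass in cells at
# 1 h and ~45% at 24 h, plastic binding faster than cell uptake, full
# recovery through 24 h dropping toward 85% by 48 h.
.default_truth_rates <- c(
  ka_cell = 0.1554622,
  kd_cell = 0.1337705,
  ka_plastic = 0.2823686,
  kd_plastic = 1.0000000,
  kdeg = 0.0057667
)

#' Ground truth for synthetic studies
#'
#' Bundles everything the synthetic-data generator needs: the "true" rate
#' constants of the well model, a true viability dose-response on the
#' cell-associated Cmax scale (the dose metric assumed to drive
#' cytotoxicity), noise levels, replication, and the destructive-sampling
#' design (times 1, 3, 6, 24, 48, 168 and 336 h; nominal 1-3 uM;
#' triplicates).
#'
#' Defaults: kinetic noise is multiplicative lognormal with 15% CV (typical
#' HPLC-UV replicate spread); viability noise is additive Gaussian with an
#' 8-percentage-point SD; the true viability curve is steep (hill slope -4)
#' with IC50 0.13 nmol per 100,000 cells, full top (100%) and zero bottom.
#'
#' @param params A [rate_parameters()] object (default: rates calibrated to
#'   the printed kinetic anchors, see `scripts/calibrate_ground_truth.R`).
#' @param viability_truth Named list with `top`, `bottom`, `hill_slope`,
#'   `log_ic50` on the cmax-cells scale.
#' @param noise_cv_kinetics CV of the lognormal kinetic noise.
#' @param noise_sd_viability SD of the Gaussian viability noise (% points).
#' @param replicates Kinetic replicates per design point (destructive
#'   triplicates in the emulated study).
#' @param viability_replicates Samples per (scenario, concentration)
#'   viability point; the emulated study pooled 3-9 samples from three
#'   independent experiments per point, so the default sits at 6.
#' @param sampling_times Sampling times in h.
#' @param nominal_set Nominal concentrations (uM) of the kinetic study.
#' @return An object of class `ground_truth`.
#' @examples
#' default_ground_truth()
#' @export
default_ground_truth <- function(params = do.call(rate_parameters,
                                                  as.list(.default_truth_rates)),
                                 viability_truth = list(top = 100, bottom = 0,
                                                        hill_slope = -4,
                                                        log_ic50 = log10(0.13)),
                                 noise_cv_kinetics = 0.15,
                                 noise_sd_viability = 8,
                                 replicates = 3,
                                 viability_replicates = 6,
                                 sampling_times = c(1, 3, 6, 24, 48, 168, 336),
                                 nominal_set = c(1, 2)) {
  stop_if_not(noise_cv_kinetics >= 0, "`noise_cv_kinetics` must be >= 0")
  stop_if_not(noise_sd_viability >= 0, "`noise_sd_viability` must be >= 0")
  stop_if_not(is_number(replicates) && replicates >= 1,
              "`replicates` must be >= 1")
  stop_if_not(is_number(viability_replicates) && viability_replicates >= 1,
              "`viability_replicates` must be >= 1")
  stop_if_not(!is.unsorted(sampling_times),
              "`sampling_times` must be sorted")
  structure(list(params = as_rate_parameters(params),
                 viability_truth = viability_truth,
                 noise_cv_kinetics = noise_cv_kinetics,
                 noise_sd_viability = noise_sd_viability,
                 replicates = replicates,
                 viability_replicates = viability_replicates,
                 sampling_times = sampling_times,
                 nominal_set = nominal_set),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic-study ground truth\n")
  print(x$params)
  vt <- x$viability_truth
  cat(sprintf("viability: top %g, bottom %g, hill %g, IC50 %.3g (cmax-cells scale)\n",
              vt$top, vt$bottom, vt$hill_slope, 10^vt$log_ic50))
  cat(sprintf("noise: kinetics CV %g (x%d), viability SD %g%% pts (x%d)\n",
              x$noise_cv_kinetics, x$replicates, x$noise_sd_viability,
              x$viability_replicates))
  invisible(x)
}

#' Kinetic anchors of a ground truth
#'
#' Summarizes the behaviour of the ground-truth kinetics for a 1 uM single
#' dose: the fraction of the dosed mass in cells at 1 h and 24 h, the
#' fraction on plastic at 1 h, and total recovery (medium + cells +
#' plastic, as fraction of the dose) at 24 h and 48 h.
#'
#' @param truth A [default_ground_truth()] object.
#' @param setup An [assay_setup()].
#' @return A named list of fractions.
#' @export
ground_truth_anchors <- function(truth = default_ground_truth(),
                                 setup = assay_setup()) {
  sc <- scenario_acute(1, 48, setup)
  tr <- solve_piecewise_exact(truth$params, sc, c(1, 24, 48), setup)
  dose <- attr(tr, "dosed_nmol")
  at <- function(t) tr[match(t, tr$time_h), ]
  r1 <- at(1); r24 <- at(24); r48 <- at(48)
  list(cell_fraction_1h = r1$cells_nmol / dose,
       cell_fraction_24h = r24$cells_nmol / dose,
       plastic_fraction_1h = r1$plastic_nmol / dose,
       recovery_24h = (r24$medium_nmol + r24$cells_nmol + r24$plastic_nmol) / dose,
       recovery_48h = (r48$medium_nmol + r48$cells_nmol + r48$plastic_nmol) / dose)
}

#' Default destructive-sampling design of the kinetic study
#'
#' One row per (scenario, nominal, time): acute exposure collected through
#' 48 h at every nominal concentration in the ground truth, plus the
#' repeated-dose/washout scenario at the lowest nominal concentration
#' collected at 168 h (7 d) and 336 h (7 dW).
#'
#' @param truth A [default_ground_truth()] object.
#' @return A data frame with columns `scenario_label`, `nominal_uM`,
#'   `time_h`.
#' @export
default_kinetics_design <- function(truth = default_ground_truth()) {
  early <- truth$sampling_times[truth$sampling_times <= 48]
  late <- truth$sampling_times[truth$sampling_times > 48]
  rows <- list()
  if (length(early))
    for (conc in truth$nominal_set)
      rows[[length(rows) + 1L]] <-
        data.frame(scenario_label = "48 h", nominal_uM = conc, time_h = early)
  if (length(late))
    rows[[length(rows) + 1L]] <-
      data.frame(scenario_label = "7 dW", nominal_uM = min(truth$nominal_set),
                 time_h = late)
  stop_if_not(length(rows) > 0, "no sampling times in the design")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic kinetic dataset
#'
#' Emulates the destructive-sampling HPLC study: for every (scenario,
#' nominal, time, compartment, replicate) combination the observed amount is
#' the model amount times an independent lognormal factor with unit mean and
#' CV `truth$noise_cv_kinetics` (each time point is an independent well, so
#' there is no within-well correlation).  Observations at a dosing-event
#' time take the pre-exchange value — a collected well never receives the
#' exchange scheduled at its collection time.
#'
#' @param truth A [default_ground_truth()] object.
#' @param design A design data frame ([default_kinetics_design()]).
#' @param with_cells If `FALSE`, generate the cell-free system (cell rates
#'   zeroed; compartments medium and plastic only).
#' @param seed Seed (required for reproducibility; RNG state is restored).
#' @param scenarios Named list of scenario templates.
#' @param setup An [assay_setup()].
#' @return A kinetic dataset (see [kinetic_objective()] for the schema).
#' @examples
#' ds <- generate_kinetics_dataset(default_ground_truth(), seed = 1)
#' head(ds)
#' @export
generate_kinetics_dataset <- function(truth = default_ground_truth(),
                                      design = default_kinetics_design(truth),
                                      with_cells = TRUE, seed,
                                      scenarios = standard_scenarios(1, setup),
                                      setup = assay_setup()) {
  stop_if_not(!missing(seed) && is_number(seed), "a numeric `seed` is required")
  stop_if_not(is.data.frame(design) && nrow(design) > 0,
              "`design` must be a non-empty data frame")
  comps <- if (with_cells) comp_levels else c("medium", "plastic")
  grid <- merge(merge(design, data.frame(compartment = comps)),
                data.frame(replicate = seq_len(truth$replicates)))
  skel <- data.frame(system = if (with_cells) "with_cells" else "cell_free",
                     scenario_label = grid$scenario_label,
                     nominal_uM = grid$nominal_uM,
                     compartment = grid$compartment,
                     time_h = grid$time_h,
                     replicate = grid$replicate,
                     amount_nmol = 1)
  ord <- order(skel$scenario_label, skel$nominal_uM, skel$time_h,
               skel$compartment, skel$replicate)
  skel <- skel[ord, , drop = FALSE]
  rownames(skel) <- NULL
  plan <- build_prediction_plan(skel, scenarios, setup, floor = 0)
  mu <- plan_predict(truth$params, plan)
  out <- plan$dataset
  out$amount_nmol <- with_seed(seed,
                               mu * rlnorm_cv(length(mu),
                                              truth$noise_cv_kinetics))
  out
}

#' Generate a synthetic viability dataset
#'
#' Embeds the working hypothesis that cytotoxicity is driven by the
#' cell-associated Cmax: for each (scenario, nominal, replicate) the
#' percent-of-control viability is the true 4PL response evaluated at
#' `cmax_cells(scenario, nominal)` plus Gaussian noise
#' (`truth$noise_sd_viability` percentage points), truncated to [-5, 120]%.
#' Two scenarios with equal cell-associated Cmax therefore receive
#' statistically indistinguishable viability.
#'
#' @param truth A [default_ground_truth()] object.
#' @param nominal_set Nominal concentrations (uM), 0 = vehicle control.
#' @param scenarios Named list of scenario templates (the four standard
#'   scenarios by default).
#' @param seed Seed (RNG state restored).
#' @param setup An [assay_setup()].
#' @param metrics Optional precomputed [dose_metric_table()] (saves
#'   re-simulation).
#' @return Viability records: `scenario_label`, `nominal_uM`, `replicate`,
#'   `percent_control`.
#' @export
generate_viability_dataset <- function(truth = default_ground_truth(),
                                       nominal_set = c(0, 0.625, 1.25, 1.9,
                                                       2.5, 3.75, 5, 10, 15),
                                       scenarios = standard_scenarios(1, setup),
                                       seed,
                                       setup = assay_setup(),
                                       metrics = NULL) {
  stop_if_not(!missing(seed) && is_number(seed), "a numeric `seed` is required")
  metrics <- metrics %||%
    dose_metric_table(truth$params, nominal_set, scenarios, setup)
  vt <- truth$viability_truth
  n_rep <- truth$viability_replicates %||% truth$replicates
  rows <- metrics[rep(seq_len(nrow(metrics)), each = n_rep), ]
  x <- rows$cmax_cells_nmol_per_1e5
  mu <- ifelse(x > 0,
               fourpl_curve(x, vt$top, vt$bottom, vt$hill_slope, vt$log_ic50),
               vt$top)
  pc <- with_seed(seed,
                  mu + stats::rnorm(length(mu), 0, truth$noise_sd_viability))
  out <- data.frame(scenario_label = rows$scenario_label,
                    nominal_uM = rows$nominal_uM,
                    replicate = rep(seq_len(n_rep), times = nrow(metrics)),
                    percent_control = pmin(pmax(pc, -5), 120))
  rownames(out) <- NULL
  out
}

#' Write a complete mock study to a directory
#'
#' Emits the CSV files the calibration and dose-response stages consume:
#' `kinetics_with_cells.csv`, `kinetics_cell_free.csv`, `viability.csv`.
#'
#' @param dir Output directory (created if needed).
#' @param truth A [default_ground_truth()] object.
#' @param seed Base seed; the three files use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @param setup An [assay_setup()].
#' @return The directory path, invisibly.
#' @export
write_mock_study <- function(dir, truth = default_ground_truth(), seed = 1,
                             setup = assay_setup()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scen <- standard_scenarios(1, setup)
  wc <- generate_kinetics_dataset(truth, with_cells = TRUE, seed = seed,
                                  scenarios = scen, setup = setup)
  cf <- generate_kinetics_dataset(truth, with_cells = FALSE, seed = seed + 1,
                                  scenarios = scen, setup = setup)
  via <- generate_viability_dataset(truth, seed = seed + 2,
                                    scenarios = scen, setup = setup)
  utils::write.csv(wc, file.path(dir, "kinetics_with_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(cf, file.path(dir, "kinetics_cell_free.csv"),
                   row.names = FALSE)
  utils::write.csv(via, file.path(dir, "viability.csv"), row.names = FALSE)
  invisible(dir)
}
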