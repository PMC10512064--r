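# ---- I/O helpers -----------------------------------------------------------

#' Read study CSV files
#'
#' Readers for the two CSV schemas the pipeline consumes, with row-level
#' schema validation: kinetic datasets (`system`, `scenario_label`,
#' `nominal_uM`, `compartment`, `time_h`, `replicate`, `amount_nmol`) and
#' viability records (`scenario_label`, `nominal_uM`, `replicate`,
#' `percent_control`).  Leading `#` comment lines (provenance headers) are
#' skipped.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_kinetic_csv <- function(path) {
  stop_if_not(file.exists(path), "file not found: %s", path)
  ds <- utils::read.csv(path, comment.char = "#")
  bad <- which(!(ds$system %in% c("with_cells", "cell_free")) |
                 !(ds$compartment %in% comp_levels) |
                 !is.finite(ds$amount_nmol) | ds$amount_nmol < 0 |
                 !is.finite(ds$time_h) | ds$time_h < 0)
  stop_if_not(length(bad) == 0,
              "%s: schema violations in row(s) %s", path,
              paste(utils::head(bad, 10), collapse = ", "))
  validate_kinetic_dataset(ds)
}

#' @rdname read_kinetic_csv
#' @export
read_viability_csv <- function(path) {
  stop_if_not(file.exists(path), "file not found: %s", path)
  ds <- utils::read.csv(path, comment.char = "#")
  need <- c("scenario_label", "nominal_uM", "replicate", "percent_control")
  stop_if_not(all(need %in% names(ds)),
              "%s: viability CSV needs columns: %s", path,
              paste(need, collapse = ", "))
  bad <- which(!is.finite(ds$percent_control) | !is.finite(ds$nominal_uM) |
                 ds$nominal_uM < 0)
  stop_if_not(length(bad) == 0,
              "%s: schema violations in row(s) %s", path,
              paste(utils::head(bad, 10), collapse = ", "))
  ds
}

write_output_csv <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# ---- configuration ---------------------------------------------------------

default_config <- function() {
  list(
    seed = 1,
    grid_resolution = 0.1,
    setup = list(medium_volume_mL = 2, cells_per_well = 2e6,
                 reporting_unit_cells = 1e5),
    params = as.list(.default_truth_rates),
    paths = list(output_dir = "kinetox-output",
                 kinetics_with_cells = NULL,
                 kinetics_cell_free = NULL,
                 viability = NULL),
    synthetic = list(noise_cv_kinetics = 0.15, noise_sd_viability = 8,
                     replicates = 3, viability_replicates = 6),
    fit = list(n_starts = 8, pin = "kdeg", floor = 1e-3,
               inclusion = list(max_time_h = NULL, nominal_uM = NULL,
                                scenario_labels = NULL)),
    dose_response = list(
      metrics = c("nominal", "cmax_medium", "cmax_cells",
                  "auc_medium", "auc_cells"),
      viability_nominal = c(0, 0.625, 1.25, 1.9, 2.5, 3.75, 5, 10, 15))
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read an analysis configuration
#'
#' Reads a YAML configuration file and merges it over the built-in defaults
#' (which mirror the standard study setup: 2 mL medium, 2e6 cells/well,
#' the standard exposure schedule, synthetic inputs).  Call with
#' `path = NULL` for the pure defaults.
#'
#' @param path YAML file path, or `NULL`.
#' @return A configuration list of class `kinetox_config`.
#' @export
read_analysis_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    stop_if_not(file.exists(path), "config file not found: %s", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  structure(cfg, class = "kinetox_config")
}

# Hash of everything that determines the numbers (the output location does
# not), so re-runs into different directories stay byte-identical.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$paths$output_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

config_setup <- function(config) do.call(assay_setup, config$setup)

config_inputs <- function(config, setup, scenarios) {
  p <- config$paths
  syn <- config$synthetic
  truth <- default_ground_truth(noise_cv_kinetics = syn$noise_cv_kinetics,
                                noise_sd_viability = syn$noise_sd_viability,
                                replicates = syn$replicates,
                                viability_replicates = syn$viability_replicates)
  list(
    with_cells = if (!is.null(p$kinetics_with_cells))
      read_kinetic_csv(p$kinetics_with_cells)
    else generate_kinetics_dataset(truth, with_cells = TRUE,
                                   seed = config$seed, scenarios = scenarios,
                                   setup = setup),
    cell_free = if (!is.null(p$kinetics_cell_free))
      read_kinetic_csv(p$kinetics_cell_free)
    else generate_kinetics_dataset(truth, with_cells = FALSE,
                                   seed = config$seed + 1,
                                   scenarios = scenarios, setup = setup),
    viability = if (!is.null(p$viability)) read_viability_csv(p$viability)
    else generate_viability_dataset(truth,
                                    nominal_set = config$dose_response$viability_nominal,
                                    scenarios = scenarios,
                                    seed = config$seed + 2, setup = setup),
    truth = truth
  )
}

# ---- full analysis ---------------------------------------------------------

#' Run the full kinetics-to-dose-response analysis
#'
#' Executes the complete workflow: cell-free calibration, with-cells
#' calibration, scenario simulation, dose-metric tabulation, and per-metric
#' dose-response re-expression, then writes `parameters.csv`,
#' `dose_metrics.csv`, `ic50_table.csv` and `run_log.txt` (seed, config
#' hash, fold-error summary) to the configured output directory.  Inputs
#' are the configured CSV files, or synthetic datasets generated under the
#' configured seed when no files are given.  All numeric outputs are fully
#' determined by the configuration and seed.
#'
#' @param config A `kinetox_config` from [read_analysis_config()], or a
#'   path to a YAML configuration file, or `NULL` for the defaults.
#' @param output_dir Optional override of the configured output directory.
#' @return An object of class `kinetox_analysis`: list with the fits, the
#'   dose-metric table, the re-expressions per metric, the IC50 table, and
#'   provenance (`seed`, `config_hash`, output paths).
#' @examples
#' \donttest{
#' res <- run_full_analysis(output_dir = tempfile())
#' res$ic50_table
#' }
#' @export
run_full_analysis <- function(config = NULL, output_dir = NULL) {
  if (is.character(config)) config <- read_analysis_config(config)
  config <- config %||% read_analysis_config(NULL)
  if (!is.null(output_dir)) config$paths$output_dir <- output_dir
  hash <- config_hash(config)
  prov <- sprintf("# kinetox %s | config %s | seed %d",
                  as.character(utils::packageVersion("kinetox")), hash,
                  as.integer(config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  setup <- stage("setup", config_setup(config))
  scenarios <- standard_scenarios(1, setup)
  inputs <- stage("inputs", config_inputs(config, setup, scenarios))
  inc <- config$fit$inclusion
  wc_fit_data <- stage("inclusion-filter",
                       filter_dataset(inputs$with_cells,
                                      max_time_h = inc$max_time_h,
                                      nominal_uM = inc$nominal_uM,
                                      scenario_labels = inc$scenario_labels))
  fit <- stage("calibration",
               fit_two_stage(inputs$cell_free, wc_fit_data, scenarios, setup,
                             pin = unlist(config$fit$pin),
                             n_starts = config$fit$n_starts,
                             seed = config$seed, floor = config$fit$floor))
  metrics <- stage("dose-metrics",
                   dose_metric_table(coef(fit),
                                     config$dose_response$viability_nominal,
                                     scenarios, setup,
                                     config$grid_resolution))
  reexp <- stage("dose-response", {
    out <- lapply(config$dose_response$metrics, function(m)
      reexpress_dose_response(inputs$viability, metrics, m))
    names(out) <- config$dose_response$metrics
    out
  })
  ic50_table <- do.call(rbind, lapply(reexp, `[[`, "table"))
  rownames(ic50_table) <- NULL

  dir <- config$paths$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  par_tab <- rbind(
    data.frame(stage = "cell_free", parameter = rate_names,
               value = unname(coef(fit$cell_free)[rate_names]),
               objective = fit$cell_free$objective_value,
               converged = fit$cell_free$converged),
    data.frame(stage = "with_cells", parameter = rate_names,
               value = unname(coef(fit$with_cells)[rate_names]),
               objective = fit$with_cells$objective_value,
               converged = fit$with_cells$converged))
  paths <- list(parameters = file.path(dir, "parameters.csv"),
                metrics = file.path(dir, "dose_metrics.csv"),
                ic50 = file.path(dir, "ic50_table.csv"),
                log = file.path(dir, "run_log.txt"))
  write_output_csv(par_tab, paths$parameters, prov)
  write_output_csv(metrics, paths$metrics, prov)
  write_output_csv(ic50_table, paths$ic50, prov)
  fe <- summary(fit$with_cells)
  writeLines(c(prov,
               sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               sprintf("seed: %d", as.integer(config$seed)),
               sprintf("config_hash: %s", hash),
               sprintf("cell-free objective: %.6g (converged: %s)",
                       fit$cell_free$objective_value,
                       fit$cell_free$converged),
               sprintf("with-cells objective: %.6g (converged: %s)",
                       fit$with_cells$objective_value,
                       fit$with_cells$converged),
               sprintf("training fold errors: median %.3f, max %.3f",
                       fe$fold_error_median, fe$fold_error_max)),
             paths$log)
  structure(list(config = config, config_hash = hash, seed = config$seed,
                 fit = fit, dose_metric_table = metrics,
                 reexpressions = reexp, ic50_table = ic50_table,
                 paths = paths),
            class = "kinetox_analysis")
}

#' @export
print.kinetox_analysis <- function(x, ...) {
  cat(sprintf("kinetox analysis (seed %d, config %s)\n", x$seed,
              substr(x$config_hash, 1, 8)))
  cat("calibrated rates (1/h):\n")
  print(signif(coef(x$fit), 4))
  cat("IC50 by dose metric and scenario:\n")
  tab <- x$ic50_table
  tab$ic50 <- signif(tab$ic50, 4)
  print(tab[, c("metric", "scenario_label", "ic50", "ambiguous")],
        row.names = FALSE)
  invisible(x)
}

#' Run one pipeline stage
#'
#' Wraps exactly one module's top operation with the shared configuration:
#' `"synth"` writes a mock study ([write_mock_study()]), `"simulate"`
#' writes trajectory CSVs for the standard scenarios at the configured
#' parameters, `"calibrate"` runs the two-stage fit and writes
#' `parameters.csv`, `"metrics"` writes the dose-metric table for the
#' configured parameters, and `"doseresponse"` re-expresses the viability
#' input on every configured metric.
#'
#' @param config As in [run_full_analysis()].
#' @param stage One of `"synth"`, `"simulate"`, `"calibrate"`, `"metrics"`,
#'   `"doseresponse"`.
#' @param output_dir Optional override of the configured output directory.
#' @return The stage result, invisibly (paths written are in the `paths`
#'   attribute or printed).
#' @export
run_stage <- function(config = NULL,
                      stage = c("synth", "simulate", "calibrate", "metrics",
                                "doseresponse"),
                      output_dir = NULL) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_analysis_config(config)
  config <- config %||% read_analysis_config(NULL)
  if (!is.null(output_dir)) config$paths$output_dir <- output_dir
  hash <- config_hash(config)
  prov <- sprintf("# kinetox %s | config %s | seed %d",
                  as.character(utils::packageVersion("kinetox")), hash,
                  as.integer(config$seed))
  setup <- config_setup(config)
  scenarios <- standard_scenarios(1, setup)
  dir <- config$paths$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- as_rate_parameters(unlist(config$params))
  switch(stage,
    synth = {
      syn <- config$synthetic
      truth <- default_ground_truth(
        noise_cv_kinetics = syn$noise_cv_kinetics,
        noise_sd_viability = syn$noise_sd_viability,
        replicates = syn$replicates,
        viability_replicates = syn$viability_replicates)
      invisible(write_mock_study(dir, truth, config$seed, setup))
    },
    simulate = {
      paths <- character(0)
      for (lab in names(scenarios)) {
        sc <- rescale_scenario(scenarios[[lab]],
                               config$dose_response$viability_nominal[
                                 which(config$dose_response$viability_nominal > 0)[1]],
                               setup)
        tr <- simulate_scenario(params, sc, setup, config$grid_resolution)
        f <- file.path(dir, sprintf("trajectory_%s.csv", gsub(" ", "", lab)))
        write_trajectory_csv(tr, f)
        paths <- c(paths, f)
      }
      invisible(paths)
    },
    calibrate = {
      inputs <- config_inputs(config, setup, scenarios)
      inc <- config$fit$inclusion
      wc <- filter_dataset(inputs$with_cells, max_time_h = inc$max_time_h,
                           nominal_uM = inc$nominal_uM,
                           scenario_labels = inc$scenario_labels)
      fit <- fit_two_stage(inputs$cell_free, wc, scenarios, setup,
                           pin = unlist(config$fit$pin),
                           n_starts = config$fit$n_starts,
                           seed = config$seed, floor = config$fit$floor)
      par_tab <- data.frame(stage = rep(c("cell_free", "with_cells"), each = 5),
                            parameter = rep(rate_names, 2),
                            value = c(unname(coef(fit$cell_free)[rate_names]),
                                      unname(coef(fit$with_cells)[rate_names])))
      write_output_csv(par_tab, file.path(dir, "parameters.csv"), prov)
      invisible(fit)
    },
    metrics = {
      m <- dose_metric_table(params, config$dose_response$viability_nominal,
                             scenarios, setup, config$grid_resolution)
      write_output_csv(m, file.path(dir, "dose_metrics.csv"), prov)
      invisible(m)
    },
    doseresponse = {
      inputs <- config_inputs(config, setup, scenarios)
      m <- dose_metric_table(params, config$dose_response$viability_nominal,
                             scenarios, setup, config$grid_resolution)
      out <- lapply(config$dose_response$metrics, function(mm)
        reexpress_dose_response(inputs$viability, m, mm))
      names(out) <- config$dose_response$metrics
      tab <- do.call(rbind, lapply(out, `[[`, "table"))
      rownames(tab) <- NULL
      write_output_csv(tab, file.path(dir, "ic50_table.csv"), prov)
      invisible(out)
    })
}
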