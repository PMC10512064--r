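#' Kinetics-derived dose metrics of a trajectory
#'
#' Computes the four dose metrics used to re-express dose-response curves:
#' peak medium concentration `cmax_medium_uM` (max medium amount divided by
#' medium volume; nmol/mL = uM), peak cell-associated amount
#' `cmax_cells_nmol_per_1e5` (max cell amount per reporting unit of 100,000
#' cells, with the cell number fixed at its value at seeding), and the areas
#' under the amount-time curves of medium and cells, `auc_medium_nmolh` and
#' `auc_cells_nmolh` (trapezoidal rule on the stored grid; the duplicated
#' pre/post rows at dosing events make the discontinuous medium series
#' integrate exactly across exchanges).
#'
#' @param traj A `trajectory` from [simulate_scenario()] or
#'   [solve_piecewise_exact()] (on a grid fine enough for quadrature).
#' @param setup The [assay_setup()] used for normalization; defaults to the
#'   setup stored with the trajectory.
#' @param window_end End of the evaluation window \[0, T\] in h; defaults to
#'   the trajectory end.  Must not exceed the trajectory end.
#' @return A one-row data frame with columns `window_end_h`,
#'   `cmax_medium_uM`, `cmax_cells_nmol_per_1e5`, `auc_medium_nmolh`,
#'   `auc_cells_nmolh`.
#' @examples
#' p <- rate_parameters(ka_cell = 0.05, kd_cell = 0.01,
#'                      ka_plastic = 0.5, kd_plastic = 0.3, kdeg = 0.004)
#' tr <- simulate_scenario(p, scenario_acute(1, 24))
#' dose_metrics(tr)
#' @export
dose_metrics <- function(traj, setup = NULL, window_end = NULL) {
  stop_if_not(inherits(traj, "trajectory"), "`traj` must be a trajectory")
  setup <- setup %||% attr(traj, "setup") %||% assay_setup()
  t_end <- max(traj$time_h)
  window_end <- window_end %||% t_end
  stop_if_not(is_number(window_end) && window_end > 0,
              "`window_end` must be a positive number")
  stop_if_not(window_end <= t_end,
              "`window_end` (%g h) lies beyond the trajectory end (%g h)",
              window_end, t_end)
  keep <- traj$time_h <= window_end
  tt <- traj$time_h[keep]
  med <- traj$medium_nmol[keep]
  cel <- traj$cells_nmol[keep]
  if (max(tt) < window_end) {
    # window ends between grid points: linear interpolation within segment
    i <- sum(keep)
    f <- (window_end - traj$time_h[i]) / (traj$time_h[i + 1] - traj$time_h[i])
    tt <- c(tt, window_end)
    med <- c(med, (1 - f) * traj$medium_nmol[i] + f * traj$medium_nmol[i + 1])
    cel <- c(cel, (1 - f) * traj$cells_nmol[i] + f * traj$cells_nmol[i + 1])
  }
  trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  per_unit <- setup$cells_per_well / setup$reporting_unit_cells
  data.frame(
    window_end_h = window_end,
    cmax_medium_uM = max(med) / setup$medium_volume_mL,
    cmax_cells_nmol_per_1e5 = max(cel) / per_unit,
    auc_medium_nmolh = trapz(tt, med),
    auc_cells_nmolh = trapz(tt, cel)
  )
}

#' Dose-metric table over scenarios and nominal concentrations
#'
#' Simulates every scenario at every nominal concentration and tabulates the
#' four dose metrics, one row per (scenario, nominal) pair.  This is the
#' x-axis source for [reexpress_dose_response()].
#'
#' @param params A [rate_parameters()] object (typically `coef()` of a
#'   [fit_kinetics()] result).
#' @param nominal_set Nominal concentrations (uM) to tabulate.
#' @param scenarios Named list of [exposure_scenario()]s (templates; each is
#'   rescaled to every nominal concentration, which is exact because the
#'   kinetics are linear).  Defaults to [standard_scenarios()].
#' @param setup An [assay_setup()].
#' @param grid_resolution Simulation grid spacing in h.
#' @param solver `"exact"` (piecewise matrix exponential, default) or
#'   `"numeric"` (lsoda); the two agree to solver tolerance.
#' @return A data frame with columns `scenario_label`, `nominal_uM`, the
#'   four metric columns of [dose_metrics()], and `nominal` (a copy of
#'   `nominal_uM`, so "nominal" can be addressed like any other metric).
#' @examples
#' p <- rate_parameters(ka_cell = 0.05, kd_cell = 0.01,
#'                      ka_plastic = 0.5, kd_plastic = 0.3, kdeg = 0.004)
#' dose_metric_table(p, nominal_set = c(1, 5))
#' @export
dose_metric_table <- function(params, nominal_set,
                              scenarios = standard_scenarios(1, setup),
                              setup = assay_setup(),
                              grid_resolution = 0.1,
                              solver = c("exact", "numeric")) {
  solver <- match.arg(solver)
  stop_if_not(is.numeric(nominal_set) && length(nominal_set) >= 1 &&
                all(nominal_set >= 0), "`nominal_set` must be non-negative")
  rows <- list()
  for (lab in names(scenarios)) {
    for (conc in nominal_set) {
      sc <- rescale_scenario(scenarios[[lab]], conc, setup)
      traj <- if (solver == "exact") {
        grid <- unique(sort(c(seq(0, sc$end_time_h, by = grid_resolution),
                              sc$end_time_h, sc$events$time_h)))
        solve_piecewise_exact(params, sc, grid, setup)
      } else {
        simulate_scenario(params, sc, setup, grid_resolution)
      }
      dm <- dose_metrics(traj, setup)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(scenario_label = lab, nominal_uM = conc), dm)
    }
  }
  out <- do.call(rbind, rows)
  out$nominal <- out$nominal_uM
  rownames(out) <- NULL
  out
}
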