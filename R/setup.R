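#' Assay setup: well geometry and cell numbers
#'
#' Describes the physical setup of one exposure well: the volume of exposure
#' medium, the number of cells seeded per well, and the cell count used as the
#' reporting unit when expressing cell-associated amounts "per 100,000 cells".
#' Defaults correspond to a six-well plate with 2 mL of medium and two million
#' cells per well.  The cell number is treated as constant over the exposure
#' (the number at seeding), including at cytotoxic doses; dose metrics
#' normalized per cell therefore carry that assumption.
#'
#' @param medium_volume_mL Volume of exposure medium per well, in mL.
#' @param cells_per_well Number of cells seeded per well.
#' @param reporting_unit_cells Cell count used as reporting unit for
#'   cell-associated dose metrics (fixed at 1e5 in the standard analysis).
#' @return An object of class `assay_setup`.
#' @examples
#' assay_setup()
#' @export
assay_setup <- function(medium_volume_mL = 2,
                        cells_per_well = 2e6,
                        reporting_unit_cells = 1e5) {
  stop_if_not(is_number(medium_volume_mL) && medium_volume_mL > 0,
              "`medium_volume_mL` must be a positive number")
  stop_if_not(is_number(cells_per_well) && cells_per_well > 0,
              "`cells_per_well` must be a positive number")
  stop_if_not(is_number(reporting_unit_cells) && reporting_unit_cells > 0,
              "`reporting_unit_cells` must be a positive number")
  structure(list(medium_volume_mL = medium_volume_mL,
                 cells_per_well = cells_per_well,
                 reporting_unit_cells = reporting_unit_cells),
            class = "assay_setup")
}

#' @export
print.assay_setup <- function(x, ...) {
  cat("Assay setup: ", x$medium_volume_mL, " mL medium, ",
      format(x$cells_per_well, big.mark = ","), " cells/well (reported per ",
      format(x$reporting_unit_cells, big.mark = ","), " cells)\n", sep = "")
  invisible(x)
}

#' First-order rate constants of the three-compartment well model
#'
#' The model tracks the amount of test chemical in three compartments of one
#' culture well: exposure medium, cells, and well-plate plastic.  All
#' transfers are first order in the source compartment's amount:
#' uptake into cells (`ka_cell`) and release back to medium (`kd_cell`),
#' sorption to plastic (`ka_plastic`) and desorption (`kd_plastic`), and an
#' irreversible abiotic degradation acting on the medium compartment only
#' (`kdeg`).  Units are 1/h throughout.
#'
#' @param ka_cell,kd_cell Cell uptake and efflux rate constants (1/h).
#' @param ka_plastic,kd_plastic Plastic sorption and desorption rate
#'   constants (1/h).
#' @param kdeg Abiotic degradation rate constant in the medium (1/h).
#' @return An object of class `rate_parameters` (a named numeric vector).
#' @examples
#' rate_parameters(ka_cell = 0.05, kd_cell = 0.01,
#'                 ka_plastic = 0.5, kd_plastic = 0.3, kdeg = 0.004)
#' @export
rate_parameters <- function(ka_cell = 0, kd_cell = 0,
                            ka_plastic = 0, kd_plastic = 0, kdeg = 0) {
  p <- c(ka_cell = ka_cell, kd_cell = kd_cell,
         ka_plastic = ka_plastic, kd_plastic = kd_plastic, kdeg = kdeg)
  stop_if_not(all(vapply(p, is_number, logical(1))) && all(p >= 0),
              "all rate constants must be finite, non-negative numbers")
  structure(p, class = "rate_parameters")
}

rate_names <- c("ka_cell", "kd_cell", "ka_plastic", "kd_plastic", "kdeg")

as_rate_parameters <- function(p) {
  if (inherits(p, "rate_parameters")) return(p)
  stop_if_not(is.numeric(p) && all(rate_names %in% names(p)),
              "rate parameters must be named with: %s",
              paste(rate_names, collapse = ", "))
  do.call(rate_parameters, as.list(p[rate_names]))
}

#' @export
print.rate_parameters <- function(x, digits = 4, ...) {
  cat("Rate constants (1/h):\n")
  print(signif(unclass(x), digits))
  invisible(x)
}

#' Exposure scenarios: dosing events, washouts, and collection horizon
#'
#' An exposure scenario is an ordered list of complete medium exchanges
#' ("dosing events") plus a collection horizon.  At each event the medium is
#' discarded in full and replaced by fresh medium containing
#' `medium_amount_after` nmol of chemical (0 nmol for a washout refresh);
#' amounts in cells and on plastic carry over unchanged.  The first event is
#' the initial dose at t = 0 with `nominal_uM * medium_volume_mL` nmol.
#'
#' `exposure_scenario()` builds an arbitrary scenario; `scenario_acute()`,
#' `scenario_repeated()` and `standard_scenarios()` build the standard study
#' designs: a single dose collected at 24 or 48 h; repeated dosing at 0, 48
#' and 120 h (three medium changes per week) collected at 168 h ("7 d"); and
#' the same repeated dosing followed by blank-medium washout refreshes at
#' 168, 216 and 288 h, collected at 336 h ("7 dW").
#'
#' @param nominal_uM Nominal concentration of the dosing medium, in uM.
#' @param event_times_h Times of medium exchanges (h); must start at 0,
#'   strictly increasing, all before `end_time_h`.
#' @param event_amounts_nmol Amount of chemical in the fresh medium at each
#'   event (nmol).  The first must equal `nominal_uM * medium_volume_mL`.
#' @param end_time_h Collection time (h).
#' @param label Scenario label, e.g. "24 h", "48 h", "7 d", "7 dW".
#' @param setup An [assay_setup()].
#' @return An object of class `exposure_scenario`.
#' @examples
#' standard_scenarios(nominal_uM = 1)
#' @export
exposure_scenario <- function(nominal_uM, event_times_h, event_amounts_nmol,
                              end_time_h, label = "custom",
                              setup = assay_setup()) {
  stop_if_not(is_number(nominal_uM) && nominal_uM >= 0,
              "`nominal_uM` must be a non-negative number")
  stop_if_not(is.numeric(event_times_h) && is.numeric(event_amounts_nmol) &&
                length(event_times_h) == length(event_amounts_nmol) &&
                length(event_times_h) >= 1,
              "event times and amounts must be numeric vectors of equal length")
  stop_if_not(event_times_h[1] == 0, "the first dosing event must be at t = 0")
  stop_if_not(!is.unsorted(event_times_h, strictly = TRUE),
              "dosing events must be sorted strictly increasing in time")
  stop_if_not(all(event_amounts_nmol >= 0), "event amounts must be >= 0")
  stop_if_not(is_number(end_time_h) && all(event_times_h < end_time_h),
              "all event times must lie before `end_time_h`")
  dose0 <- nominal_uM * setup$medium_volume_mL
  stop_if_not(isTRUE(all.equal(event_amounts_nmol[1], dose0)),
              "initial event amount must equal nominal_uM * medium volume (%g nmol)",
              dose0)
  structure(list(nominal_uM = nominal_uM,
                 events = data.frame(time_h = event_times_h,
                                     medium_amount_after = event_amounts_nmol),
                 end_time_h = end_time_h,
                 label = label),
            class = "exposure_scenario")
}

#' @rdname exposure_scenario
#' @export
scenario_acute <- function(nominal_uM, end_time_h = 24, setup = assay_setup()) {
  exposure_scenario(nominal_uM, 0, nominal_uM * setup$medium_volume_mL,
                    end_time_h,
                    label = if (end_time_h %in% c(24, 48))
                      paste(end_time_h, "h") else "custom",
                    setup = setup)
}

#' @rdname exposure_scenario
#' @param washout If `TRUE`, append blank-medium refreshes at 168, 216 and
#'   288 h and collect at 336 h ("7 dW"); otherwise collect at 168 h ("7 d").
#' @export
scenario_repeated <- function(nominal_uM, washout = FALSE,
                              setup = assay_setup()) {
  dose <- nominal_uM * setup$medium_volume_mL
  if (washout) {
    exposure_scenario(nominal_uM,
                      c(0, 48, 120, 168, 216, 288),
                      c(dose, dose, dose, 0, 0, 0),
                      end_time_h = 336, label = "7 dW", setup = setup)
  } else {
    exposure_scenario(nominal_uM, c(0, 48, 120), rep(dose, 3),
                      end_time_h = 168, label = "7 d", setup = setup)
  }
}

#' @rdname exposure_scenario
#' @export
standard_scenarios <- function(nominal_uM = 1, setup = assay_setup()) {
  list("24 h" = scenario_acute(nominal_uM, 24, setup),
       "48 h" = scenario_acute(nominal_uM, 48, setup),
       "7 d"  = scenario_repeated(nominal_uM, FALSE, setup),
       "7 dW" = scenario_repeated(nominal_uM, TRUE, setup))
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf("Exposure scenario '%s': %g uM nominal, collection at %g h\n",
              x$label, x$nominal_uM, x$end_time_h))
  cat(sprintf("  %d medium exchange(s) at t = %s h\n",
              nrow(x$events), paste(x$events$time_h, collapse = ", ")))
  invisible(x)
}

# Rebuild a scenario at a different nominal concentration (linear kinetics:
# dosing amounts scale with the nominal).
rescale_scenario <- function(scenario, nominal_uM, setup) {
  amounts <- scenario$events$medium_amount_after
  ref <- scenario$nominal_uM * setup$medium_volume_mL
  scale <- if (ref > 0) nominal_uM * setup$medium_volume_mL / ref else 0
  exposure_scenario(nominal_uM, scenario$events$time_h, amounts * scale,
                    scenario$end_time_h, scenario$label, setup)
}
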