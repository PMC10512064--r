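# ---- prediction plan -------------------------------------------------------
# A "plan" pre-resolves a kinetic dataset against scenario definitions so the
# objective can be evaluated many times cheaply inside the optimizer: one
# eigendecomposition per parameter set, one matrix-vector propagation per
# (system, scenario, nominal) group.

comp_levels <- c("medium", "cells", "plastic")

validate_kinetic_dataset <- function(dataset) {
  need <- c("system", "scenario_label", "nominal_uM", "compartment",
            "time_h", "replicate", "amount_nmol")
  stop_if_not(is.data.frame(dataset) && all(need %in% names(dataset)),
              "kinetic dataset needs columns: %s", paste(need, collapse = ", "))
  stop_if_not(all(dataset$system %in% c("with_cells", "cell_free")),
              "`system` must be 'with_cells' or 'cell_free'")
  stop_if_not(all(dataset$compartment %in% comp_levels),
              "`compartment` must be one of: %s",
              paste(comp_levels, collapse = ", "))
  bad <- dataset$system == "cell_free" & dataset$compartment == "cells"
  stop_if_not(!any(bad),
              "cell-free observations cannot have compartment = 'cells'")
  stop_if_not(all(is.finite(dataset$amount_nmol) & dataset$amount_nmol >= 0),
              "amounts must be finite and >= 0")
  invisible(dataset)
}

build_prediction_plan <- function(dataset, scenarios, setup = assay_setup(),
                                  floor = 1e-3) {
  validate_kinetic_dataset(dataset)
  included <- dataset$amount_nmol >= floor
  n_excluded <- sum(!included)
  stop_if_not(any(included),
              "all %d observations fall below the quantification floor (%g nmol)",
              nrow(dataset), floor)
  ds <- dataset[included, , drop = FALSE]
  # equal total weight per time point: w_i = 1 / n(t_i), n(t_i) counting all
  # included observations that share the time point (across nominal
  # concentrations, compartments, scenarios and replicates)
  n_t <- table(ds$time_h)
  w <- 1 / as.numeric(n_t[as.character(ds$time_h)])
  key <- interaction(ds$system, ds$scenario_label, ds$nominal_uM, drop = TRUE)
  groups <- lapply(split(seq_len(nrow(ds)), key), function(idx) {
    lab <- as.character(ds$scenario_label[idx[1]])
    stop_if_not(lab %in% names(scenarios),
                "no scenario definition for label '%s'", lab)
    sc <- rescale_scenario(scenarios[[lab]], ds$nominal_uM[idx[1]], setup)
    times <- sort(unique(ds$time_h[idx]))
    stop_if_not(all(times <= sc$end_time_h),
                "observations at t > end of scenario '%s'", lab)
    list(cell_free = ds$system[idx[1]] == "cell_free",
         events = sc$events, end = sc$end_time_h, times = times,
         obs_idx = idx,
         comp_idx = match(ds$compartment[idx], comp_levels),
         time_idx = match(ds$time_h[idx], times))
  })
  list(groups = groups, obs = ds$amount_nmol, weights = w,
       n_obs = nrow(ds), n_excluded = n_excluded, dataset = ds)
}

# Compartment states at observation times for one group.  Observations at an
# event time take the pre-exchange value: a destructively sampled well never
# receives the exchange scheduled at its collection time.
group_states <- function(prop, events, end, times) {
  out <- matrix(0, 4, length(times))
  state <- c(0, 0, 0, 0)
  nb <- nrow(events)
  for (j in seq_len(nb)) {
    t0 <- events$time_h[j]
    t1 <- if (j < nb) events$time_h[j + 1] else end
    state[1] <- events$medium_amount_after[j]
    if (j == 1L && any(times == t0)) out[, times == t0] <- state
    sel <- which(times > t0 & times <= t1)
    ts <- unique(c(times[sel], t1))
    st <- prop(state, ts - t0)
    if (length(sel)) out[, sel] <- st[, match(times[sel], ts), drop = FALSE]
    state <- st[, match(t1, ts)]
  }
  out
}

plan_predict <- function(params, plan) {
  params <- as_rate_parameters(params)
  props <- list()
  preds <- numeric(plan$n_obs)
  for (g in plan$groups) {
    key <- if (g$cell_free) "cf" else "wc"
    if (is.null(props[[key]])) {
      p <- params
      if (g$cell_free) {
        p[["ka_cell"]] <- 0
        p[["kd_cell"]] <- 0
      }
      props[[key]] <- make_propagator(p)
    }
    states <- group_states(props[[key]], g$events, g$end, g$times)
    preds[g$obs_idx] <- states[cbind(g$comp_idx, g$time_idx)]
  }
  preds
}

plan_objective <- function(params, plan) {
  preds <- plan_predict(params, plan)
  sum(plan$weights * ((preds - plan$obs) / plan$obs)^2)
}

#' Time-point-balanced relative-error objective
#'
#' The calibration objective: squared errors between predicted and observed
#' compartment amounts, normalized to the observed value (relative residuals)
#' and to the time point.  Each observation `i` contributes
#' `w_i * ((pred_i - obs_i) / obs_i)^2` with `w_i = 1 / n(t_i)`, where
#' `n(t_i)` is the number of included observations sharing the time point
#' `t_i`, so every time point carries equal total weight regardless of how
#' many concentrations, compartments and replicates were sampled there.
#' Observations below the quantification floor are excluded (relative error
#' is unstable near zero).
#'
#' @param params A [rate_parameters()] object (or named numeric).
#' @param dataset A kinetic dataset: data frame with columns `system`
#'   (`"with_cells"`/`"cell_free"`), `scenario_label`, `nominal_uM`,
#'   `compartment` (`"medium"`/`"cells"`/`"plastic"`), `time_h`, `replicate`,
#'   `amount_nmol`.  Cell-free rows may not carry compartment `"cells"`;
#'   cell-free predictions use the same parameters with cell rates zeroed.
#' @param scenarios Named list of [exposure_scenario()] templates keyed by
#'   `scenario_label` (rescaled per observation's nominal concentration).
#' @param setup An [assay_setup()].
#' @param floor Quantification floor in nmol (default 1e-3); observations
#'   below it are excluded.
#' @return The objective value (unitless, >= 0), with attribute
#'   `n_excluded`.
#' @examples
#' truth <- default_ground_truth()
#' ds <- generate_kinetics_dataset(truth, seed = 1)
#' kinetic_objective(truth$params, ds, standard_scenarios(1))
#' @export
kinetic_objective <- function(params, dataset, scenarios,
                              setup = assay_setup(), floor = 1e-3) {
  plan <- build_prediction_plan(dataset, scenarios, setup, floor)
  structure(plan_objective(as_rate_parameters(params), plan),
            n_excluded = plan$n_excluded)
}

# ---- fitting ---------------------------------------------------------------

#' Fit rate constants to compartment measurements
#'
#' Estimates the well model's rate constants by minimizing
#' [kinetic_objective()] with BFGS (`stats::optim`) on log-transformed
#' parameters (so positivity holds without constraints), from multiple
#' starting points drawn log-uniformly under a fixed seed.
#'
#' `fit_cell_free()` fits the two-compartment reduction (medium/plastic;
#' `ka_plastic`, `kd_plastic`, `kdeg` free, cell rates pinned at 0) to
#' cell-free data; `fit_with_cells()` fits the full system to with-cells
#' data, optionally pinning parameters estimated in the cell-free stage
#' (by default the degradation rate constant, which is the same with and
#' without cells).  [fit_two_stage()] chains the two.
#'
#' @param dataset A kinetic dataset (see [kinetic_objective()]).
#' @param scenarios Named list of [exposure_scenario()] templates.
#' @param setup An [assay_setup()].
#' @param fixed Named numeric of rate constants to hold fixed (must be
#'   >= 0); the remaining ones are free.
#' @param n_starts Number of multi-start optimizations (default 8).
#' @param seed Seed for drawing starting points.
#' @param start_range Range (1/h) from which starts are drawn log-uniformly.
#' @param floor Quantification floor in nmol.
#' @param control Passed to [stats::optim()].
#' @return An object of class `kinetic_fit` with methods `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `fitted` and `simulate`.  Components
#'   include `params` (all five rate constants, fixed ones merged in),
#'   `objective_value`, `converged`, `n_starts`, `starts` (per-start
#'   results), and `residual_table` (per-observation predictions, normalized
#'   residuals and fold errors).
#' @examples
#' truth <- default_ground_truth()
#' ds <- generate_kinetics_dataset(truth, with_cells = FALSE, seed = 1)
#' fit <- fit_cell_free(ds, standard_scenarios(1), n_starts = 2)
#' coef(fit)
#' @export
fit_kinetics <- function(dataset, scenarios, setup = assay_setup(),
                         fixed = NULL, n_starts = 8, seed = 1,
                         start_range = c(1e-4, 1), floor = 1e-3,
                         control = list(maxit = 500, reltol = 1e-12)) {
  if (!is.null(fixed)) {
    stop_if_not(is.numeric(fixed) && all(names(fixed) %in% rate_names),
                "`fixed` must be a named numeric of rate constants")
    stop_if_not(all(is.finite(fixed) & fixed >= 0),
                "fixed parameters must be finite and >= 0")
  }
  free <- setdiff(rate_names, names(fixed))
  stop_if_not(length(free) >= 1, "no free parameters left to fit")
  stop_if_not(is_number(n_starts) && n_starts >= 1,
              "`n_starts` must be >= 1")
  plan <- build_prediction_plan(dataset, scenarios, setup, floor)
  base <- stats::setNames(numeric(5), rate_names)
  base[names(fixed)] <- fixed
  fn <- function(lp) {
    p <- base
    p[free] <- exp(lp)
    val <- tryCatch(plan_objective(p, plan), error = function(e) Inf)
    if (!is.finite(val)) 1e10 else val
  }
  starts <- with_seed(seed, matrix(
    stats::runif(n_starts * length(free),
                 log(start_range[1]), log(start_range[2])),
    nrow = n_starts))
  runs <- lapply(seq_len(n_starts), function(i) {
    tryCatch({
      # derivative-free pre-stage pulls the start off the flat
      # "predict-nothing" plateau before the quasi-Newton polish
      pre <- if (length(free) > 1)
        stats::optim(starts[i, ], fn, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-10))$par
      else starts[i, ]
      stats::optim(pre, fn, method = "BFGS", control = control)
    }, error = function(e) list(par = starts[i, ], value = fn(starts[i, ]),
                                convergence = 99L))
  })
  values <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(values)]]
  params <- base
  params[free] <- exp(best$par)
  params <- as_rate_parameters(params)
  preds <- plan_predict(params, plan)
  ds <- plan$dataset
  residual_table <- cbind(
    ds[, c("system", "scenario_label", "nominal_uM", "compartment",
           "time_h", "replicate")],
    data.frame(observed_nmol = plan$obs, predicted_nmol = preds,
               weight = plan$weights,
               norm_residual = (preds - plan$obs) / plan$obs,
               fold_error = pmax(preds / plan$obs, plan$obs / preds))
  )
  structure(list(
    params = params, free = free,
    fixed = if (is.null(fixed)) stats::setNames(numeric(0), character(0)) else fixed,
    objective_value = best$value,
    converged = identical(best$convergence, 0L),
    n_starts = n_starts, seed = seed,
    starts = data.frame(start = seq_len(n_starts),
                        objective = values,
                        convergence = vapply(runs, `[[`, numeric(1),
                                             "convergence")),
    residual_table = residual_table,
    n_excluded = plan$n_excluded,
    floor = floor,
    scenarios = scenarios, setup = setup,
    dataset = dataset,
    call = match.call()
  ), class = "kinetic_fit")
}

#' @rdname fit_kinetics
#' @export
fit_cell_free <- function(dataset, scenarios, setup = assay_setup(), ...) {
  stop_if_not(all(dataset$system == "cell_free"),
              "`fit_cell_free()` expects a dataset of cell-free observations only")
  fit_kinetics(dataset, scenarios, setup,
               fixed = c(ka_cell = 0, kd_cell = 0), ...)
}

#' @rdname fit_kinetics
#' @export
fit_with_cells <- function(dataset, scenarios, setup = assay_setup(),
                           fixed = NULL, ...) {
  stop_if_not(all(dataset$system == "with_cells"),
              "`fit_with_cells()` expects a dataset of with-cells observations only")
  fit_kinetics(dataset, scenarios, setup, fixed = fixed, ...)
}

#' Two-stage calibration: cell-free system first
#'
#' Stage 1 fits `ka_plastic`, `kd_plastic` and `kdeg` to the cell-free
#' dataset; stage 2 fits the with-cells dataset with `kdeg` pinned at the
#' stage-1 estimate (the degradation process is abiotic, so the same rate
#' applies with and without cells) and the plastic rates re-fit.  Set
#' `pin = c("kdeg", "ka_plastic", "kd_plastic")` to carry the plastic rates
#' over as well, or `pin = character(0)` for a joint re-fit of everything.
#'
#' @param cell_free_data,with_cells_data Kinetic datasets for the two
#'   systems.
#' @param scenarios Named list of [exposure_scenario()] templates.
#' @param setup An [assay_setup()].
#' @param pin Which stage-1 estimates to hold fixed in stage 2.
#' @param ... Passed to [fit_kinetics()] (e.g. `n_starts`, `seed`).
#' @return A list of class `two_stage_fit` with components `cell_free` and
#'   `with_cells` (both `kinetic_fit`); `coef()` returns the final
#'   parameters.
#' @export
fit_two_stage <- function(cell_free_data, with_cells_data, scenarios,
                          setup = assay_setup(), pin = "kdeg", ...) {
  stop_if_not(all(pin %in% c("kdeg", "ka_plastic", "kd_plastic")),
              "`pin` may only name cell-free-stage parameters")
  stage1 <- fit_cell_free(cell_free_data, scenarios, setup, ...)
  fixed <- unclass(stage1$params)[pin]
  stage2 <- fit_with_cells(with_cells_data, scenarios, setup,
                           fixed = if (length(fixed)) fixed else NULL, ...)
  structure(list(cell_free = stage1, with_cells = stage2),
            class = "two_stage_fit")
}

#' @export
coef.two_stage_fit <- function(object, ...) coef(object$with_cells)

#' @export
print.two_stage_fit <- function(x, ...) {
  cat("Two-stage kinetic calibration\n-- Stage 1 (cell-free):\n")
  print(x$cell_free)
  cat("-- Stage 2 (with cells):\n")
  print(x$with_cells)
  invisible(x)
}

# ---- kinetic_fit methods ---------------------------------------------------

#' @export
coef.kinetic_fit <- function(object, ...) unclass(object$params)

#' @export
print.kinetic_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Kinetic fit (%d free parameter%s, %d start%s)%s\n",
              length(x$free), if (length(x$free) > 1) "s" else "",
              x$n_starts, if (x$n_starts > 1) "s" else "",
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(signif(unclass(x$params), digits))
  if (length(x$fixed))
    cat("fixed:", paste(names(x$fixed), signif(x$fixed, digits),
                        sep = " = ", collapse = ", "), "\n")
  cat(sprintf("objective: %.6g on %d observations (%d below floor)\n",
              x$objective_value, nrow(x$residual_table), x$n_excluded))
  invisible(x)
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  fe <- object$residual_table$fold_error
  structure(list(fit = object,
                 fold_error_median = stats::median(fe),
                 fold_error_max = max(fe),
                 resid_quartiles = stats::quantile(
                   object$residual_table$norm_residual,
                   c(0.25, 0.5, 0.75))),
            class = "summary.kinetic_fit")
}

#' @export
print.summary.kinetic_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("fold errors: median %.3f, max %.3f\n",
              x$fold_error_median, x$fold_error_max))
  cat("normalized residual quartiles:\n")
  print(signif(x$resid_quartiles, 3))
  cat("per-start objectives:\n")
  print(x$fit$starts)
  invisible(x)
}

#' @export
residuals.kinetic_fit <- function(object, ...) {
  object$residual_table$norm_residual
}

#' @export
fitted.kinetic_fit <- function(object, ...) {
  object$residual_table$predicted_nmol
}

#' Predict compartment amounts at new observations
#'
#' @param object A `kinetic_fit`.
#' @param newdata A kinetic dataset (defaults to the training data); the
#'   `amount_nmol` column is ignored for prediction but must be present.
#' @param ... Unused.
#' @return `newdata` with a `predicted_nmol` column appended.
#' @export
predict.kinetic_fit <- function(object, newdata = NULL, ...) {
  newdata <- newdata %||% object$dataset
  # floor = 0: predict at every observation, including sub-floor ones
  plan <- build_prediction_plan(newdata, object$scenarios, object$setup,
                                floor = 0)
  out <- plan$dataset
  out$predicted_nmol <- plan_predict(object$params, plan)
  out
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws new destructive-sampling datasets at the fit's training design from
#' the fitted rate constants, with multiplicative lognormal noise.
#'
#' @param object A `kinetic_fit`.
#' @param nsim Number of datasets.
#' @param seed Seed (RNG state is restored afterwards).
#' @param noise_cv Coefficient of variation of the lognormal noise.
#' @param ... Unused.
#' @return A list of `nsim` kinetic datasets.
#' @export
simulate.kinetic_fit <- function(object, nsim = 1, seed = NULL,
                                 noise_cv = 0.15, ...) {
  plan <- build_prediction_plan(object$dataset, object$scenarios,
                                object$setup, floor = 0)
  mu <- plan_predict(object$params, plan)
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    out <- plan$dataset
    out$amount_nmol <- mu * rlnorm_cv(length(mu), noise_cv)
    out
  }))
}

#' Fold errors of model predictions on held-out observations
#'
#' For each held-out observation computes `max(pred/obs, obs/pred)`, the
#' symmetric fold error used to judge predictive accuracy of the calibrated
#' model (e.g. "predictions within 2.5-fold of measurements").
#'
#' @param fit A `kinetic_fit` (or `two_stage_fit`).
#' @param holdout A kinetic dataset of held-out observations.
#' @param floor Quantification floor in nmol; observations below it are
#'   excluded.
#' @return A data frame (one row per included observation) with a
#'   `fold_error` column and attributes `median` and `max`.
#' @export
predict_fold_errors <- function(fit, holdout, floor = 1e-3) {
  if (inherits(fit, "two_stage_fit")) fit <- fit$with_cells
  stop_if_not(inherits(fit, "kinetic_fit"), "`fit` must be a kinetic_fit")
  plan <- build_prediction_plan(holdout, fit$scenarios, fit$setup, floor)
  preds <- plan_predict(fit$params, plan)
  out <- plan$dataset
  out$predicted_nmol <- preds
  out$fold_error <- pmax(preds / out$amount_nmol, out$amount_nmol / preds)
  structure(out, median = stats::median(out$fold_error),
            max = max(out$fold_error))
}

#' Subset a kinetic dataset by design factors
#'
#' Convenience inclusion filter used to restrict calibration to, e.g., the
#' first 24 h of the 1 uM data, or to non-cytotoxic concentrations.
#'
#' @param dataset A kinetic dataset.
#' @param max_time_h,nominal_uM,scenario_labels,compartments Optional
#'   restrictions; `NULL` keeps everything.
#' @return The filtered dataset.
#' @export
filter_dataset <- function(dataset, max_time_h = NULL, nominal_uM = NULL,
                           scenario_labels = NULL, compartments = NULL) {
  keep <- rep(TRUE, nrow(dataset))
  if (!is.null(max_time_h)) keep <- keep & dataset$time_h <= max_time_h
  if (!is.null(nominal_uM)) keep <- keep & dataset$nominal_uM %in% nominal_uM
  if (!is.null(scenario_labels))
    keep <- keep & dataset$scenario_label %in% scenario_labels
  if (!is.null(compartments))
    keep <- keep & dataset$compartment %in% compartments
  dataset[keep, , drop = FALSE]
}
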