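#' Normalize raw viability plates to percent-of-control
#'
#' Resazurin plate normalization: after subtracting the mean blank
#' (resazurin solution only), fluorescence is expressed as percent of the
#' mean vehicle-control wells, per scenario:
#' `percent_control = 100 * (raw - mean(blank)) / (mean(control) - mean(blank))`.
#'
#' @param raw A data frame with columns `scenario_label`, `nominal_uM`,
#'   `replicate`, `fluorescence`, and `well_type` (`"blank"`, `"control"`,
#'   or `"sample"`).  Each scenario needs at least one blank and one control
#'   well.
#' @return A data frame of viability records: `scenario_label`,
#'   `nominal_uM`, `replicate`, `percent_control`.
#' @examples
#' raw <- data.frame(scenario_label = "24 h", nominal_uM = c(0, 0, 1),
#'                   replicate = 1, fluorescence = c(100, 1100, 600),
#'                   well_type = c("blank", "control", "sample"))
#' normalize_viability(raw)
#' @export
normalize_viability <- function(raw) {
  need <- c("scenario_label", "nominal_uM", "replicate", "fluorescence",
            "well_type")
  stop_if_not(is.data.frame(raw) && all(need %in% names(raw)),
              "raw plate table needs columns: %s", paste(need, collapse = ", "))
  stop_if_not(all(raw$well_type %in% c("blank", "control", "sample")),
              "`well_type` must be 'blank', 'control' or 'sample'")
  out <- lapply(split(raw, raw$scenario_label), function(plate) {
    lab <- plate$scenario_label[1]
    blank <- plate$fluorescence[plate$well_type == "blank"]
    ctrl <- plate$fluorescence[plate$well_type == "control"]
    stop_if_not(length(blank) >= 1 && length(ctrl) >= 1,
                "scenario '%s' needs at least one blank and one control well",
                lab)
    b <- mean(blank)
    c0 <- mean(ctrl)
    stop_if_not(c0 > b,
                "scenario '%s': control signal (%.3g) not above blank (%.3g); plate uninterpretable",
                lab, c0, b)
    smp <- plate[plate$well_type == "sample", , drop = FALSE]
    data.frame(scenario_label = smp$scenario_label,
               nominal_uM = smp$nominal_uM,
               replicate = smp$replicate,
               percent_control = 100 * (smp$fluorescence - b) / (c0 - b))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

fourpl_curve <- function(x, top, bottom, hill_slope, log_ic50) {
  bottom + (top - bottom) / (1 + 10^((log_ic50 - log10(x)) * hill_slope))
}

#' Four-parameter logistic ("variable slope") dose-response fit
#'
#' Least-squares fit of the GraphPad-style four-parameter logistic
#' \deqn{y = bottom + \frac{top - bottom}{1 + 10^{(\log IC_{50} - \log_{10} x)\, h}}}
#' with parameters `top`, `bottom`, `hill_slope` (`h`; signed — decreasing
#' viability curves carry a negative slope) and `log_ic50`.  Doses enter on
#' the log10 scale; non-positive doses (vehicle controls) are dropped before
#' fitting, as in the cited plate-reader procedure.
#'
#' A 95% confidence interval for the IC50 is derived from the asymptotic
#' standard error of `log_ic50`.  The fit is flagged *ambiguous* — and the
#' CI reported as unavailable — when the parameter covariance is singular or
#' ill-conditioned (condition number > 1e8), when the `log_ic50` standard
#' error spans more than the tested dose range, when `log_ic50` falls
#' outside the tested range, or when no fit converges (e.g. a flat
#' response).
#'
#' @param x Dose-metric values (any metric scale; must contain at least 4
#'   distinct positive values).
#' @param y Responses in percent of control.
#' @param fixed Optional named numeric fixing `top` and/or `bottom` (e.g.
#'   `c(top = 100)`); unfixed parameters are estimated.
#' @param dose_metric Label of the x-axis metric, carried in the result.
#' @return An object of class `fourpl` with methods `print`, `summary`,
#'   `coef`, `predict` and `plot`.  Components: `coefficients` (top,
#'   bottom, hill_slope, log_ic50), `ic50`, `ci95` (length-2 numeric or
#'   `NULL` when unavailable), `ambiguous`, `converged`, `rss`, `data`.
#' @examples
#' x <- c(0.625, 1.25, 1.9, 2.5, 3.75, 5, 10, 15)
#' y <- fourpl_curve(x, 100, 0, -3, log10(2.5))
#' fit <- fit_4pl(x, y)
#' coef(fit)
#' @export
fit_4pl <- function(x, y, fixed = NULL, dose_metric = "dose") {
  stop_if_not(is.numeric(x) && is.numeric(y) && length(x) == length(y),
              "`x` and `y` must be numeric vectors of equal length")
  keep <- is.finite(x) & is.finite(y) & x > 0
  if (sum(!keep) > 0 && any(x <= 0, na.rm = TRUE))
    message(sum(x <= 0, na.rm = TRUE),
            " non-positive dose(s) dropped before 4PL fitting")
  x <- x[keep]
  y <- y[keep]
  stop_if_not(length(unique(x)) >= 4,
              "need at least 4 distinct positive doses, got %d",
              length(unique(x)))
  if (!is.null(fixed))
    stop_if_not(all(names(fixed) %in% c("top", "bottom")),
                "`fixed` may only name 'top' and/or 'bottom'")
  lx <- log10(x)
  rng <- range(lx)
  dat <- c(list(y = y, lx = lx), as.list(fixed))
  free <- setdiff(c("top", "bottom", "hill_slope", "log_ic50"), names(fixed))
  start0 <- list(top = max(y), bottom = min(y),
                 hill_slope = NA, log_ic50 = stats::median(lx))
  fml <- y ~ bottom + (top - bottom) / (1 + 10^((log_ic50 - lx) * hill_slope))
  best <- NULL
  for (h0 in c(-1, -4, 1, 4)) {
    start0$hill_slope <- h0
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = dat, start = start0[free],
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  cf <- c(top = unname(fixed["top"]), bottom = unname(fixed["bottom"]),
          hill_slope = NA_real_, log_ic50 = NA_real_)
  if (is.null(best)) {
    cf["top"] <- if ("top" %in% names(fixed)) fixed[["top"]] else max(y)
    cf["bottom"] <- if ("bottom" %in% names(fixed)) fixed[["bottom"]] else min(y)
    out <- list(coefficients = cf[c("top", "bottom", "hill_slope", "log_ic50")],
                ic50 = NA_real_, ci95 = NULL, se_log_ic50 = NA_real_,
                ambiguous = TRUE, converged = FALSE, rss = NA_real_,
                dose_metric = dose_metric, data = data.frame(x = x, y = y))
    return(structure(out, class = "fourpl"))
  }
  est <- stats::coef(best$fit)
  for (nm in free) cf[nm] <- est[[nm]]
  for (nm in names(fixed)) cf[nm] <- fixed[[nm]]
  cf <- cf[c("top", "bottom", "hill_slope", "log_ic50")]
  sm <- summary(best$fit)
  cov_unscaled <- sm$cov.unscaled
  kap <- tryCatch(kappa(cov_unscaled, exact = TRUE),
                  error = function(e) Inf)
  se <- sm$sigma * sqrt(diag(cov_unscaled))["log_ic50"]
  ambiguous <- !is.finite(kap) || kap > 1e8 ||
    !is.finite(se) || se > diff(rng) ||
    cf[["log_ic50"]] < rng[1] || cf[["log_ic50"]] > rng[2]
  ci95 <- NULL
  if (!ambiguous) {
    tq <- stats::qt(0.975, df = length(y) - length(free))
    ci95 <- 10^(cf[["log_ic50"]] + c(-1, 1) * tq * se)
  }
  structure(list(coefficients = cf,
                 ic50 = 10^cf[["log_ic50"]],
                 ci95 = ci95, se_log_ic50 = unname(se),
                 ambiguous = ambiguous, converged = TRUE, rss = best$rss,
                 dose_metric = dose_metric,
                 data = data.frame(x = x, y = y)),
            class = "fourpl")
}

#' @export
coef.fourpl <- function(object, ...) object$coefficients

#' @export
print.fourpl <- function(x, digits = 4, ...) {
  cat(sprintf("4PL fit on '%s'%s\n", x$dose_metric,
              if (x$ambiguous) "  [ambiguous]" else ""))
  print(signif(x$coefficients, digits))
  if (is.finite(x$ic50)) {
    cat(sprintf("IC50 = %.4g", x$ic50))
    if (!is.null(x$ci95))
      cat(sprintf(" (95%% CI %.4g-%.4g)", x$ci95[1], x$ci95[2]))
    else cat(" (95% CI cannot be calculated: ambiguous curve fit)")
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.fourpl <- function(object, ...) object

#' @export
predict.fourpl <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
  else if (is.data.frame(newdata)) newdata$x else newdata
  cf <- object$coefficients
  fourpl_curve(x, cf[["top"]], cf[["bottom"]], cf[["hill_slope"]],
               cf[["log_ic50"]])
}

#' @export
plot.fourpl <- function(x, n_grid = 200, ...) {
  d <- x$data
  graphics::plot(d$x, d$y, log = "x", xlab = x$dose_metric,
                 ylab = "% of control", ...)
  if (!x$ambiguous) {
    xs <- 10^seq(log10(min(d$x)), log10(max(d$x)), length.out = n_grid)
    graphics::lines(xs, predict(x, xs), col = "red", lwd = 2)
    graphics::abline(v = x$ic50, lty = 2, col = "grey40")
  }
  invisible(x)
}

#' Inhibitory concentrations from a fitted 4PL curve
#'
#' Closed-form inversion of the fitted curve.  In `"relative"` mode (the
#' default) the ICx is the dose where the curve reaches
#' `top - (x_percent/100) * (top - bottom)`, i.e. x% of the fitted span;
#' in `"absolute"` mode it is the dose where the curve equals
#' `100 - x_percent` percent of control, which may not exist within the
#' fitted span.
#'
#' @param fit A `fourpl` fit (must not be ambiguous).
#' @param x_percent Inhibition percentage(s) in (0, 100); 50 gives the IC50.
#' @param mode `"relative"` or `"absolute"`.
#' @return Dose-metric value(s), `NA` where the absolute level is outside
#'   the fitted span.
#' @examples
#' x <- c(0.625, 1.25, 1.9, 2.5, 3.75, 5, 10, 15)
#' fit <- fit_4pl(x, fourpl_curve(x, 100, 0, -1, log10(2)))
#' compute_icx(fit, c(10, 50, 90))
#' @export
compute_icx <- function(fit, x_percent, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  stop_if_not(inherits(fit, "fourpl"), "`fit` must be a fourpl object")
  stop_if_not(!fit$ambiguous,
              "ICx cannot be derived from an ambiguous 4PL fit")
  stop_if_not(is.numeric(x_percent) && all(x_percent > 0 & x_percent < 100),
              "`x_percent` must lie strictly between 0 and 100")
  cf <- fit$coefficients
  top <- cf[["top"]]
  bottom <- cf[["bottom"]]
  h <- cf[["hill_slope"]]
  target <- if (mode == "relative") top - (x_percent / 100) * (top - bottom)
  else 100 - x_percent
  z <- (top - bottom) / (target - bottom) - 1
  out <- ifelse(is.finite(z) & z > 0,
                10^(cf[["log_ic50"]] - log10(z) / h),
                NA_real_)
  stats::setNames(out, paste0("IC", x_percent))
}

#' Re-express dose-response curves on a kinetics-derived dose metric
#'
#' Replaces the nominal concentration on the x-axis of each scenario's
#' viability data with a chosen dose metric (computed from the calibrated
#' kinetic model via [dose_metric_table()]) and fits a 4PL curve per
#' scenario.  When the metric actually drives the response, the per-scenario
#' curves — and their IC50s — collapse onto each other regardless of
#' exposure scenario; on the nominal scale, accumulating chemicals instead
#' show IC50s that fall with repeated exposure.
#'
#' @param viability Viability records: data frame with `scenario_label`,
#'   `nominal_uM`, `percent_control` (e.g. from [normalize_viability()] or
#'   [generate_viability_dataset()]).
#' @param metrics A dose-metric table from [dose_metric_table()]; every
#'   (scenario, nominal) pair present in `viability` (apart from 0 uM
#'   controls) must have a row.
#' @param metric One of `"nominal"`, `"cmax_medium"`, `"cmax_cells"`,
#'   `"auc_medium"`, `"auc_cells"`.
#' @param ... Passed to [fit_4pl()] (e.g. `fixed = c(top = 100)`).
#' @return An object of class `dose_reexpression`: list with `metric`,
#'   `fits` (named list of `fourpl` per scenario) and `table` (one row per
#'   scenario: `metric`, `scenario_label`, `ic50`, `ci_low`, `ci_high`,
#'   `hill_slope`, `ambiguous`).
#' @export
reexpress_dose_response <- function(viability, metrics,
                                    metric = c("nominal", "cmax_medium",
                                               "cmax_cells", "auc_medium",
                                               "auc_cells"),
                                    ...) {
  metric <- match.arg(metric)
  need <- c("scenario_label", "nominal_uM", "percent_control")
  stop_if_not(is.data.frame(viability) && all(need %in% names(viability)),
              "viability needs columns: %s", paste(need, collapse = ", "))
  col <- c(nominal = "nominal", cmax_medium = "cmax_medium_uM",
           cmax_cells = "cmax_cells_nmol_per_1e5",
           auc_medium = "auc_medium_nmolh",
           auc_cells = "auc_cells_nmolh")[[metric]]
  stop_if_not(col %in% names(metrics),
              "metric column '%s' missing from `metrics`", col)
  via <- viability[viability$nominal_uM > 0, , drop = FALSE]
  mkey <- paste(metrics$scenario_label, metrics$nominal_uM)
  vkey <- paste(via$scenario_label, via$nominal_uM)
  miss <- !(vkey %in% mkey)
  stop_if_not(!any(miss),
              "no dose metric for (scenario, nominal) pair(s): %s",
              paste(unique(vkey[miss]), collapse = "; "))
  via$x <- metrics[[col]][match(vkey, mkey)]
  labs <- unique(via$scenario_label)
  fits <- lapply(labs, function(lab) {
    d <- via[via$scenario_label == lab, ]
    fit_4pl(d$x, d$percent_control, dose_metric = metric, ...)
  })
  names(fits) <- labs
  tab <- do.call(rbind, lapply(labs, function(lab) {
    f <- fits[[lab]]
    data.frame(metric = metric, scenario_label = lab, ic50 = f$ic50,
               ci_low = if (is.null(f$ci95)) NA_real_ else f$ci95[1],
               ci_high = if (is.null(f$ci95)) NA_real_ else f$ci95[2],
               hill_slope = f$coefficients[["hill_slope"]],
               ambiguous = f$ambiguous)
  }))
  rownames(tab) <- NULL
  structure(list(metric = metric, fits = fits, table = tab),
            class = "dose_reexpression")
}

#' @export
print.dose_reexpression <- function(x, digits = 4, ...) {
  cat(sprintf("Dose-response re-expression on metric '%s'\n", x$metric))
  tab <- x$table
  tab$ic50 <- signif(tab$ic50, digits)
  tab$ci_low <- signif(tab$ci_low, digits)
  tab$ci_high <- signif(tab$ci_high, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
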