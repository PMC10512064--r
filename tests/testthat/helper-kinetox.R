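# Shared fixtures, built in code.

toy_params <- function() {
  rate_parameters(ka_cell = 0.05, kd_cell = 0.01,
                  ka_plastic = 0.5, kd_plastic = 0.3, kdeg = 0.004)
}

# log-uniform random rate set in [1e-4, 1] /h
random_params <- function() {
  r <- 10^stats::runif(5, -4, 0)
  rate_parameters(r[1], r[2], r[3], r[4], r[5])
}

# trapezoid on arbitrary rows of a trajectory (independent of dose_metrics)
trapz_rows <- function(t, y) sum(diff(t) * (y[-1] + y[-length(y)]) / 2)

noise_free_truth <- function(...) {
  default_ground_truth(noise_cv_kinetics = 0, noise_sd_viability = 0, ...)
}
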