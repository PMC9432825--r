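# Shared fixtures: small rate sets and models built in code.

atp_rates <- function(k_trans = 0.3, km1 = 10) {
  rate_set(12.9, 12.9, 12.9, 11.6, km1, 2.2, 2.2, 1.4,
           k_trans = k_trans, interpretation = "atp_hydrolysis")
}

equal_rates <- function(k = 12.9, km = 2.2) {
  rate_set(k, k, k, k, km, km, km, km, k_trans = 0)
}

zero_rates <- function() rate_set(0, 0, 0, 0, 0, 0, 0, 0)

quiet_integrate <- function(model, t_grid, solver_config = list()) {
  suppressWarnings(integrate_model(model, t_grid, solver_config))
}

# distribution container with prescribed concentrations at one time,
# for metric edge cases (zero-rate model holds any state constant)
static_dist <- function(conc, total = sum(conc * seq_along(conc))) {
  model <- build_single_state_model(zero_rates(), length(conc),
                                    initial_distribution = conc)
  quiet_integrate(model, c(0, 1))
}

fast_solver <- list(rtol = 1e-6, atol = 1e-10, truncation_warn_frac = 1)
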