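# Forward-model builders mapping a fitted parameter vector onto
# predicted observables. Each builder returns a closure with a one-slot
# cache (the sampler evaluates the same theta twice when computing the
# likelihood at the MAP).

substitute_rates <- function(rates, fit_names, theta,
                             scheme = "two_state") {
  vals <- list(k1 = rates$k1, k2 = rates$k2, k3 = rates$k3, k4 = rates$k4,
               km1 = rates$km1, km2 = rates$km2, km3 = rates$km3,
               km4 = rates$km4, k_trans = rates$k_trans)
  rate_names <- intersect(fit_names, names(vals))
  vals[rate_names] <- as.list(theta[match(rate_names, fit_names)])
  if (scheme == "single_state") vals$k_trans <- 0
  rate_set(vals$k1, vals$k2, vals$k3, vals$k4,
           vals$km1, vals$km2, vals$km3, vals$km4, vals$k_trans,
           interpretation = "custom")
}

build_scheme_model <- function(scheme, rates, n_max, total_conc,
                               initial_distribution = NULL) {
  if (scheme == "single_state") {
    build_single_state_model(rates, n_max, total_conc,
                             initial_distribution)
  } else {
    build_two_state_model(rates, n_max, total_conc, initial_distribution)
  }
}

#' Forward model for mass-photometry subunit fractions
#'
#' Builds a function of the fitted parameter vector that integrates the
#' chosen scheme and returns the subunit-mass fractions of species
#' `1..n_species_out` at the requested observation times, concatenated
#' time-major. This is the solution-side quantity; detected event lists
#' are mapped to the same scale by [mp_recover_fractions()] before
#' fitting.
#'
#' @param scheme `"single_state"` or `"two_state"`.
#' @param rates baseline [rate_set()]; components named in `fit_names`
#'   are replaced by the fitted values.
#' @param fit_names character vector naming the fitted components
#'   (subset of `k1..k4`, `km1..km4`, `k_trans`).
#' @param n_max largest simulated species.
#' @param total_conc total actin, uM.
#' @param t_points_s observation times, s (must be > 0).
#' @param n_species_out number of species reported per time point.
#' @param solver_config passed to [integrate_model()].
#' @param initial_distribution optional starting distribution.
#' @return Function `f(theta)` returning a numeric vector of length
#'   `length(t_points_s) * n_species_out`.
#' @export
mp_forward_model <- function(scheme, rates, fit_names, n_max, total_conc,
                             t_points_s, n_species_out,
                             solver_config = list(),
                             initial_distribution = NULL) {
  force(list(scheme, rates, fit_names, n_max, total_conc, t_points_s,
             n_species_out, solver_config, initial_distribution))
  cache_theta <- NULL
  cache_val <- NULL
  t_grid <- c(0, sort(t_points_s))
  idx <- match(sort(t_points_s), t_grid)
  ord <- order(order(t_points_s))   # restore caller's time order
  function(theta) {
    if (!is.null(cache_theta) && identical(theta, cache_theta)) {
      return(cache_val)
    }
    r <- substitute_rates(rates, fit_names, theta, scheme)
    model <- build_scheme_model(scheme, r, n_max, total_conc,
                                initial_distribution)
    dist <- integrate_model(model, t_grid, solver_config)
    tot <- species_totals(dist)
    i <- seq_len(n_species_out)
    fr <- sweep(tot[idx, i, drop = FALSE], 2L, i, `*`) / total_conc
    out <- as.numeric(t(fr[ord, , drop = FALSE]))
    cache_theta <<- theta
    cache_val <<- out
    out
  }
}

#' Forward model for a bulk light-scattering trace
#'
#' Builds a function of the fitted parameter vector returning the
#' simulated scattering signal on the measurement grid. `fit_names` may
#' include `"sds"` (detection floor, rounded to an integer subunit
#' count) and `"s"` (scale) in addition to rate constants.
#'
#' @inheritParams mp_forward_model
#' @param t_grid_s measurement time grid, s, starting at 0.
#' @param sds,s defaults for the detection floor and scale when not
#'   fitted.
#' @return Function `f(theta)` returning the signal vector.
#' @export
scattering_forward_model <- function(scheme, rates, fit_names, n_max,
                                     total_conc, t_grid_s, sds = 30L,
                                     s = 1, solver_config = list(),
                                     initial_distribution = NULL) {
  force(list(scheme, rates, fit_names, n_max, total_conc, t_grid_s, sds,
             s, solver_config, initial_distribution))
  cache_theta <- NULL
  cache_val <- NULL
  function(theta) {
    if (!is.null(cache_theta) && identical(theta, cache_theta)) {
      return(cache_val)
    }
    sds_i <- if ("sds" %in% fit_names) {
      max(1L, round(theta[match("sds", fit_names)]))
    } else sds
    s_i <- if ("s" %in% fit_names) theta[match("s", fit_names)] else s
    r <- substitute_rates(rates, fit_names, theta, scheme)
    model <- build_scheme_model(scheme, r, n_max, total_conc,
                                initial_distribution)
    dist <- integrate_model(model, t_grid_s, solver_config)
    tr <- scattering_signal(dist, scattering_params(sds = sds_i, s = s_i,
                                                    n = n_max))
    cache_theta <<- theta
    cache_val <<- tr$signal
    tr$signal
  }
}
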