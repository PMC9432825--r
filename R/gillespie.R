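#' Exact stochastic simulation oracle for a polymerization model
#'
#' Runs Gillespie's direct method over the same reaction network as the
#' chosen scheme, in a finite volume that converts the macroscopic
#' uM^-1 s^-1 constants into per-molecule-pair propensities. Intended as
#' an independent check of the mean-field ODE solution on small
#' instances; it refuses systems above `molecule_cap`.
#'
#' The dimerization propensity is `(k1/omega) nA (nA - 1)` with
#' `omega = 1e-6 N_A V` molecules per uM, consistent with the
#' deterministic monomer loss `-2 k1 [A]^2`.
#'
#' @param model a `"model_spec"`.
#' @param copy_numbers optional integer vector of initial copy numbers
#'   per state; defaults to `round(omega * initial_distribution)`.
#' @param volume_L reaction volume in litres (sets `omega`).
#' @param t_grid times (s) at which state counts are recorded; must start
#'   at 0.
#' @param n_runs number of independent trajectories.
#' @param seed RNG seed; runs are reproducible given the seed.
#' @param molecule_cap refuse initial totals above this (the oracle is
#'   meant for small instances).
#' @param max_events per-run event cap (guards runaway simulations).
#' @return List with `counts` (array run x time x state), `omega`,
#'   `n_events` (per run) and `first_event_time` (per run).
#' @export
gillespie_oracle <- function(model, copy_numbers = NULL, volume_L,
                             t_grid, n_runs = 1L, seed = NULL,
                             molecule_cap = 1e6, max_events = 5e7) {
  stopifnot(inherits(model, "model_spec"))
  t_grid <- as.numeric(t_grid)
  if (t_grid[1] != 0 || any(diff(t_grid) <= 0)) {
    stop("t_grid must start at 0 and increase strictly")
  }
  omega <- 1e-6 * 6.02214076e23 * volume_L   # molecules per uM
  nst <- n_states(model)
  if (is.null(copy_numbers)) {
    copy_numbers <- round(omega * model$initial_distribution)
  }
  if (length(copy_numbers) != nst) {
    stop("copy_numbers must have length ", nst)
  }
  if (any(copy_numbers < 0) || any(copy_numbers != round(copy_numbers))) {
    stop("copy_numbers must be non-negative integers")
  }
  w <- subunit_weights(model$scheme, model$n_max)
  if (sum(w * copy_numbers) > molecule_cap) {
    stop("total subunit count exceeds molecule_cap = ", molecule_cap,
         ": the SSA oracle is for small instances")
  }
  if (!is.null(seed)) set.seed(seed)
  r <- model$rates
  rates <- as.numeric(c(r$k1, r$k2, r$k3, r$k4,
                        r$km1, r$km2, r$km3, r$km4, r$k_trans))
  scheme <- if (model$scheme == "single_state") 1L else 2L
  counts <- array(NA_real_, c(n_runs, length(t_grid), nst))
  n_events <- numeric(n_runs)
  first_event <- numeric(n_runs)
  for (run in seq_len(n_runs)) {
    res <- .Call(C_ssa, scheme, model$n_max, rates,
                 as.numeric(copy_numbers), omega, t_grid,
                 as.numeric(max_events))
    counts[run, , ] <- res$counts
    n_events[run] <- res$n_events
    first_event[run] <- res$first_event_time
  }
  list(counts = counts, omega = omega, t_grid = t_grid,
       n_events = n_events, first_event_time = first_event)
}
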