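#' Build the single-state nucleation-elongation model
#'
#' Constructs the classical stepwise polymerization scheme in which the
#' dimer forms with `k1/km1`, the trimer with `k2/km2`, the tetramer with
#' `k3/km3` and every further addition uses `k4/km4`. The largest simulated
#' species `n_max` is absorbing (no flux to `n_max + 1`). The monomer
#' balance carries a stoichiometric factor 2 on the dimerization terms.
#'
#' @param rates a [rate_set()] with `k_trans = 0`.
#' @param n_max largest simulated species (subunit count), at least 5 so
#'   that all distinguished steps up to the tetramer exist.
#' @param total_conc total subunit concentration in uM; defaults to the
#'   subunit mass of `initial_distribution`, or is required when the
#'   default all-monomer start is used.
#' @param initial_distribution optional numeric vector of length `n_max`
#'   with starting concentrations `[A_i]` in uM; default puts everything
#'   into monomers.
#' @return A `"model_spec"` object.
#' @seealso [build_two_state_model()], [integrate_model()]
#' @export
build_single_state_model <- function(rates, n_max, total_conc = NULL,
                                     initial_distribution = NULL) {
  stopifnot(inherits(rates, "rate_set"))
  if (rates$k_trans != 0) {
    stop("single-state scheme has no transition; k_trans must be 0")
  }
  if (n_max < 5) {
    stop("n_max must be >= 5: the scheme distinguishes steps up to the ",
         "tetramer")
  }
  new_model_spec("single_state", rates, n_max, total_conc,
                 initial_distribution)
}

#' Build the two-state (slow transition) polymerization model
#'
#' Constructs the scheme in which oligomers of trimer size and above
#' irreversibly transition (rate `k_trans`) into a kinetically distinct
#' primed state `A'` with its own association/dissociation constants
#' `k4/km4`. The unprimed pathway uses `k1/km1`, `k2/km2`, and `k3/km3`
#' for every step above the trimer. The primed trimer dissociates into a
#' dimer and a monomer at `km4`; no reverse primed-trimer formation from
#' the dimer exists.
#'
#' With `k_trans = 0` and matched stepwise rates the trajectories reduce
#' to those of the single-state scheme and the primed pool stays zero.
#'
#' @inheritParams build_single_state_model
#' @param rates a [rate_set()]; `k_trans >= 0`.
#' @param n_max largest simulated species, at least 4.
#' @param initial_distribution optional; either a length-`n_max` vector of
#'   unprimed concentrations (all species start unprimed, as when
#'   polymerization is induced at t = 0) or a length `2 * n_max - 2`
#'   vector including the primed species `A'_3..A'_n`.
#' @return A `"model_spec"` object.
#' @export
build_two_state_model <- function(rates, n_max, total_conc = NULL,
                                  initial_distribution = NULL) {
  stopifnot(inherits(rates, "rate_set"))
  if (n_max < 4) stop("n_max must be >= 4 for the two-state scheme")
  new_model_spec("two_state", rates, n_max, total_conc,
                 initial_distribution)
}

n_states <- function(model) {
  if (model$scheme == "single_state") model$n_max else 2L * model$n_max - 2L
}

new_model_spec <- function(scheme, rates, n_max, total_conc,
                           initial_distribution) {
  n_max <- as.integer(n_max)
  nst <- if (scheme == "single_state") n_max else 2L * n_max - 2L
  if (is.null(initial_distribution)) {
    if (is.null(total_conc)) {
      stop("either total_conc or initial_distribution must be given")
    }
    initial_distribution <- c(total_conc, numeric(nst - 1L))
  } else {
    if (length(initial_distribution) == n_max && nst != n_max) {
      # all species start unprimed
      initial_distribution <- c(initial_distribution, numeric(nst - n_max))
    }
    if (length(initial_distribution) != nst) {
      stop("initial_distribution must have length n_max (unprimed only) ",
           "or ", nst)
    }
    if (any(initial_distribution < 0)) {
      stop("initial distribution must be non-negative")
    }
    mass <- sum(subunit_weights(scheme, n_max) * initial_distribution)
    if (is.null(total_conc)) {
      total_conc <- mass
    } else if (abs(mass - total_conc) > 1e-9 * max(total_conc, 1e-300)) {
      stop(sprintf(
        "initial distribution carries %.12g uM subunits but total_conc = %g",
        mass, total_conc))
    }
  }
  structure(
    list(scheme = scheme, rates = rates, n_max = n_max,
         initial_distribution = initial_distribution,
         total_conc = total_conc),
    class = "model_spec")
}

# subunit multiplicity of each state-vector slot
subunit_weights <- function(scheme, n_max) {
  if (scheme == "single_state") seq_len(n_max)
  else c(seq_len(n_max), seq.int(3L, n_max))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> scheme: %s, n_max: %d, total %g uM actin\n",
              x$scheme, x$n_max, x$total_conc))
  print(x$rates)
  invisible(x)
}

#' Evaluate the model right-hand side in R
#'
#' Pure-R reference implementation of the scheme ODEs, used to cross-check
#' the compiled right-hand side and for small exploratory calculations.
#' State layout: `[A_1..A_n]` for the single-state scheme, followed by
#' `[A'_3..A'_n]` for the two-state scheme.
#'
#' @param model a `"model_spec"`.
#' @param state numeric state vector (uM).
#' @return Numeric vector of time derivatives (uM/s).
#' @export
model_rhs <- function(model, state) {
  r <- model$rates
  n <- model$n_max
  stopifnot(length(state) == n_states(model))
  A <- state[1]
  if (model$scheme == "single_state") {
    kon <- c(r$k1, r$k2, r$k3, rep(r$k4, n - 4L))      # step i -> i+1
    koff <- c(r$km1, r$km2, r$km3, rep(r$km4, n - 4L))
    f <- kon * state[seq_len(n - 1L)] * A
    f[1] <- r$k1 * A * A
    b <- koff * state[2:n]
    d <- numeric(n)
    d[2:n] <- c(f) - c(b)
    d[1:(n - 1L)] <- d[1:(n - 1L)] - (f - b)
    d[1] <- d[1] - (f[1] - b[1])                        # factor 2 on dimer
    d[1] <- d[1] - sum(f[-1] - b[-1])                   # monomer as substrate
    d
  } else {
    y <- state[seq_len(n)]
    yp <- c(0, 0, state[(n + 1L):(2L * n - 2L)])        # yp[i] = [A'_i]
    kon <- c(r$k1, r$k2, rep(r$k3, n - 3L))
    koff <- c(r$km1, r$km2, rep(r$km3, n - 3L))
    f <- kon * y[seq_len(n - 1L)] * A
    f[1] <- r$k1 * A * A
    b <- koff * y[2:n]
    d <- numeric(n)
    d[2:n] <- f - b
    d[1:(n - 1L)] <- d[1:(n - 1L)] - (f - b)
    d[1] <- d[1] - (f[1] - b[1])
    d[1] <- d[1] - sum(f[-1] - b[-1])
    tr <- r$k_trans * y[3:n]
    d[3:n] <- d[3:n] - tr
    dp <- numeric(n)
    dp[3:n] <- tr
    # primed trimer dissociation into dimer + monomer
    rel <- r$km4 * yp[3]
    dp[3] <- dp[3] - rel
    d[2] <- d[2] + rel
    d[1] <- d[1] + rel
    # primed elongation A'_i + A <-> A'_{i+1}
    if (n >= 4L) {
      fp <- r$k4 * yp[3:(n - 1L)] * A
      bp <- r$km4 * yp[4:n]
      dp[4:n] <- dp[4:n] + fp - bp
      dp[3:(n - 1L)] <- dp[3:(n - 1L)] - (fp - bp)
      d[1] <- d[1] - sum(fp - bp)
    }
    c(d, dp[3:n])
  }
}
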