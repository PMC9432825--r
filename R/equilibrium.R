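#' Closed-form steady state of the single-state scheme
#'
#' Solves the detailed-balance recursion
#' `[A_{i+1}] = (k_i / k_{-i}) [A] [A_i]` with the free monomer
#' concentration chosen by a monotone scalar root-find so that the total
#' subunit concentration equals `total_conc`. The result is an exact
#' fixed point of the single-state right-hand side (every stepwise flux
#' pair balances, including the absorbing top species).
#'
#' With equal stepwise rates and `k [A] / km < 1` the tail is geometric:
#' successive concentrations have the constant ratio `(k4/km4) [A]`,
#' the "approximately exponential distribution of oligomers" regime in
#' which long polymers stay rare.
#'
#' @param rates a [rate_set()] for the single-state scheme; all
#'   dissociation constants must be positive.
#' @param total_conc total subunit concentration, uM.
#' @param n_max largest species.
#' @return Numeric vector of length `n_max` with equilibrium
#'   concentrations in uM; attribute `"monomer"` holds the free monomer
#'   root.
#' @export
equilibrium_single_state <- function(rates, total_conc, n_max) {
  stopifnot(inherits(rates, "rate_set"))
  if (rates$k_trans != 0) {
    stop("equilibrium_single_state applies to the single-state scheme only")
  }
  if (min(rates$km1, rates$km2, rates$km3, rates$km4) <= 0) {
    stop("all dissociation rate constants must be > 0")
  }
  if (total_conc <= 0) stop("total_conc must be > 0")
  n_max <- as.integer(n_max)
  lr <- log(c(rates$k1 / rates$km1, rates$k2 / rates$km2,
              rates$k3 / rates$km3, rep(rates$k4 / rates$km4,
                                        max(0L, n_max - 4L))))
  # log [A_i] as a function of log [A]: cumulative sums in log space to
  # survive long geometric tails without overflow
  total_mass <- function(logA) {
    lc <- c(logA, logA + cumsum(lr[seq_len(n_max - 1L)] + logA))
    m <- sum(exp(log(seq_len(n_max)) + lc))
    if (!is.finite(m)) m <- 1e300   # supersaturated overflow: keep monotone
    m
  }
  f <- function(logA) total_mass(logA) - total_conc
  hi <- log(total_conc)
  lo <- hi
  while (f(lo) > 0) lo <- lo - 5
  if (f(hi) < 0) {
    # supersaturated ratios can put the root above the all-monomer guess
    while (f(hi) < 0 && hi < log(total_conc) + 50) hi <- hi + 1
    if (f(hi) < 0) stop("no equilibrium root in (0, total_conc]")
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-15)$root
  lc <- c(root, root + cumsum(lr[seq_len(n_max - 1L)] + root))
  conc <- exp(lc)
  structure(conc, monomer = exp(root))
}
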