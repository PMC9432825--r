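#' Kinetic rate-constant set for a polymerization scheme
#'
#' Bundles the stepwise association constants `k1..k4` (uM^-1 s^-1), the
#' dissociation constants `km1..km4` (s^-1) and the irreversible
#' state-transition constant `k_trans` (s^-1, 0 for the single-state
#' scheme) together with a biological interpretation label.
#'
#' Interpretations map the generic constants onto end-specific actin
#' rates: in the `atp_hydrolysis` reading `k1..k3` are the summed barbed +
#' pointed end association rates of Mg-ATP-actin, `km2 = km3` the summed
#' shortening rates, and `k_trans` is the filament ATP hydrolysis rate
#' `k_hydr`; in the `cation_exchange` reading the unprimed pathway carries
#' Ca-actin rates, the primed pathway Mg-actin rates, and `k_trans` the
#' Ca->Mg activation rate.
#'
#' @param k1,k2,k3,k4 association rate constants, uM^-1 s^-1.
#' @param km1,km2,km3,km4 dissociation rate constants, s^-1.
#' @param k_trans irreversible transition rate constant, s^-1.
#' @param interpretation one of `"sept_mccammon"`, `"sept_mccammon_adjusted"`,
#'   `"atp_hydrolysis"`, `"cation_exchange"`, `"custom"`.
#' @param provenance named character vector or list of free-text provenance
#'   notes per constant (e.g. literature citation or "fitted").
#' @return An object of class `"rate_set"`.
#' @examples
#' rs <- rate_set(k1 = 12.9, k2 = 12.9, k3 = 12.9, k4 = 12.9,
#'                km1 = 10, km2 = 2.2, km3 = 2.2, km4 = 2.2,
#'                k_trans = 0.3, interpretation = "atp_hydrolysis")
#' @export
rate_set <- function(k1, k2, k3, k4, km1, km2, km3, km4, k_trans = 0,
                     interpretation = "custom", provenance = list()) {
  vals <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4,
            km1 = km1, km2 = km2, km3 = km3, km4 = km4,
            k_trans = k_trans)
  if (any(!is.finite(vals))) {
    stop("all rate constants must be finite numbers")
  }
  if (any(vals < 0)) {
    stop("negative rate constant: ",
         paste(names(vals)[vals < 0], collapse = ", "))
  }
  interpretation <- match.arg(interpretation,
    c("custom", "sept_mccammon", "sept_mccammon_adjusted",
      "atp_hydrolysis", "cation_exchange"))
  if (interpretation == "atp_hydrolysis") {
    if (!isTRUE(all.equal(k1, k2)) || !isTRUE(all.equal(k2, k3))) {
      stop("atp_hydrolysis interpretation requires k1 = k2 = k3 ",
           "(summed barbed + pointed end association rate)")
    }
    if (!isTRUE(all.equal(km2, km3))) {
      stop("atp_hydrolysis interpretation requires km2 = km3")
    }
  }
  structure(
    list(k1 = k1, k2 = k2, k3 = k3, k4 = k4,
         km1 = km1, km2 = km2, km3 = km3, km4 = km4,
         k_trans = k_trans,
         interpretation = interpretation,
         provenance = provenance),
    class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set> interpretation:", x$interpretation, "\n")
  cat(sprintf("  association  k1..k4  : %g %g %g %g  uM^-1 s^-1\n",
              x$k1, x$k2, x$k3, x$k4))
  cat(sprintf("  dissociation km1..km4: %g %g %g %g  s^-1\n",
              x$km1, x$km2, x$km3, x$km4))
  cat(sprintf("  transition   k_trans : %g  s^-1\n", x$k_trans))
  invisible(x)
}

#' Map generic rate constants onto filament-end language
#'
#' Returns the biological reading of a rate set: `k_b + k_p` style sums for
#' the elongation steps and `k_hydr` (or the cation activation rate) for the
#' transition, following the interpretation label.
#'
#' @param rates a [rate_set()].
#' @return Named list with `k_elong`, `km_elong`, `km_dimer`, `k_trans` and
#'   the interpretation label.
#' @export
rate_interpretation <- function(rates) {
  stopifnot(inherits(rates, "rate_set"))
  list(interpretation = rates$interpretation,
       k_elong = rates$k3,
       km_elong = rates$km3,
       km_dimer = rates$km1,
       k_trans = rates$k_trans)
}
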