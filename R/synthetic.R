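#' Define a synthetic-data scenario
#'
#' A scenario bundles a kinetic model with a mass-photometry acquisition
#' plan (time points and target event counts per landing video), a bulk
#' light-scattering plan (sampling interval, number of points, additive
#' noise variance) and the instrument noise settings the analysis
#' assumes: Gaussian oligomer mass peaks at multiples of 42 kDa,
#' species landing rates biased by their diffusion coefficients, and an
#' imperfect monomer detection efficiency.
#'
#' @param name scenario name.
#' @param scheme `"single_state"` or `"two_state"`.
#' @param rates a [rate_set()]; `NULL` only for citation-placeholder
#'   templates.
#' @param n_max largest simulated species.
#' @param total_conc total actin, uM.
#' @param time_points_min MP acquisition times, minutes after induction.
#' @param target_events target detected events per video (recycled to
#'   the number of time points). Experimental videos yield roughly
#'   3,000-30,000 events; defaults are scaled down tenfold for speed.
#' @param mass_peak_sd Gaussian SD of the oligomer mass peaks, kDa.
#' @param monomer_efficiency monomer detection efficiency.
#' @param scattering list with `interval_s`, `n_points`, `noise_var`
#'   (a.u.^2), `sds`, `s`.
#' @param diffusion a [diffusion_params()].
#' @param contaminant_frac fraction of additional false-positive events
#'   with uniform masses in the low-mass window 21-210 kDa (default 0;
#'   real acquisitions show ~5% monomer-sized false positives, which
#'   are not corrected for by the analysis).
#' @param seed default RNG seed of the scenario.
#' @param template logical; `TRUE` marks a citation-placeholder preset
#'   that carries no usable rate constants.
#' @param provenance free-text provenance notes.
#' @return A `"scenario_preset"`.
#' @export
scenario_preset <- function(name, scheme, rates, n_max, total_conc,
                            time_points_min = c(1, 5, 10, 15),
                            target_events = 1500,
                            mass_peak_sd = 8,
                            monomer_efficiency = 0.876,
                            scattering = list(interval_s = 2,
                                              n_points = 1800,
                                              noise_var = 1740,
                                              sds = 30, s = 1000),
                            diffusion = diffusion_params(),
                            contaminant_frac = 0,
                            seed = 1L, template = FALSE,
                            provenance = character()) {
  if (contaminant_frac < 0 || contaminant_frac > 0.5) {
    stop("contaminant_frac must be in [0, 0.5]")
  }
  if (!template) {
    stopifnot(inherits(rates, "rate_set"))
    # validates the model invariants (n_max floor, mass bookkeeping)
    invisible(build_scheme_model(scheme, rates, n_max, total_conc))
    target_events <- rep_len(target_events, length(time_points_min))
    if (any(target_events <= 0)) stop("target event counts must be > 0")
    if (mass_peak_sd < 0 || scattering$noise_var < 0) {
      stop("noise scales must be >= 0")
    }
  }
  structure(list(name = name, scheme = scheme, rates = rates,
                 n_max = as.integer(n_max), total_conc = total_conc,
                 time_points_min = time_points_min,
                 target_events = target_events,
                 mass_peak_sd = mass_peak_sd,
                 monomer_efficiency = monomer_efficiency,
                 scattering = scattering, diffusion = diffusion,
                 contaminant_frac = contaminant_frac,
                 seed = seed, template = template,
                 provenance = provenance),
            class = "scenario_preset")
}

#' Built-in scenario presets
#'
#' Ships ready-made study conditions:
#' \describe{
#'   \item{atp_hydrolysis_900nM}{two-state scheme at 900 nM actin with
#'     the summed barbed + pointed end rates (12.9 uM^-1 s^-1 on,
#'     2.2 s^-1 off) and the filament ATP hydrolysis rate as the
#'     transition.}
#'   \item{atp_hydrolysis_2uM_scattering}{same rates at 2 uM for bulk
#'     light-scattering comparisons (1800 points at 2-s spacing).}
#'   \item{cation_exchange_AMPPNP}{Ca-actin rates (10.6 uM^-1 s^-1 on,
#'     5.0 s^-1 off) in the unprimed pathway, Mg-actin rates (12.9 /
#'     2.2) in the primed pathway, Ca->Mg activation as the transition.}
#'   \item{single_state_equal_rates}{single-state scheme with one
#'     association and one dissociation constant for every step.}
#'   \item{sm_template_empty_rates}{citation-only template for the
#'     free-energy-derived nucleation rate table, which must be
#'     transcribed from the original reference by the user; carries no
#'     fabricated numbers.}
#' }
#'
#' The dimer dissociation constant `km1` (never published) defaults to
#' 10 s^-1 as a documented order-of-magnitude placeholder and is a
#' primary target of parameter recovery. The transition rates default
#' to 0.3 s^-1 (canonical filament ATP hydrolysis rate) and 0.02 s^-1
#' (Ca->Mg activation); both are config fields, not hard-coded
#' constants.
#'
#' @param km1 dimer dissociation rate constant, s^-1.
#' @param k_hydr filament ATP hydrolysis rate constant, s^-1.
#' @param k_cation Ca->Mg activation rate constant, s^-1.
#' @return Named list of [scenario_preset()] objects.
#' @export
fixture_presets <- function(km1 = 10, k_hydr = 0.3, k_cation = 0.02) {
  atp_rates <- rate_set(
    k1 = 12.9, k2 = 12.9, k3 = 12.9, k4 = 11.6,
    km1 = km1, km2 = 2.2, km3 = 2.2, km4 = 1.4, k_trans = k_hydr,
    interpretation = "atp_hydrolysis",
    provenance = list(
      k1 = "sum of barbed (11.6) + pointed (1.3) end association rates",
      km2 = "sum of barbed (1.4) + pointed (0.8) end dissociation rates",
      k4 = "barbed-end association only: pointed end stabilized by ADP-Pi",
      km4 = "barbed-end dissociation only (stabilized pointed end)",
      km1 = "order-of-magnitude placeholder, unverified; fit target",
      k_trans = "filament ATP hydrolysis rate, literature"))
  cation_rates <- rate_set(
    k1 = 10.6, k2 = 10.6, k3 = 10.6, k4 = 12.9,
    km1 = km1, km2 = 5.0, km3 = 5.0, km4 = 2.2, k_trans = k_cation,
    interpretation = "cation_exchange",
    provenance = list(
      k1 = "Ca-actin barbed (9.5) + pointed (1.1) association rates",
      km2 = "Ca-actin barbed (4.2) + pointed (0.8) dissociation rates",
      k4 = "Mg-actin summed end rates",
      km1 = "order-of-magnitude placeholder, unverified; fit target",
      k_trans = "Ca->Mg monomer activation rate, literature"))
  equal_rates <- rate_set(
    k1 = 12.9, k2 = 12.9, k3 = 12.9, k4 = 12.9,
    km1 = 2.2, km2 = 2.2, km3 = 2.2, km4 = 2.2, k_trans = 0,
    interpretation = "custom",
    provenance = list(all = "equal stepwise rates (no nucleation barrier)"))
  list(
    atp_hydrolysis_900nM = scenario_preset(
      "atp_hydrolysis_900nM", "two_state", atp_rates,
      n_max = 400L, total_conc = 0.9,
      target_events = c(900, 2900, 1400, 2000)),
    atp_hydrolysis_2uM_scattering = scenario_preset(
      "atp_hydrolysis_2uM_scattering", "two_state", atp_rates,
      n_max = 2000L, total_conc = 2.0),
    cation_exchange_AMPPNP = scenario_preset(
      "cation_exchange_AMPPNP", "two_state", cation_rates,
      n_max = 400L, total_conc = 2.0),
    single_state_equal_rates = scenario_preset(
      "single_state_equal_rates", "single_state", equal_rates,
      n_max = 400L, total_conc = 0.9),
    sm_template_empty_rates = scenario_preset(
      "sm_template_empty_rates", "single_state", rates = NULL,
      n_max = 400L, total_conc = 0.9, template = TRUE,
      provenance = c(
        "stepwise nucleation rate constants from free-energy",
        "calculations; transcribe from the original reference",
        "supplement (original and adjusted tables) before use")))
}

#' Generate a synthetic mass-photometry dataset
#'
#' Inverts the analysis chain: integrates the scenario's model, converts
#' the species concentrations at each acquisition time into expected
#' detected counts (landing-rate downscaling by `D_i / D_monomer` as
#' independent per-species thinning, monomer detection-efficiency
#' thinning), draws the event composition from a multinomial at the
#' target total, and synthesizes particle masses with Gaussian peak
#' noise. Returns the events together with the exact generating
#' trajectory.
#'
#' @param preset a [scenario_preset()].
#' @param seed RNG seed (defaults to the preset's).
#' @param output_interval_s trajectory output spacing, s.
#' @return List with `events` (one [mass_event_list()] per time point),
#'   `truth` (the generating `"distribution_timecourse"`),
#'   `components` (the Gaussian peak table used) and `preset`.
#' @export
generate_mp_dataset <- function(preset, seed = NULL,
                                output_interval_s = 30) {
  stopifnot(inherits(preset, "scenario_preset"))
  if (preset$template) stop("template presets carry no rate constants")
  if (is.null(seed)) seed <- preset$seed
  set.seed(seed)
  if (any(preset$target_events < 100)) {
    warning("fewer than 100 expected events at some time point: ",
            "recovery tests will be unreliable")
  }
  model <- build_scheme_model(preset$scheme, preset$rates, preset$n_max,
                              preset$total_conc)
  horizon <- max(preset$time_points_min) * 60
  t_grid <- seq(0, horizon, by = output_interval_s)
  dist <- integrate_model(model, t_grid)
  components <- data.frame(species_index = 1:3,
                           mean = 42 * (1:3),
                           sd = preset$mass_peak_sd)
  i <- seq_len(preset$n_max)
  landing_bias <- diffusion_coefficient(i, preset$diffusion) /
    preset$diffusion$D_monomer
  events <- vector("list", length(preset$time_points_min))
  names(events) <- paste0("t", preset$time_points_min, "min")
  for (j in seq_along(preset$time_points_min)) {
    ti <- which.min(abs(t_grid - preset$time_points_min[j] * 60))
    conc <- species_totals(dist)[ti, ]
    expected <- concentrations_to_counts(conc, N_total = 1e6,
                                         round_counts = FALSE)$N
    w <- expected * landing_bias
    w[1] <- w[1] * preset$monomer_efficiency
    p <- w / sum(w)
    draws <- stats::rmultinom(1, preset$target_events[j], p)[, 1]
    ev <- synthesize_mass_events(
      species_counts(draws), components,
      time_label_min = preset$time_points_min[j])
    cf <- preset$contaminant_frac
    if (!is.null(cf) && cf > 0) {
      n_fp <- round(cf * length(ev$masses))
      ev$masses <- c(ev$masses, stats::runif(n_fp, 21, 210))
    }
    events[[j]] <- ev
  }
  list(events = events, truth = dist, components = components,
       preset = preset, seed = seed)
}

#' Generate a synthetic bulk light-scattering dataset
#'
#' Noiseless squared-mass forward trace plus i.i.d. zero-mean Gaussian
#' noise of the configured variance on the measurement grid.
#'
#' @param preset a [scenario_preset()].
#' @param seed RNG seed (defaults to the preset's).
#' @return List with `trace` (noisy, provenance `"synthetic"`),
#'   `truth_trace` (noiseless) and `truth` (the trajectory).
#' @export
generate_scattering_dataset <- function(preset, seed = NULL) {
  stopifnot(inherits(preset, "scenario_preset"))
  if (preset$template) stop("template presets carry no rate constants")
  if (is.null(seed)) seed <- preset$seed
  set.seed(seed)
  sc <- preset$scattering
  model <- build_scheme_model(preset$scheme, preset$rates, preset$n_max,
                              preset$total_conc)
  t_grid <- seq(0, by = sc$interval_s, length.out = sc$n_points)
  dist <- integrate_model(model, t_grid)
  pars <- scattering_params(sds = sc$sds, s = sc$s, n = preset$n_max)
  clean <- scattering_signal(dist, pars)
  noisy <- scattering_trace(
    clean$times, clean$signal + stats::rnorm(sc$n_points, 0,
                                             sqrt(sc$noise_var)),
    params = pars, provenance = "synthetic")
  list(trace = noisy, truth_trace = clean, truth = dist, seed = seed)
}

#' Recover subunit-mass fractions from a mass-event list
#'
#' The analysis half of the pipeline: decomposes the low-mass peaks with
#' a Gaussian mixture fit, counts heavier species in 42-kDa bins,
#' applies the landing-rate and monomer-efficiency upscale, and converts
#' to concentrations. Returns the subunit-mass fraction per species.
#'
#' @param events a [mass_event_list()].
#' @param total_conc total actin concentration, uM.
#' @param n_components Gaussian components for the low-mass fit.
#' @param n_species_max largest species index reported.
#' @param params a [diffusion_params()].
#' @param monomer_efficiency monomer detection efficiency.
#' @param fit_components `FALSE` substitutes exact peak positions
#'   (means at multiples of 42 kDa) instead of fitting, for use deep in
#'   loops.
#' @return List with `fractions` (subunit-mass fraction per species),
#'   `concentrations`, `counts` and `components`.
#' @export
mp_recover_fractions <- function(events, total_conc, n_components = 3,
                                 n_species_max = 400L,
                                 params = diffusion_params(),
                                 monomer_efficiency = 0.876,
                                 fit_components = TRUE) {
  stopifnot(inherits(events, "mass_event_list"))
  if (fit_components) {
    lowmass <- events$masses[events$masses < 42 * (n_components + 0.5)]
    hist4 <- mass_histogram(lowmass, bin_width = 4,
                            mass_range = c(0, 42 * (n_components + 0.5)))
    comps <- fit_gaussian_mixture(hist4, n_components)
  } else {
    comps <- data.frame(species_index = seq_len(n_components),
                        mean = 42 * seq_len(n_components), sd = 8,
                        area = NA_real_)
    comps$area <- vapply(comps$species_index, function(i) {
      sum(events$masses >= 42 * i - 21 & events$masses < 42 * i + 21)
    }, numeric(1))
  }
  counts <- counts_from_events(events, comps,
                               n_species_max = n_species_max)
  up <- landing_rate_correction(counts, "upscale", params,
                                monomer_efficiency)
  conc <- counts_to_concentrations(up, total_conc)
  i <- seq_along(conc)
  list(fractions = conc * i / total_conc, concentrations = conc,
       counts = counts, components = comps)
}
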