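#' Mass-photometry event list
#'
#' A flat list of detected single-particle masses (kDa) from one landing
#' video, with its acquisition time label and metadata.
#'
#' @param masses numeric vector of particle masses, kDa; positive, finite.
#' @param time_label_min minutes after polymerization induction.
#' @param dilution_factor fold dilution applied immediately before the
#'   measurement (metadata only; the dilution step is not modelled).
#' @param video_duration_s landing-video duration, s.
#' @return A `"mass_event_list"`.
#' @export
mass_event_list <- function(masses, time_label_min = NA_real_,
                            dilution_factor = NA_real_,
                            video_duration_s = 60) {
  masses <- as.numeric(masses)
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("all event masses must be finite and > 0 kDa")
  }
  structure(list(masses = masses, time_label_min = time_label_min,
                 dilution_factor = dilution_factor,
                 video_duration_s = video_duration_s),
            class = "mass_event_list")
}

#' Bin an event list into a mass histogram
#'
#' @param events a [mass_event_list()] or numeric vector of masses (kDa).
#' @param bin_width histogram bin width, kDa (4 for display, 42 for
#'   species counting).
#' @param mass_range optional `c(lo, hi)` range to cover; defaults to the
#'   data range padded by one bin.
#' @return `data.frame` with `bin_center_kDa` and `count`.
#' @export
mass_histogram <- function(events, bin_width = 4, mass_range = NULL) {
  masses <- if (inherits(events, "mass_event_list")) events$masses
            else as.numeric(events)
  if (is.null(mass_range)) {
    mass_range <- range(masses)
    mass_range <- mass_range + c(-1, 1) * bin_width
  }
  breaks <- seq(floor(mass_range[1] / bin_width) * bin_width,
                ceiling(mass_range[2] / bin_width) * bin_width,
                by = bin_width)
  h <- graphics::hist(masses, breaks = breaks, plot = FALSE, right = FALSE)
  data.frame(bin_center_kDa = h$mids, count = h$counts)
}

#' Fit a sum of Gaussians to the low-mass region of a histogram
#'
#' Decomposes the resolved low-order oligomer peaks (centred near integer
#' multiples of the subunit mass) into Gaussian components by bounded
#' least squares. The area under each component is the species count.
#'
#' @param histogram `data.frame` with `bin_center_kDa` and `count`.
#' @param n_components number of components, 1 to 4.
#' @param bounds_config list with optional entries `monomer_mass` (42),
#'   `mean_tol_frac` (0.25: means constrained to i * monomer_mass +/-
#'   25%), `sd_lo` (2), `sd_hi` (30), `sd_init` (8).
#' @return `data.frame` of components: `species_index`, `mean`, `sd`,
#'   `area` (event count by analytic Gaussian integral), sorted by
#'   strictly increasing mean.
#' @export
fit_gaussian_mixture <- function(histogram, n_components,
                                 bounds_config = list()) {
  cfg <- utils::modifyList(
    list(monomer_mass = 42, mean_tol_frac = 0.25, sd_lo = 2, sd_hi = 30,
         sd_init = 8), bounds_config)
  if (!all(c("bin_center_kDa", "count") %in% names(histogram))) {
    stop("histogram needs columns bin_center_kDa and count")
  }
  if (nrow(histogram) == 0 || sum(histogram$count) == 0) {
    stop("empty histogram: nothing to fit")
  }
  if (!n_components %in% 1:4) stop("n_components must be 1..4")
  x <- histogram$bin_center_kDa
  y <- histogram$count
  w <- stats::median(diff(sort(unique(x))))
  m0 <- cfg$monomer_mass * seq_len(n_components)
  if (max(x) < m0[n_components] * (1 - cfg$mean_tol_frac)) {
    stop("histogram does not cover the low-mass region of all components")
  }
  a0 <- vapply(m0, function(m) {
    max(sum(y[abs(x - m) < cfg$monomer_mass / 2]), 1)
  }, numeric(1))
  start <- c(m0, rep(cfg$sd_init, n_components), a0)
  lower <- c(m0 * (1 - cfg$mean_tol_frac), rep(cfg$sd_lo, n_components),
             rep(0, n_components))
  upper <- c(m0 * (1 + cfg$mean_tol_frac), rep(cfg$sd_hi, n_components),
             rep(sum(y) * 10, n_components))
  nc <- n_components
  mixture <- function(p) {
    yy <- numeric(length(x))
    for (j in seq_len(nc)) {
      yy <- yy + p[2 * nc + j] * w * stats::dnorm(x, p[j], p[nc + j])
    }
    yy
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper,
    fn = function(p) mixture(p) - y,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  rss <- sum(fit$fvec^2)
  if (!fit$info %in% 1:4) {
    stop("Gaussian mixture fit did not converge (", fit$message,
         "); residual sum of squares ", signif(rss, 4))
  }
  p <- fit$par
  out <- data.frame(
    species_index = seq_len(nc),
    mean = p[seq_len(nc)],
    sd = p[nc + seq_len(nc)],
    area = p[2 * nc + seq_len(nc)])
  if (any(diff(out$mean) <= 0)) {
    stop("fitted component means are not strictly increasing; ",
         "residual sum of squares ", signif(rss, 4))
  }
  out
}

#' Detected-particle counts per species
#'
#' @param N numeric vector of event counts; element `i` is species `i`.
#' @param corrected_landing,corrected_efficiency flags tracking whether
#'   landing-rate / detection-efficiency corrections have been applied.
#' @return A `"species_counts"` with fields `N`, `N_subunits = N * i`,
#'   `N_total` and the correction flags.
#' @export
species_counts <- function(N, corrected_landing = FALSE,
                           corrected_efficiency = FALSE) {
  N <- as.numeric(N)
  if (any(!is.finite(N)) || any(N < 0)) {
    stop("species counts must be finite and >= 0")
  }
  i <- seq_along(N)
  structure(list(N = N, N_subunits = N * i, N_total = sum(N * i),
                 corrected_landing = corrected_landing,
                 corrected_efficiency = corrected_efficiency),
            class = "species_counts")
}

#' @export
print.species_counts <- function(x, ...) {
  nz <- which(x$N > 0)
  cat(sprintf(
    "<species_counts> %d species with events, %g subunits total%s%s\n",
    length(nz), x$N_total,
    if (x$corrected_landing) ", landing-corrected" else "",
    if (x$corrected_efficiency) ", efficiency-corrected" else ""))
  invisible(x)
}

#' Count events per species from a mass-event list
#'
#' Species covered by fitted Gaussian components are counted by the
#' component areas; heavier species are counted by occupancy of
#' half-open bins `[i*42 - 21, i*42 + 21)` centred on integer multiples
#' of the subunit mass (boundary events go to the upper bin).
#'
#' @param events a [mass_event_list()].
#' @param components `data.frame` from [fit_gaussian_mixture()] covering
#'   species `1..m` contiguously; `NULL` to bin everything.
#' @param bin_width species bin width, kDa (the subunit mass).
#' @param n_species_max largest species index to keep.
#' @return A [species_counts()].
#' @export
counts_from_events <- function(events, components = NULL, bin_width = 42,
                               n_species_max = NULL) {
  stopifnot(inherits(events, "mass_event_list"))
  m <- 0L
  if (!is.null(components)) {
    if (!identical(as.integer(components$species_index),
                   seq_len(nrow(components)))) {
      stop("components must cover species 1..m contiguously; ",
           "overlapping or gapped assignment")
    }
    m <- nrow(components)
  }
  idx <- floor((events$masses + bin_width / 2) / bin_width)
  idx <- idx[idx > m]            # bins tile masses above the last component
  if (is.null(n_species_max)) {
    n_species_max <- max(c(idx, m, 1L))
  }
  idx <- idx[idx <= n_species_max]
  N <- numeric(n_species_max)
  if (m > 0) N[seq_len(m)] <- components$area
  tb <- tabulate(idx, nbins = n_species_max)
  N <- N + tb
  species_counts(N)
}

#' Convert species counts to concentrations
#'
#' Distributes the known total actin concentration over species in
#' proportion to their subunit-weighted counts:
#' `N_subunits,i = N_i * i`, `[A_i]_subunits = total * N_subunits,i /
#' sum(N_subunits)`, `[A_i] = [A_i]_subunits / i`. The subunit mass
#' balance `sum(i * [A_i]) = total_conc` holds exactly.
#'
#' @param counts a [species_counts()].
#' @param total_conc total actin concentration, uM.
#' @return Numeric vector of species concentrations `[A_i]`, uM.
#' @export
counts_to_concentrations <- function(counts, total_conc) {
  stopifnot(inherits(counts, "species_counts"))
  if (counts$N_total <= 0) stop("zero total subunit count")
  i <- seq_along(counts$N)
  conc_sub <- total_conc * counts$N_subunits / counts$N_total
  conc_sub / i
}

#' Convert species concentrations to detected counts
#'
#' Inverse bookkeeping at a fixed total subunit count:
#' `[A_i]_subunits = [A_i] * i`, `N_subunits,i = N_total *
#' [A_i]_subunits / sum([A_i]_subunits)`, `N_i = round(N_subunits,i /
#' i)` (round-half-even). For two-state trajectories pass the primed +
#' unprimed sum per size ([species_totals()]): the two states are
#' indistinguishable by mass measurement.
#'
#' @param concs numeric vector of species concentrations, uM.
#' @param N_total total subunit count to distribute.
#' @param round_counts apply the integer rounding (`TRUE`, as printed) or
#'   keep fractional expected counts (`FALSE`, used when the counts feed
#'   a multinomial draw).
#' @return A [species_counts()].
#' @export
concentrations_to_counts <- function(concs, N_total, round_counts = TRUE) {
  concs <- as.numeric(concs)
  if (any(concs < 0)) stop("concentrations must be >= 0")
  if (all(concs == 0)) stop("all-zero concentrations")
  if (N_total <= 0) stop("N_total must be > 0")
  i <- seq_along(concs)
  conc_sub <- concs * i
  n_sub <- N_total * conc_sub / sum(conc_sub)
  N <- n_sub / i
  if (round_counts) N <- round(N)
  species_counts(N)
}

#' Diffusion-model parameters for landing-rate corrections
#'
#' @param D_monomer monomer diffusion coefficient, cm^2 s^-1.
#' @param M_monomer subunit mass, kDa.
#' @param rod_diameter_nm filament diameter, nm.
#' @param subunit_rise_nm filament length per subunit, nm (`L = i * rise`).
#' @param temperature_K temperature for the rod model.
#' @param viscosity_Pa_s solvent viscosity.
#' @param sphere_max_i largest species treated as a sphere; larger
#'   species use the rigid-rod model.
#' @return A `"diffusion_params"` list.
#' @export
diffusion_params <- function(D_monomer = 7.9e-7, M_monomer = 42,
                             rod_diameter_nm = 7, subunit_rise_nm = 2.7,
                             temperature_K = 293.15,
                             viscosity_Pa_s = 1e-3, sphere_max_i = 4L) {
  vals <- c(D_monomer, M_monomer, rod_diameter_nm, subunit_rise_nm,
            temperature_K, viscosity_Pa_s, sphere_max_i)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all diffusion parameters must be positive and finite")
  }
  structure(list(D_monomer = D_monomer, M_monomer = M_monomer,
                 rod_diameter_nm = rod_diameter_nm,
                 subunit_rise_nm = subunit_rise_nm,
                 temperature_K = temperature_K,
                 viscosity_Pa_s = viscosity_Pa_s,
                 sphere_max_i = as.integer(sphere_max_i)),
            class = "diffusion_params")
}

#' Diffusion coefficient of an oligomer
#'
#' Species up to `sphere_max_i` are treated as spheres whose diffusion
#' coefficient scales with the cube root of mass,
#' `D_i = D_monomer * i^(-1/3)`. Larger species are modelled as rigid
#' rods of diameter `d` and length `L = i * rise` with
#' `D = kB T (ln p + v) / (3 pi eta L)`, `p = L/d`,
#' `v = 0.312 + 0.565/p - 0.1/p^2` (Tirado-Garcia de la Torre end
#' correction). The sphere/rod discontinuity at the regime boundary is
#' kept as is, not smoothed.
#'
#' @param i species index (number of subunits); vectorized.
#' @param params a [diffusion_params()].
#' @return Diffusion coefficients in cm^2 s^-1.
#' @export
diffusion_coefficient <- function(i, params = diffusion_params()) {
  stopifnot(inherits(params, "diffusion_params"))
  i <- as.numeric(i)
  if (any(i < 1)) stop("species index must be >= 1")
  kB <- 1.380649e-23
  D <- params$D_monomer * i^(-1 / 3)
  rod <- i > params$sphere_max_i
  if (any(rod)) {
    L <- i[rod] * params$subunit_rise_nm * 1e-9      # m
    p <- L / (params$rod_diameter_nm * 1e-9)
    v <- 0.312 + 0.565 / p - 0.1 / p^2
    D_m2 <- kB * params$temperature_K * (log(p) + v) /
      (3 * pi * params$viscosity_Pa_s * L)
    D[rod] <- D_m2 * 1e4                             # m^2/s -> cm^2/s
  }
  D
}

#' Landing-rate and detection-efficiency correction of species counts
#'
#' Slow-diffusing large species land on the measurement surface less
#' often than monomers; `upscale` multiplies each count by
#' `D_monomer / D_i` to recover solution proportions, and divides the
#' monomer count by the monomer detection efficiency. `downscale` is the
#' exact inverse, used when projecting simulated counts onto what the
#' instrument would detect. Double application in the same direction is
#' refused via the correction flags.
#'
#' @param counts a [species_counts()].
#' @param direction `"upscale"` (detected -> solution) or `"downscale"`.
#' @param params a [diffusion_params()].
#' @param monomer_efficiency monomer true-positive detection efficiency
#'   (0.876 for actin at the instrument settings modelled here).
#' @return Corrected [species_counts()] with updated flags.
#' @export
landing_rate_correction <- function(counts, direction = c("upscale",
                                                          "downscale"),
                                    params = diffusion_params(),
                                    monomer_efficiency = 0.876) {
  stopifnot(inherits(counts, "species_counts"))
  direction <- match.arg(direction)
  if (direction == "upscale" && counts$corrected_landing) {
    stop("counts are already landing-rate corrected (upscale refused)")
  }
  if (direction == "downscale" && !counts$corrected_landing) {
    stop("counts are not landing-rate corrected (downscale refused)")
  }
  i <- seq_along(counts$N)
  ratio <- params$D_monomer / diffusion_coefficient(i, params)
  N <- counts$N
  if (direction == "upscale") {
    N <- N * ratio
    N[1] <- N[1] / monomer_efficiency
    species_counts(N, corrected_landing = TRUE,
                   corrected_efficiency = TRUE)
  } else {
    N[1] <- N[1] * monomer_efficiency
    N <- N / ratio
    species_counts(N, corrected_landing = FALSE,
                   corrected_efficiency = FALSE)
  }
}

#' Synthesize a mass-event list from species counts
#'
#' Emits `N_i` particle masses per species: the fitted component mean
#' (or `i * 42` kDa beyond the fitted range) plus zero-mean Gaussian
#' noise with the component's standard deviation; species beyond the
#' fitted range reuse the largest component's SD.
#'
#' @param counts a [species_counts()]; counts are rounded to integers.
#' @param components `data.frame` with `species_index`, `mean`, `sd` for
#'   the fitted species (at least one row).
#' @param seed optional RNG seed for reproducibility.
#' @param monomer_mass subunit mass, kDa.
#' @param time_label_min passed through to the event list.
#' @return A [mass_event_list()].
#' @export
synthesize_mass_events <- function(counts, components, seed = NULL,
                                   monomer_mass = 42,
                                   time_label_min = NA_real_) {
  stopifnot(inherits(counts, "species_counts"))
  if (is.null(components) || nrow(components) == 0) {
    stop("missing component means/SDs and no largest-component fallback")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(counts$N)
  m <- max(components$species_index)
  sd_fallback <- components$sd[which.max(components$species_index)]
  masses <- numeric(0)
  for (i in which(n > 0)) {
    if (i <= m && i %in% components$species_index) {
      row <- components[components$species_index == i, ]
      mu <- row$mean[1]; s <- row$sd[1]
    } else {
      mu <- i * monomer_mass; s <- sd_fallback
    }
    masses <- c(masses, stats::rnorm(n[i], mu, s))
  }
  masses <- masses[masses > 0]   # physical masses only
  mass_event_list(masses, time_label_min = time_label_min)
}

#' Write / read mass-event lists as columnar text
#'
#' CSV with columns `mass_kDa`, `time_min`; one file per time point.
#'
#' @param events a [mass_event_list()].
#' @param path file path.
#' @return `path` (write) or a [mass_event_list()] (read).
#' @export
write_mass_events <- function(events, path) {
  stopifnot(inherits(events, "mass_event_list"))
  utils::write.csv(
    data.frame(mass_kDa = events$masses,
               time_min = events$time_label_min),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mass_events
#' @export
read_mass_events <- function(path) {
  df <- utils::read.csv(path)
  mass_event_list(df$mass_kDa, time_label_min = df$time_min[1])
}
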