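test_that("Gaussian mixture fit recovers exact single-peak parameters", {
  x <- seq(2, 82, by = 4)
  hist1 <- data.frame(bin_center_kDa = x,
                      count = 1000 * 4 * dnorm(x, 42, 8))
  fit <- fit_gaussian_mixture(hist1, 1)
  expect_equal(fit$mean, 42, tolerance = 0.02)
  expect_equal(fit$sd, 8, tolerance = 0.02)
  expect_equal(fit$area, 1000, tolerance = 0.02)
})

test_that("Gaussian mixture fit resolves two peaks and their area ratio", {
  x <- seq(2, 130, by = 4)
  y <- 1000 * 4 * dnorm(x, 42, 8) + 400 * 4 * dnorm(x, 84, 9)
  set.seed(2)
  hist2 <- data.frame(bin_center_kDa = x,
                      count = pmax(y + rnorm(length(x), 0, 0.5), 0))
  fit <- fit_gaussian_mixture(hist2, 2)
  expect_equal(fit$area[1] / fit$area[2], 2.5, tolerance = 0.05)
  expect_true(all(diff(fit$mean) > 0))
})

test_that("degenerate histograms are rejected, not fitted", {
  empty <- data.frame(bin_center_kDa = numeric(0), count = numeric(0))
  expect_error(fit_gaussian_mixture(empty, 2), "empty")
  zeroed <- data.frame(bin_center_kDa = 1:10, count = rep(0, 10))
  expect_error(fit_gaussian_mixture(zeroed, 2), "empty")
  good <- data.frame(bin_center_kDa = seq(2, 82, 4),
                     count = dnorm(seq(2, 82, 4), 42, 8))
  expect_error(fit_gaussian_mixture(good, 7), "n_components")
})

test_that("event binning uses half-open 42-kDa bins centred on multiples", {
  ev <- mass_event_list(c(42, 84, 84))
  n <- counts_from_events(ev)
  expect_equal(n$N[1:2], c(1, 2))
  # 125.9 kDa lies in the trimer bin [105, 147)
  expect_equal(counts_from_events(mass_event_list(125.9))$N[3], 1)
  # exact midpoint 105.0 goes to the upper (trimer) bin
  expect_equal(counts_from_events(mass_event_list(105))$N[3], 1)
  expect_equal(counts_from_events(mass_event_list(104.999))$N[2], 1)
  # fitted components take over species 1..m; bins tile above them
  comps <- data.frame(species_index = 1:2, mean = c(42, 84),
                      sd = c(8, 8), area = c(10, 4))
  n2 <- counts_from_events(mass_event_list(c(60, 126, 170)), comps)
  expect_equal(n2$N[1:4], c(10, 4, 1, 1))
  bad <- data.frame(species_index = c(1, 3), mean = c(42, 126),
                    sd = c(8, 8), area = c(1, 1))
  expect_error(counts_from_events(ev, bad), "contiguous")
})

test_that("count <-> concentration bookkeeping matches hand evaluation", {
  expect_equal(counts_to_concentrations(species_counts(c(100)), 1), 1)
  conc <- counts_to_concentrations(species_counts(c(50, 25)), 1)
  expect_equal(conc, c(0.5, 0.25))
  expect_error(counts_to_concentrations(species_counts(c(0, 0)), 1),
               "zero total")

  n <- concentrations_to_counts(c(1), 600)
  expect_equal(n$N, 600)
  # equal subunit mass in monomers and trimers
  n2 <- concentrations_to_counts(c(0.3, 0, 0.1), 600)
  expect_equal(n2$N, c(300, 0, 100))
  expect_error(concentrations_to_counts(c(0, 0), 10), "all-zero")
})

test_that("count rounding is half-even and the round trip is exact to 1", {
  # N_subunits / i = 2.5 and 3.5 round to 2 and 4
  n <- concentrations_to_counts(c(3, 2.5), 8)
  expect_equal(n$N, c(3, 2))
  n2 <- concentrations_to_counts(c(1, 3.5), 8)
  expect_equal(n2$N, c(1, 4))

  set.seed(11)
  for (rep in 1:20) {
    counts <- species_counts(rpois(15, lambda = c(500, 100, rep(10, 13))))
    if (counts$N_total == 0) next
    conc <- counts_to_concentrations(counts, total_conc = runif(1, 0.1, 2))
    back <- concentrations_to_counts(conc, counts$N_total)
    expect_true(all(abs(back$N - counts$N) <= 1))
  }
})

test_that("diffusion coefficients follow sphere then rod scaling", {
  expect_equal(diffusion_coefficient(1), 7.9e-7)
  expect_equal(diffusion_coefficient(2), 7.9e-7 * 2^(-1 / 3))
  # independent evaluation of the rod model for the pentamer
  L <- 5 * 2.7e-9; p <- L / 7e-9
  v <- 0.312 + 0.565 / p - 0.1 / p^2
  D5 <- 1.380649e-23 * 293.15 * (log(p) + v) / (3 * pi * 1e-3 * L) * 1e4
  expect_equal(diffusion_coefficient(5), D5)
  expect_equal(D5, 3.9e-7, tolerance = 0.02)
  # strictly decreasing within each regime
  expect_true(all(diff(diffusion_coefficient(1:4)) < 0))
  expect_true(all(diff(diffusion_coefficient(5:100)) < 0))
  expect_error(diffusion_params(viscosity_Pa_s = -1), "positive")
  expect_error(diffusion_coefficient(0), ">= 1")
})

test_that("landing-rate correction is an exact inverse pair with flag guards", {
  counts <- species_counts(c(1000, 100, 30, 10, 5))
  up <- landing_rate_correction(counts, "upscale")
  expect_equal(up$N[1], 1000 / 0.876 * 1)
  expect_equal(up$N[4], 10 * 4^(1 / 3))
  expect_true(up$corrected_landing)
  down <- landing_rate_correction(up, "downscale")
  expect_equal(down$N, counts$N, tolerance = 1e-12)
  expect_false(down$corrected_landing)
  expect_error(landing_rate_correction(up, "upscale"), "already")
  expect_error(landing_rate_correction(counts, "downscale"), "not")
  # zero species stay zero
  expect_equal(which(up$N > 0), which(counts$N > 0))
})

test_that("mass-event synthesis is seeded, centred and noiseless at sd 0", {
  comps <- data.frame(species_index = 1:2, mean = c(42, 84),
                      sd = c(0, 0))
  ev <- synthesize_mass_events(species_counts(c(5, 3)), comps)
  expect_equal(sort(ev$masses), c(rep(42, 5), rep(84, 3)))

  comps8 <- data.frame(species_index = 1, mean = 42, sd = 8)
  a <- synthesize_mass_events(species_counts(1e5), comps8, seed = 3)
  b <- synthesize_mass_events(species_counts(1e5), comps8, seed = 3)
  expect_identical(a$masses, b$masses)
  expect_equal(mean(a$masses), 42, tolerance = 3 * 8 / sqrt(1e5) / 42)
  # species beyond the fitted range reuse the largest component's SD
  ev3 <- synthesize_mass_events(species_counts(c(0, 0, 0, 10)), comps8,
                                seed = 4)
  expect_equal(length(ev3$masses), 10)
  expect_equal(mean(ev3$masses), 4 * 42, tolerance = 0.2)
  expect_error(synthesize_mass_events(species_counts(5),
                                      data.frame()[0, ]), "fallback")
})

test_that("simulate -> counts -> events -> counts -> concentrations loop closes", {
  pre <- fixture_presets()$atp_hydrolysis_900nM
  model <- build_two_state_model(pre$rates, 400, total_conc = 0.9)
  dist <- integrate_model(model, seq(0, 900, 300))
  conc <- species_totals(dist)[4, ]
  truth_frac <- conc * seq_along(conc) / 0.9

  n_events <- 2e4
  solution_counts <- concentrations_to_counts(conc, n_events,
                                              round_counts = FALSE)
  solution_counts$corrected_landing <- TRUE
  solution_counts$corrected_efficiency <- TRUE
  detected <- landing_rate_correction(solution_counts, "downscale")
  set.seed(27)
  draws <- rmultinom(1, n_events, detected$N / sum(detected$N))[, 1]
  comps <- data.frame(species_index = 1:3, mean = 42 * (1:3), sd = 8)
  ev <- synthesize_mass_events(species_counts(draws), comps, seed = 27)
  rec <- mp_recover_fractions(ev, 0.9, n_species_max = 400)

  expected_events <- round(detected$N)
  check <- which(expected_events >= 100)
  rel_err <- abs(rec$fractions[check] - truth_frac[check]) /
    truth_frac[check]
  expect_lt(max(rel_err), 0.05)
})

test_that("event lists validate masses and round-trip through CSV", {
  expect_error(mass_event_list(c(42, -1)), "> 0")
  expect_error(mass_event_list(c(42, Inf)), "finite")
  ev <- mass_event_list(c(42.5, 84.1), time_label_min = 5)
  path <- tempfile(fileext = ".csv")
  write_mass_events(ev, path)
  back <- read_mass_events(path)
  expect_equal(back$masses, ev$masses)
  expect_equal(back$time_label_min, 5)
})
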