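test_that("zero rates give null dynamics and constant trajectories", {
  set.seed(4)
  st <- abs(rnorm(8, 0.1, 0.05))
  m <- build_single_state_model(zero_rates(), 8,
                                initial_distribution = st)
  expect_equal(model_rhs(m, st), numeric(8))
  d <- quiet_integrate(m, c(0, 10, 100))   # mass parked in the top species
  expect_equal(d$conc_A[3, ], st, tolerance = 1e-10)

  st2 <- abs(rnorm(14, 0.1, 0.05))
  m2 <- build_two_state_model(zero_rates(), 8,
                              initial_distribution = st2)
  expect_equal(model_rhs(m2, st2), numeric(14))
})

test_that("compiled and reference right-hand sides agree along trajectories", {
  set.seed(7)
  for (scheme in c("single_state", "two_state")) {
    rates <- if (scheme == "single_state") equal_rates() else atp_rates()
    n <- 10L
    nst <- if (scheme == "single_state") n else 2L * n - 2L
    init <- abs(rnorm(nst, 0.05, 0.03)) + 1e-3
    build <- if (scheme == "single_state") build_single_state_model
             else build_two_state_model
    model <- build(rates, n, initial_distribution = init)
    t_grid <- seq(0, 5, 0.5)
    compiled <- quiet_integrate(model, t_grid)
    rfun <- function(t, y, p) list(model_rhs(model, y))
    ref <- deSolve::ode(init, t_grid, rfun, NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    got <- cbind(compiled$conc_A,
                 if (scheme == "two_state")
                   compiled$conc_Aprime[, 3:n] else NULL)
    expect_lt(max(abs(got - unname(ref[, -1]))), 1e-7)
  }
})

test_that("monomer-dimer system reproduces the quadratic equilibrium", {
  # k2 = 0 freezes everything above the dimer
  rates <- rate_set(5, 0, 0, 0, 2, 1, 1, 1)
  total <- 0.8
  K <- 5 / 2
  A_eq <- (-1 + sqrt(1 + 8 * K * total)) / (4 * K)   # 2K A^2 + A = total
  m <- build_single_state_model(rates, 6, total_conc = total)
  d <- integrate_model(m, c(0, 2000))
  expect_equal(d$conc_A[2, 1], A_eq, tolerance = 1e-6)
  expect_equal(d$conc_A[2, 2], K * A_eq^2, tolerance = 1e-6)
  # detailed-balance ratio [A2]/[A]^2 = k1/km1
  expect_equal(d$conc_A[2, 2] / d$conc_A[2, 1]^2, K, tolerance = 1e-6)
  # closed-form constructor reduces to the same result
  eq <- equilibrium_single_state(rates, total, 6)
  expect_equal(eq[1], A_eq, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("equal-rate steady state is geometric and is the ODE fixed point", {
  rates <- equal_rates(k = 2, km = 4)    # sub-critical at 0.5 uM
  total <- 0.5
  eq <- equilibrium_single_state(rates, total, 30)
  ratios <- eq[-1] / eq[-30]
  # geometric tail: constant successive ratio (k/km) [A]
  expect_lt(diff(range(ratios)) / ratios[1], 1e-9)
  expect_equal(ratios[5], (2 / 4) * attr(eq, "monomer"),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sum(seq_len(30) * eq), total, tolerance = 1e-9)
  # fixed point of the dynamics
  m <- build_single_state_model(rates, 30,
                                initial_distribution = as.numeric(eq))
  expect_lt(max(abs(model_rhs(m, as.numeric(eq)))), 1e-9)
  # long integration from an all-monomer start converges to it
  m0 <- build_single_state_model(rates, 30, total_conc = total)
  d <- integrate_model(m0, c(0, 5000))
  expect_equal(d$conc_A[2, ], as.numeric(eq), tolerance = 1e-6)
  # sub-uM equal-rate steady state keeps almost all mass below 1 MDa
  eq9 <- equilibrium_single_state(equal_rates(), 0.9, 100)
  frac_1MDa <- sum((24:100) * eq9[24:100]) / 0.9
  expect_lt(frac_1MDa, 0.01)
})

test_that("two-state scheme with the transition off reduces to single-state", {
  rates2 <- rate_set(12.9, 12.9, 12.9, 11.6, 10, 2.2, 2.2, 1.4,
                     k_trans = 0)
  # matched single-state scheme: every step above the trimer uses k3/km3
  rates1 <- rate_set(12.9, 12.9, 12.9, 12.9, 10, 2.2, 2.2, 2.2)
  n <- 40L
  t_grid <- seq(0, 300, 30)
  d2 <- quiet_integrate(build_two_state_model(rates2, n,
                                              total_conc = 0.9), t_grid)
  d1 <- quiet_integrate(build_single_state_model(rates1, n,
                                                 total_conc = 0.9), t_grid)
  expect_lt(max(abs(d2$conc_A - d1$conc_A)), 1e-6)
  expect_equal(max(d2$conc_Aprime), 0)
})

test_that("a fast transition drains the unprimed oligomer pool", {
  rates <- rate_set(5, 5, 5, 10, 2, 2, 2, 0.1, k_trans = 5000)
  d <- quiet_integrate(build_two_state_model(rates, 30,
                                             total_conc = 1), c(0, 200))
  unprimed_oligomers <- sum(d$conc_A[2, 3:30])
  expect_lt(unprimed_oligomers, 1e-6)
  expect_gt(sum(d$conc_Aprime[2, ]), 0.01)
})

test_that("SSA oracle is seed-reproducible with exponential waiting times", {
  rates <- rate_set(2, 0, 0, 0, 0, 0, 0, 0)
  m <- build_single_state_model(rates, 6,
                                initial_distribution = c(1, 0, 0, 0, 0, 0))
  vol <- 2 / (1e-6 * 6.02214076e23)    # 2 monomer copies at 1 uM
  a <- gillespie_oracle(m, t_grid = c(0, 50), volume_L = vol,
                        n_runs = 3, seed = 99)
  b <- gillespie_oracle(m, t_grid = c(0, 50), volume_L = vol,
                        n_runs = 3, seed = 99)
  expect_identical(a$counts, b$counts)
  expect_identical(a$first_event_time, b$first_event_time)
  # single dimerization reaction: waiting time ~ Exp(k1 nA (nA-1) / omega)
  omega <- 1e-6 * 6.02214076e23 * vol
  rate_true <- 2 * 2 * 1 / omega
  w <- vapply(1:400, function(s) {
    gillespie_oracle(m, t_grid = c(0, 1e4), volume_L = vol,
                     seed = 1000 + s)$first_event_time
  }, numeric(1))
  expect_equal(mean(w), 1 / rate_true,
               tolerance = 3 / sqrt(400) * 1.2)
})

test_that("SSA ensemble mean matches the ODE solution within 3 SE", {
  rates <- rate_set(0.5, 0.5, 0.5, 0.5, 0.2, 0.2, 0.2, 0.2)
  n <- 8L
  total <- 1
  m <- build_single_state_model(rates, n, total_conc = total)
  n_mol <- 2e4
  vol <- n_mol / (total * 1e-6 * 6.02214076e23)
  t_grid <- c(0, 1, 3)
  n_runs <- 200L
  ssa <- gillespie_oracle(m, t_grid = t_grid, volume_L = vol,
                          n_runs = n_runs, seed = 5)
  ode <- quiet_integrate(m, t_grid)
  for (ti in 2:3) {
    mean_counts <- colMeans(ssa$counts[, ti, ])
    sd_counts <- apply(ssa$counts[, ti, ], 2, sd)
    expected <- ode$conc_A[ti, ] * ssa$omega
    se <- sd_counts / sqrt(n_runs)
    z <- abs(mean_counts - expected) / pmax(se, 1e-9)
    expect_lt(max(z[sd_counts > 0]), 3)
    expect_true(all(abs(mean_counts - expected)[sd_counts == 0] < 1))
  }
})

test_that("filament metrics follow hand counts and reject zero mass", {
  d <- static_dist(c(0.9, numeric(199)))
  met <- filament_metrics(d)
  expect_equal(met$frac_mass_above_140kDa, c(0, 0))
  expect_equal(met$mean_length, c(1, 1))

  conc <- numeric(200); conc[200] <- 0.9 / 200
  met200 <- filament_metrics(static_dist(conc))
  expect_equal(met200$frac_mass_above_140kDa, c(1, 1))
  expect_equal(met200$frac_mass_above_150mers, c(1, 1))

  # 50/50 subunit mass split dimers (84 kDa) / tetramers (168 kDa)
  conc <- numeric(160); conc[2] <- 0.25; conc[4] <- 0.125
  met24 <- filament_metrics(static_dist(conc))
  expect_equal(met24$frac_mass_above_140kDa[1], 0.5)
  expect_equal(met24$frac_mass_above_150mers[1], 0)

  dz <- static_dist(c(0.9, numeric(199)))
  dz$conc_A[] <- 0
  expect_error(filament_metrics(dz), "zero total")
})

test_that("model construction enforces the scheme preconditions", {
  expect_error(rate_set(-1, 1, 1, 1, 1, 1, 1, 1), "negative")
  expect_error(build_single_state_model(equal_rates(), 4), "n_max")
  expect_error(build_single_state_model(atp_rates(0.3), 10),
               "k_trans")
  expect_error(build_two_state_model(atp_rates(), 3), "n_max")
  expect_error(build_single_state_model(equal_rates(), 8,
                                        total_conc = 1,
                                        initial_distribution = rep(1, 8)),
               "total_conc")
  expect_error(rate_set(12.9, 12, 12.9, 1, 1, 1, 1, 1,
                        interpretation = "atp_hydrolysis"),
               "k1 = k2 = k3")
  m <- build_single_state_model(equal_rates(), 8, total_conc = 1)
  expect_error(integrate_model(m, c(5, 10)), "start at 0")
  expect_error(integrate_model(m, c(0, 0)), "increasing")
})

test_that("trajectories conserve subunit mass and guard the truncation", {
  d <- integrate_model(build_two_state_model(atp_rates(), 400,
                                             total_conc = 0.9),
                       seq(0, 900, 30))
  expect_lt(d$mass_conservation_error, 1e-6)
  # tiny n_max at high drive leaves mass stuck in the absorbing species
  expect_warning(
    integrate_model(build_two_state_model(atp_rates(), 6,
                                          total_conc = 2), c(0, 600)),
    "absorbing top species")
})

test_that("140-kDa mass fraction is monotone in total actin concentration", {
  fr <- vapply(c(0.12, 0.3, 0.9, 2), function(conc) {
    d <- quiet_integrate(build_two_state_model(atp_rates(), 200,
                                               total_conc = conc),
                         c(0, 900))
    filament_metrics(d)$frac_mass_above_140kDa[2]
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})
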