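test_that("joint negative log-likelihood matches hand evaluation", {
  y <- c(1, 2, 3)
  mk <- function(f) likelihood_config(list(list(
    label = "BLS", y = y, f = f, sigma2 = 1)))
  # zero residuals, sigma = 1, N = 3 -> 3 ln 2pi
  expect_equal(joint_neg_log_likelihood(0, mk(function(th) y)),
               3 * log(2 * pi))
  # quadratic scaling: doubling residuals adds 3x the residual term
  f1 <- function(th) y + 0.1
  f2 <- function(th) y + 0.2
  base <- 3 * log(2 * pi)
  r1 <- joint_neg_log_likelihood(0, mk(f1)) - base
  r2 <- joint_neg_log_likelihood(0, mk(f2)) - base
  expect_equal(r2, 4 * r1)
  # additivity over datasets
  cfg2 <- likelihood_config(list(
    list(label = "BLS", y = y, f = f1, sigma2 = 1),
    list(label = "MP", y = y, f = f2, sigma2 = 4)))
  expect_equal(joint_neg_log_likelihood(0, cfg2),
               joint_neg_log_likelihood(0, mk(f1)) +
                 joint_neg_log_likelihood(
                   0, likelihood_config(list(list(label = "MP", y = y,
                                                  f = f2, sigma2 = 4)))))
  # failed forward evaluation rejects the sample
  expect_equal(joint_neg_log_likelihood(
    0, mk(function(th) stop("boom"))), Inf)
  expect_equal(joint_neg_log_likelihood(0, mk(function(th) c(NA, 2, 3))),
               Inf)
  expect_error(likelihood_config(list(list(label = "x", y = y,
                                           f = f1, sigma2 = 0))),
               "sigma2")
})

test_that("fixed noise scales reduce the objective to weighted least squares", {
  y <- rnorm(10)
  sigma2 <- 1740
  cfg <- likelihood_config(list(list(
    label = "BLS", y = y, f = function(th) y + th, sigma2 = sigma2)))
  const <- 2 * 10 * log(sqrt(sigma2)) + 10 * log(2 * pi)
  expect_equal(joint_neg_log_likelihood(0, cfg), const)
  expect_equal(joint_neg_log_likelihood(0.5, cfg),
               const + 10 * 0.25 / (2 * sigma2))
})

test_that("the box prior is flat inside and impassable outside", {
  refs <- c(12.9, 0.3)
  expect_equal(log_prior(refs, refs), 0)
  expect_equal(log_prior(c(-0.1, 0.3), refs), -Inf)
  eps <- 1e-9
  expect_equal(log_prior(c(1e5 * 12.9 - eps, 0.3), refs), 0)
  expect_equal(log_prior(c(1e5 * 12.9 + 1, 0.3), refs), -Inf)
  expect_error(log_prior(c(1, 1), c(1, -2)), "positive")
  expect_error(log_prior(c(1, 1), 1), "one literature reference")
})

test_that("information criteria penalize parameters as defined", {
  ic <- information_criteria(0, k = 9, N = 100)
  expect_equal(ic[["AIC"]], 18)
  expect_equal(information_criteria(0, k = 9, N = exp(9))[["BIC"]], 81)
  ic5 <- information_criteria(-10, k = 5, N = 50)
  ic6 <- information_criteria(-10, k = 6, N = 50)
  expect_true(all(c(ic6[["AIC"]] > ic5[["AIC"]],
                    ic6[["BIC"]] > ic5[["BIC"]])))
  expect_error(information_criteria(0, 3, 0), "N must be")
  expect_error(information_criteria(0, 3, 2), "N > k")
})

test_that("autocorrelation times recover white-noise and AR(1) benchmarks", {
  set.seed(8)
  white <- array(rnorm(4 * 4000), c(4, 4000, 1))
  act <- autocorrelation_time(white)
  expect_equal(act$tau, 1, tolerance = 0.2)
  expect_true(act$converged)

  phi <- 0.9
  n <- 40000
  x <- as.numeric(stats::filter(rnorm(n), phi, method = "recursive"))
  act1 <- autocorrelation_time(matrix(x, ncol = 1))
  expect_equal(act1$tau, (1 + phi) / (1 - phi), tolerance = 0.25)

  const <- array(1, c(2, 500, 1))
  actc <- autocorrelation_time(const)
  expect_true(is.na(actc$tau))
  expect_false(actc$converged)
})

test_that("ensemble sampler is exact on a correlated Gaussian target", {
  S <- matrix(c(1, 0.6, 0.6, 2), 2)
  Si <- solve(S)
  mu <- c(3, -2)
  lp <- function(x) -0.5 * drop(t(x - mu) %*% Si %*% (x - mu))
  res <- run_ensemble_mcmc(lp, n_walkers = 32, n_steps = 4000,
                           init = mu, init_ball_frac = 0.5, seed = 42)
  flat <- matrix(aperm(res$chains[, -(1:500), , drop = FALSE],
                       c(2, 1, 3)), ncol = 2)
  expect_equal(colMeans(flat), mu, tolerance = 0.05)
  expect_equal(unname(cov(flat)), S, tolerance = 0.05)
  expect_true(all(res$acceptance_fraction > 0.1))
  expect_true(all(res$converged))
})

test_that("chains are seed-reproducible and invariant to likelihood offsets", {
  lp <- function(x) -0.5 * sum(x^2)
  a <- run_ensemble_mcmc(lp, 12, 200, init = c(0, 0), seed = 9)
  b <- run_ensemble_mcmc(lp, 12, 200, init = c(0, 0), seed = 9)
  expect_identical(a$chains, b$chains)
  # posterior ~ likelihood x prior: a constant shift cancels in the
  # acceptance ratio and leaves trajectories unchanged
  c_ <- run_ensemble_mcmc(function(x) lp(x) + 7.25, 12, 200,
                          init = c(0, 0), seed = 9)
  expect_equal(a$chains, c_$chains, tolerance = 1e-12)
  expect_error(run_ensemble_mcmc(lp, 6, 10, init = c(0, 0), seed = 1),
               "n_walkers")
})

test_that("walkers never initialize outside the prior support", {
  refs <- c(1, 1)
  lp <- function(x) {
    pr <- log_prior(x, refs, bound_factor = 1.05)
    if (!is.finite(pr)) return(-Inf)
    -0.5 * sum((x - 1)^2)
  }
  res <- run_ensemble_mcmc(lp, 12, 50, init = refs,
                           init_ball_frac = 0.5, seed = 13)
  expect_true(all(is.finite(res$log_posterior[, 1])))
})

test_that("corner data are normalized marginals with sane symmetry", {
  set.seed(14)
  chains <- array(rnorm(8 * 2000 * 2), c(8, 2000, 2))
  cd <- corner_data(chains, burn_in = 100, bins = 25)
  for (m in cd$marginals) expect_equal(sum(m$density), 1)
  pair <- cd$pairs[[1]]
  expect_equal(sum(pair$density), 1)
  # isotropic target: x and y marginals of the 2-D histogram agree
  expect_lt(max(abs(rowSums(pair$density) - colSums(pair$density))), 0.05)
  expect_error(corner_data(chains, burn_in = 2000), "burn_in")
  expect_error(corner_data(chains, bins = 1), "bins")
})
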