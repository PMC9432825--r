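#' Assemble a joint likelihood configuration
#'
#' Pairs observed datasets with their forward models for the joint
#' Gaussian likelihood. Each dataset is a list with elements `label`
#' (e.g. `"BLS"` or `"MP"`), `y` (numeric observations), `f` (function
#' of the parameter vector returning predictions of the same length) and
#' `sigma2` (noise-scale parameter of that technique).
#'
#' The per-technique noise scales act as relative weights between the
#' techniques; by default they are held fixed (the values the sampler
#' converges to track the approximate experimental noise variance:
#' about 1740 squared arbitrary units for bulk light scattering, about
#' 0.003 for mass-photometry histograms).
#'
#' @param datasets list of dataset descriptors (see Details).
#' @param objective `"gaussian"` for the joint Gaussian form, or
#'   `"neyman"` for a Neyman chi-squared weighting of count data
#'   (per-point variance `max(y, 1)` replacing `sigma2`).
#' @param fixed_sigma logical; kept as metadata (when `FALSE`, callers
#'   may append `sigma2` entries to the sampled parameter vector).
#' @return A `"likelihood_config"`.
#' @export
likelihood_config <- function(datasets, objective = c("gaussian", "neyman"),
                              fixed_sigma = TRUE) {
  objective <- match.arg(objective)
  for (d in datasets) {
    if (!all(c("label", "y", "f", "sigma2") %in% names(d))) {
      stop("each dataset needs label, y, f and sigma2")
    }
    if (d$sigma2 <= 0) stop("sigma2 must be > 0 (dataset ", d$label, ")")
    if (!is.function(d$f)) stop("f must be a function of theta")
  }
  structure(list(datasets = datasets, objective = objective,
                 fixed_sigma = fixed_sigma,
                 n_data = sum(vapply(datasets,
                                     function(d) length(d$y), numeric(1)))),
            class = "likelihood_config")
}

#' Joint negative log-likelihood over all datasets
#'
#' Evaluates, for each technique `j`,
#' `2 N_j ln sigma_j + N_j ln 2pi + sum_i (y_ij - f_ij(theta))^2 /
#' (2 sigma_j^2)` and sums over techniques. A failed or non-finite
#' forward evaluation maps to `+Inf` (the sample is rejected) and is
#' tallied in the attribute `"n_failed"` of the returned closure
#' environment when used through [run_ensemble_mcmc()].
#'
#' @param theta numeric parameter vector passed to each forward model.
#' @param cfg a [likelihood_config()].
#' @return Scalar negative log-likelihood (possibly `Inf`).
#' @export
joint_neg_log_likelihood <- function(theta, cfg) {
  stopifnot(inherits(cfg, "likelihood_config"))
  total <- 0
  for (d in cfg$datasets) {
    fj <- tryCatch(suppressWarnings(d$f(theta)), error = function(e) NULL)
    if (is.null(fj) || length(fj) != length(d$y) || any(!is.finite(fj))) {
      return(Inf)
    }
    r2 <- (d$y - fj)^2
    nj <- length(d$y)
    if (cfg$objective == "neyman") {
      v <- pmax(d$y, 1)
      total <- total + sum(log(v)) + nj * log(2 * pi) + sum(r2 / (2 * v))
    } else {
      total <- total + 2 * nj * log(sqrt(d$sigma2)) + nj * log(2 * pi) +
        sum(r2) / (2 * d$sigma2)
    }
  }
  total
}

#' Uniform box prior anchored at literature rate constants
#'
#' Uninformative prior: uniform on `[0, bound_factor * reference]` per
#' fitted component, i.e. log-density 0 inside the box and `-Inf`
#' outside. The box bounds the parameter space to a physically plausible
#' region around previously published values.
#'
#' @param theta numeric parameter vector.
#' @param literature_refs positive reference value per component.
#' @param bound_factor upper bound multiplier (default 1e5).
#' @return 0 or `-Inf`.
#' @export
log_prior <- function(theta, literature_refs, bound_factor = 1e5) {
  if (length(literature_refs) != length(theta)) {
    stop("need one literature reference value per fitted component")
  }
  if (any(!is.finite(literature_refs)) || any(literature_refs <= 0)) {
    stop("literature reference values must be positive")
  }
  if (any(theta < 0) || any(theta > bound_factor * literature_refs)) {
    return(-Inf)
  }
  0
}

#' Affine-invariant ensemble MCMC with differential-evolution moves
#'
#' Evolves an ensemble of walkers under a mixture of the
#' differential-evolution move (default 80% probability) and the snooker
#' move (20%), both proposed from the complementary half of the
#' ensemble, which makes the sampler invariant under affine rescalings
#' of parameter space. Walkers start in a Gaussian ball around `init`
#' and are never initialized outside the prior support.
#'
#' @param log_posterior function of the parameter vector returning the
#'   log posterior density (may be `-Inf`).
#' @param n_walkers ensemble size; must exceed `2 * dim + 2`.
#' @param n_steps number of ensemble steps to record.
#' @param init numeric vector: ball centre (e.g. published rate
#'   constants).
#' @param move_mix named vector of move probabilities,
#'   `c(de = 0.8, snooker = 0.2)`.
#' @param init_ball_frac relative SD of the initial Gaussian ball.
#' @param seed RNG seed; chains are reproducible given the seed.
#' @param stall_horizon error out if no walker accepts any move over
#'   this many consecutive steps.
#' @param log_likelihood optional function returning the log-likelihood
#'   (without prior); enables AIC/BIC in the result.
#' @param n_data total number of data points `N` for the BIC penalty.
#' @return An `"inference_result"`: `chains` (array walkers x steps x
#'   dim), `log_posterior` (walkers x steps), `acceptance_fraction`,
#'   `tau` (integrated autocorrelation times), `converged` flags,
#'   `AIC`/`BIC` (when computable), `seed`, `move_mix`.
#' @export
run_ensemble_mcmc <- function(log_posterior, n_walkers, n_steps, init,
                              move_mix = c(de = 0.8, snooker = 0.2),
                              init_ball_frac = 0.01, seed = NULL,
                              stall_horizon = 100L,
                              log_likelihood = NULL, n_data = NULL) {
  d <- length(init)
  if (n_walkers <= 2 * d + 2) {
    stop("n_walkers must exceed 2 * dim + 2 = ", 2 * d + 2)
  }
  if (!is.null(seed)) set.seed(seed)
  move_mix <- move_mix / sum(move_mix)

  # initialize inside the prior support
  X <- matrix(NA_real_, n_walkers, d)
  lp <- numeric(n_walkers)
  for (k in seq_len(n_walkers)) {
    for (try in 1:1000) {
      x <- init * (1 + init_ball_frac * stats::rnorm(d))
      v <- log_posterior(x)
      if (is.finite(v)) break
    }
    if (!is.finite(v)) {
      stop("could not initialize walker ", k, " inside the prior support")
    }
    X[k, ] <- x
    lp[k] <- v
  }

  chains <- array(NA_real_, c(n_walkers, n_steps, d))
  lp_store <- matrix(NA_real_, n_walkers, n_steps)
  n_accept <- numeric(n_walkers)
  gamma0 <- 2.38 / sqrt(2 * d)
  gamma_snooker <- 1.7
  halves <- list(seq_len(n_walkers %/% 2),
                 (n_walkers %/% 2 + 1):n_walkers)
  stall <- 0L

  for (step in seq_len(n_steps)) {
    accepted_any <- FALSE
    for (h in 1:2) {
      active <- halves[[h]]
      comp <- halves[[3 - h]]
      for (k in active) {
        x <- X[k, ]
        use_snooker <- stats::runif(1) < move_mix[["snooker"]]
        if (!use_snooker) {
          ab <- sample(comp, 2L)
          g <- gamma0 * (1 + 1e-5 * stats::rnorm(1))
          xp <- x + g * (X[ab[1], ] - X[ab[2], ])
          log_mh_corr <- 0
        } else {
          zzz <- sample(comp, 3L)
          z <- X[zzz[1], ]
          e <- x - z
          ne <- sqrt(sum(e^2))
          if (ne < 1e-300) next   # degenerate direction: skip
          ehat <- e / ne
          proj <- sum((X[zzz[2], ] - X[zzz[3], ]) * ehat)
          xp <- x + gamma_snooker * proj * ehat
          np <- sqrt(sum((xp - z)^2))
          if (np < 1e-300) next
          log_mh_corr <- (d - 1) * (log(np) - log(ne))
        }
        lpp <- log_posterior(xp)
        if (is.finite(lpp) &&
            log(stats::runif(1)) < lpp - lp[k] + log_mh_corr) {
          X[k, ] <- xp
          lp[k] <- lpp
          n_accept[k] <- n_accept[k] + 1
          accepted_any <- TRUE
        }
      }
    }
    stall <- if (accepted_any) 0L else stall + 1L
    if (stall >= stall_horizon) {
      stop(sprintf(
        "all walkers rejected every move for %d consecutive steps %s%.4g",
        stall, "(sampler stalled); best log posterior so far ", max(lp)))
    }
    chains[, step, ] <- X
    lp_store[, step] <- lp
  }

  act <- autocorrelation_time(chains)
  res <- list(chains = chains, log_posterior = lp_store,
              acceptance_fraction = n_accept / n_steps,
              tau = act$tau, converged = act$converged,
              move_mix = move_mix, seed = seed,
              AIC = NA_real_, BIC = NA_real_,
              max_log_likelihood = NA_real_)
  if (!is.null(log_likelihood)) {
    best <- arrayInd(which.max(lp_store), dim(lp_store))
    theta_hat <- chains[best[1], best[2], ]
    llhat <- log_likelihood(theta_hat)
    res$max_log_likelihood <- llhat
    res$map_estimate <- theta_hat
    if (!is.null(n_data)) {
      ic <- information_criteria(llhat, k = d, N = n_data)
      res$AIC <- ic[["AIC"]]
      res$BIC <- ic[["BIC"]]
    }
  }
  class(res) <- "inference_result"
  res
}

#' @export
print.inference_result <- function(x, ...) {
  dm <- dim(x$chains)
  cat(sprintf(
    "<inference_result> %d walkers x %d steps x %d parameters\n",
    dm[1], dm[2], dm[3]))
  cat(sprintf("  mean acceptance %.2f; tau: %s; converged: %s\n",
              mean(x$acceptance_fraction),
              paste(signif(x$tau, 3), collapse = ", "),
              paste(x$converged, collapse = ", ")))
  if (is.finite(x$AIC)) {
    cat(sprintf("  max lnL %.4g, AIC %.4g, BIC %.4g\n",
                x$max_log_likelihood, x$AIC, x$BIC))
  }
  invisible(x)
}

#' Integrated autocorrelation time of ensemble chains
#'
#' Averages the normalized autocorrelation function over walkers per
#' parameter and integrates it under the self-consistent window rule
#' `M = smallest lag with M >= c * tau(M)` (window constant `c`,
#' default 5). A parameter is flagged unconverged when the chain is
#' shorter than `50 * tau` or its variance is zero.
#'
#' @param chains array walkers x steps x dim (a matrix is treated as a
#'   single-walker chain steps x dim).
#' @param c_window window constant of the truncation rule.
#' @return List with `tau` (per parameter; `NA` where not estimable) and
#'   `converged` (logical per parameter).
#' @export
autocorrelation_time <- function(chains, c_window = 5) {
  if (is.matrix(chains)) {
    chains <- array(t(chains), c(1, nrow(chains), ncol(chains)))
  }
  if (length(dim(chains)) != 3) stop("chains must be walkers x steps x dim")
  nw <- dim(chains)[1]; ns <- dim(chains)[2]; d <- dim(chains)[3]
  tau <- rep(NA_real_, d)
  converged <- rep(FALSE, d)
  for (p in seq_len(d)) {
    acfs <- matrix(0, nw, ns)
    ok <- TRUE
    for (k in seq_len(nw)) {
      x <- chains[k, , p] - mean(chains[k, , p])
      if (sum(x^2) == 0) { ok <- FALSE; break }
      npad <- 2L * stats::nextn(ns, 2)
      fx <- stats::fft(c(x, numeric(npad - ns)))
      ac <- Re(stats::fft(fx * Conj(fx), inverse = TRUE))[seq_len(ns)]
      acfs[k, ] <- ac / ac[1]
    }
    if (!ok) next
    rho <- colMeans(acfs)
    tau_run <- 2 * cumsum(rho) - 1    # tau(M) = 1 + 2 sum_{1..M} rho_t
    m <- which(seq_len(ns) >= c_window * tau_run)
    tau[p] <- if (length(m)) max(tau_run[m[1]], 1e-8) else tau_run[ns]
    converged[p] <- length(m) > 0 && ns >= 50 * tau[p]
  }
  list(tau = tau, converged = converged)
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = 2k - 2 ln L_hat`, `BIC = k ln N - 2 ln L_hat` with `k` fitted
#' parameters, `N` data points and `L_hat` the maximum likelihood.
#'
#' @param max_log_likelihood maximum log-likelihood found.
#' @param k number of fitted parameters, `>= 1`.
#' @param N number of data points, `> k`.
#' @return Named vector `c(AIC, BIC)`.
#' @export
information_criteria <- function(max_log_likelihood, k, N) {
  if (N <= 0) stop("N must be > 0")
  if (k < 1) stop("k must be >= 1")
  if (N <= k) stop("need more data points than parameters (N > k)")
  c(AIC = 2 * k - 2 * max_log_likelihood,
    BIC = k * log(N) - 2 * max_log_likelihood)
}

#' One- and two-dimensional marginal histograms of the posterior
#'
#' Computes corner-plot data: normalized 1-D marginal histograms per
#' parameter and normalized 2-D histograms per parameter pair after
#' burn-in removal. The global density maxima across the 2-D planes
#' locate the maximum-likelihood region.
#'
#' @param chains array walkers x steps x dim.
#' @param burn_in steps discarded from the front of every walker.
#' @param bins number of histogram bins per axis, `>= 2`.
#' @param param_names optional parameter names.
#' @return List with `marginals` (per parameter: `breaks`, `mids`,
#'   `density` summing to 1) and `pairs` (per pair: `x_mids`, `y_mids`,
#'   `density` matrix summing to 1).
#' @export
corner_data <- function(chains, burn_in = 0L, bins = 30L,
                        param_names = NULL) {
  if (length(dim(chains)) != 3) stop("chains must be walkers x steps x dim")
  ns <- dim(chains)[2]; d <- dim(chains)[3]
  if (bins < 2) stop("bins must be >= 2")
  if (burn_in >= ns) stop("burn_in must be smaller than the chain length")
  keep <- (burn_in + 1L):ns
  if (is.null(param_names)) param_names <- paste0("theta", seq_len(d))
  flat <- matrix(aperm(chains[, keep, , drop = FALSE], c(2, 1, 3)),
                 ncol = d)
  colnames(flat) <- param_names
  marg <- vector("list", d)
  names(marg) <- param_names
  brk <- vector("list", d)
  for (p in seq_len(d)) {
    rng <- range(flat[, p])
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    brk[[p]] <- seq(rng[1], rng[2], length.out = bins + 1L)
    cnt <- tabulate(findInterval(flat[, p], brk[[p]],
                                 rightmost.closed = TRUE),
                    nbins = bins)
    marg[[p]] <- list(breaks = brk[[p]],
                      mids = (brk[[p]][-1] + brk[[p]][-(bins + 1)]) / 2,
                      density = cnt / sum(cnt))
  }
  pairs <- list()
  if (d >= 2) {
    for (p in 1:(d - 1)) for (q in (p + 1):d) {
      ix <- findInterval(flat[, p], brk[[p]], rightmost.closed = TRUE)
      iy <- findInterval(flat[, q], brk[[q]], rightmost.closed = TRUE)
      h2 <- matrix(tabulate((iy - 1L) * bins + ix, nbins = bins * bins),
                   bins, bins)
      pairs[[paste(param_names[p], param_names[q], sep = ":")]] <-
        list(x_mids = marg[[p]]$mids, y_mids = marg[[q]]$mids,
             density = h2 / sum(h2))
    }
  }
  list(marginals = marg, pairs = pairs, n_samples = nrow(flat))
}
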