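# Parameter-recovery experiment used by the inference tests: generate a
# synthetic MP dataset in the slow-transition regime resolvable by the
# {1,5,10,15}-min acquisition grid, run the analysis chain, and fit
# (km1, k_trans) with the ensemble sampler.

recovery_truth <- c(km1 = 10, k_trans = 0.005)

recovery_preset <- function() {
  fixture_presets(k_hydr = recovery_truth[["k_trans"]],
                  km1 = recovery_truth[["km1"]])$atp_hydrolysis_900nM
}

# MP noise scale on the subunit-mass-fraction scale at ~1000-3000
# events per video (multinomial sampling plus heavy-tail weight noise)
recovery_sigma2 <- 2e-4

recovery_replicate <- function(seed, n_steps = 500, n_walkers = 16,
                               burn_in = 200, n_species = 8,
                               preset = recovery_preset(),
                               truth = recovery_truth) {
  mp <- generate_mp_dataset(preset, seed = seed)
  y <- unlist(lapply(mp$events, function(e) {
    mp_recover_fractions(e, preset$total_conc,
                         n_species_max = preset$n_max)$fractions[
                           seq_len(n_species)]
  }))
  fm <- mp_forward_model(preset$scheme, preset$rates,
                         names(truth), 50, preset$total_conc,
                         preset$time_points_min * 60, n_species,
                         solver_config = fast_solver)
  lcfg <- likelihood_config(list(list(label = "MP", y = y, f = fm,
                                      sigma2 = recovery_sigma2)))
  loglik <- function(th) -joint_neg_log_likelihood(th, lcfg)
  lpost <- function(th) {
    lp <- log_prior(th, truth)
    if (!is.finite(lp)) return(-Inf)
    lp + loglik(th)
  }
  res <- run_ensemble_mcmc(lpost, n_walkers, n_steps, init = truth,
                           seed = seed, log_likelihood = loglik,
                           n_data = lcfg$n_data)
  flat <- matrix(aperm(res$chains[, -seq_len(burn_in), , drop = FALSE],
                       c(2, 1, 3)), ncol = length(truth))
  ci <- apply(flat, 2, stats::quantile, c(0.025, 0.975))
  colnames(ci) <- names(truth)
  list(ci = ci, cover = truth >= ci[1, ] & truth <= ci[2, ],
       result = res, y = y, lcfg = lcfg)
}
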