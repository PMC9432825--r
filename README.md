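# polymerkin

Kinetic modelling and Bayesian inference for actin polymerization, built
around single-particle mass photometry and bulk light scattering.

## The problem

Bulk measurements of actin assembly show the classic sigmoidal
"nucleated growth" signature, but single-particle mass photometry (MP)
reveals substantial steady-state pools of small oligomers at all times —
incompatible with models in which a rare, unstable nucleus limits
growth. `polymerkin` implements and compares two kinetic hypotheses:

* a **single-state nucleation–elongation scheme**: stepwise assembly
  `A₁ ⇌ A₂ ⇌ … ⇌ Aₙ` with constants `k₁/k₋₁` (dimer), `k₂/k₋₂`
  (trimer), `k₃/k₋₃` (tetramer) and `k₄/k₋₄` for all further steps;
* a **two-state (slow transition) scheme**: oligomers of trimer size
  and above convert irreversibly at rate `k_trans` into a kinetically
  stabilized state `A′` with its own constants `k₄/k₋₄`. `k_trans` is
  interpreted as the filament ATP hydrolysis rate (pointed-end
  stabilization by ADP-Pᵢ) or as the Ca²⁺→Mg²⁺ activation rate.

Both schemes are well-mixed ODE systems in the species concentrations
`[A_i]` (µM), integrated with a compiled right-hand side and an
absorbing largest species that keeps subunit mass exactly conserved.
Around the kinetic core the package provides:

* an exact Gillespie stochastic simulation oracle and a closed-form
  detailed-balance steady state, as independent checks of the ODEs;
* conversions between species concentrations and detected-particle
  counts: Gaussian-mixture decomposition of resolved low-mass peaks,
  42-kDa binning above them, diffusion-dependent landing-rate
  corrections (sphere scaling up to the tetramer, Tirado–García de la
  Torre rods above) and the 0.876 monomer detection efficiency;
* the squared-mass light-scattering forward model
  `signal = s · Σ_{i≥sds} i² [A_i]` with detection floor `sds`;
* a joint Gaussian likelihood over both observables, affine-invariant
  ensemble MCMC (differential-evolution + snooker moves),
  autocorrelation-time convergence diagnostics and AIC/BIC model
  comparison;
* a synthetic-data generator producing MP event lists and scattering
  traces with known ground truth, so the entire analysis chain is
  testable end to end.

## Worked example

Simulate 900 nM actin with the ATP-hydrolysis parameterization, then
generate a synthetic MP experiment at the experimental event totals and
run the analysis chain on it:

```r
library(polymerkin)

pre <- fixture_presets()$atp_hydrolysis_900nM
print(pre$rates)
#> <rate_set> interpretation: atp_hydrolysis
#>   association  k1..k4  : 12.9 12.9 12.9 11.6  uM^-1 s^-1
#>   dissociation km1..km4: 10 2.2 2.2 1.4  s^-1
#>   transition   k_trans : 0.3  s^-1

model <- build_two_state_model(pre$rates, n_max = 400, total_conc = 0.9)
traj <- integrate_model(model, seq(0, 900, by = 30))
filament_metrics(traj)[c(3, 11, 31), ]
#>    time_s frac_mass_above_140kDa frac_mass_above_150mers mean_length
#> 3      60                 0.8089                       0      4.4499
#> 11    300                 0.8119                       0      4.6069
#> 31    900                 0.8120                       0      4.6165
```

At 900 nM, 81% of the actin mass ends up in species heavier than
140 kDa within the 15-min window; the same run at 120 nM stays below
18% (the critical-concentration contrast). Now the synthetic MP round
trip — generate events, decompose the low-mass peaks, correct for
landing rates and detection efficiency, and compare with the generating
trajectory:

```r
pre$target_events <- c(9000, 29314, 14211, 19668)
mp <- generate_mp_dataset(pre, seed = 1)
rec <- mp_recover_fractions(mp$events$t15min, total_conc = 0.9,
                            n_species_max = 400)
round(rec$components, 2)
#>   species_index   mean   sd     area
#> 1             1  42.08 8.11 13507.47
#> 2             2  84.01 7.69  1688.38
#> 3             3 125.36 7.40  1008.94
```

The fitted Gaussian components sit at 42, 84 and 125 kDa with ~8-kDa
peak widths; their areas are the monomer/dimer/trimer event counts.
The recovered subunit-mass fractions match the generating trajectory:

```r
#>            species_1 species_2 species_3 species_4
#> generating    0.1195    0.0332    0.0352    0.0358
#> recovered     0.1200    0.0331    0.0340    0.0367
```

For fitting, `mp_forward_model()` / `scattering_forward_model()` map a
vector of rate constants onto these observables, `likelihood_config()`
assembles the joint objective and `run_ensemble_mcmc()` samples the
posterior; `cmd_simulate()`, `cmd_scatter()`, `cmd_fit()` and
`cmd_scan()` orchestrate whole runs from YAML configs (a thin CLI
wrapper ships in `inst/cli/polymerkin.R`). The methods vignette
(`vignettes/polymerization-kinetics.Rmd`) documents the model
equations, parameter provenance and numerical choices.

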