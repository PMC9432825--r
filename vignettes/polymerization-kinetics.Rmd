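---
title: "Modelling actin polymerization kinetics with polymerkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling actin polymerization kinetics with polymerkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Classical descriptions of actin filament formation postulate a
nucleation barrier: an unstable oligomeric nucleus whose rare formation
limits the onset of polymer growth. Single-particle mass measurements of
polymerizing actin, however, show substantial steady-state pools of
small oligomers at all times — hard to reconcile with kinetically labile
nuclei. An alternative reading is that filament growth is gated not by
nucleation but by a slow, irreversible transition of oligomers into a
kinetically stabilized state, driven by ATP hydrolysis at the filament's
pointed end or by Ca^2+^ to Mg^2+^ exchange on the actin surface.

`polymerkin` implements the machinery needed to compare these two
hypotheses quantitatively: deterministic kinetic models of both schemes,
forward models for the two observables (mass-photometry particle counts
and bulk light scattering), a synthetic-data generator with the noise
structure of those observables, and Bayesian inference with
information-criterion model comparison.

## Kinetic schemes

Both schemes track species concentrations $[A_i]$ (oligomers of $i$
subunits, µM) in a well-mixed volume, with association constants in
µM^-1^ s^-1^ and dissociation constants in s^-1^.

**Single-state (nucleation–elongation) scheme.** Stepwise assembly
$A_1 \rightleftharpoons A_2 \rightleftharpoons \dots \rightleftharpoons A_n$
with constants $k_1/k_{-1}$ (dimer), $k_2/k_{-2}$ (trimer), $k_3/k_{-3}$
(tetramer) and $k_4/k_{-4}$ for every further step. The monomer balance
carries a stoichiometric factor 2 on the dimerization terms
($-2k_1[A]^2 + 2k_{-1}[A_2]$). The largest simulated species $n$ is
absorbing: it has no flux to $n+1$, which keeps total subunit mass
exactly conserved under truncation.

**Two-state (slow transition) scheme.** Oligomers of trimer size and
above additionally convert, irreversibly and at rate $k_\mathrm{trans}$,
into a primed state $A'_i$ with its own constants $k_4/k_{-4}$:

* unprimed pathway: $k_1/k_{-1}$, $k_2/k_{-2}$, then $k_3/k_{-3}$ for
  *every* step above the trimer;
* primed pathway: $A'_i + A \rightleftharpoons A'_{i+1}$ with
  $k_4/k_{-4}$;
* the primed trimer dissociates into a dimer and a monomer at $k_{-4}$,
  with no reverse reaction — the published equation set is asymmetric
  here and is implemented verbatim;
* at $t_0$ all species start unprimed (polymerization is induced at
  time zero).

In the ATP-hydrolysis reading, $k_1..k_3 = 12.9$ µM^-1^ s^-1^ is the sum
of the published barbed (11.6) and pointed (1.3) end association rates
of Mg-ATP-actin and $k_{-2} = k_{-3} = 2.2$ s^-1^ the summed
dissociation rates; $k_\mathrm{trans}$ is the filament ATPase rate
$k_\mathrm{hydr}$. For the primed (pointed-end-stabilized) pathway the
package uses the barbed-end-only values $k_4 = 11.6$ µM^-1^ s^-1^,
$k_{-4} = 1.4$ s^-1^. This is a deliberate design choice: the mechanism
is stabilization of the pointed end by the ADP-P~i~ subunit, so the
primed state must carry a more favourable equilibrium than the unprimed
one — with identical rates in both rows the transition would be
observable only as a relabeling and $k_\mathrm{trans}$ would have no
effect on any observable. The ratio $1.4/11.6 = 0.121$ µM also
reproduces the well-known ~120 nM critical concentration for filament
growth. In the cation-exchange reading the unprimed row carries the
published Ca-actin sums (10.6 / 5.0) and the primed row the Mg-actin
sums (12.9 / 2.2), with $k_\mathrm{trans}$ the Ca→Mg activation rate.

Three constants are not available in published form and are therefore
explicit configuration fields with documented defaults and provenance
strings: the dimer dissociation rate $k_{-1}$ (default 10 s^-1^, an
order-of-magnitude placeholder and a primary target of parameter
recovery), $k_\mathrm{hydr}$ (default 0.3 s^-1^, the canonical filament
ATPase rate) and the cation activation rate (default 0.02 s^-1^).

With these defaults the model reproduces the qualitative phenomenology
the schemes were built to explain: abundant fast-equilibrating small
oligomers; strong growth of >140-kDa mass at 900 nM and weak growth at
120 nM; no long filaments without the transition (the equal-free-energy
ladder equilibrates to an approximately geometric oligomer distribution);
suppressed >150-mer formation at 2 µM when $k_\mathrm{hydr} = 0$ even
with a five-fold faster barbed end; and a drop in apparent critical
concentration when the barbed-end rate is raised.

## Numerical integration

`integrate_model()` uses deSolve with the scheme right-hand sides
compiled in C (`lsoda` below 200 state variables, `lsodes` with an
internally generated sparse Jacobian above). Defaults: `rtol = 1e-8`,
`atol = 1e-13` µM. Rationale: rate constants span four or more orders of
magnitude, so a stiff-capable implicit method is required; the `atol`
floor sits an order of magnitude below the negativity guard so that
integrator noise below $-10^{-12}$ µM is treated as an error rather than
silently clipped (noise in $(-10^{-12}, 0)$ is clipped to zero on
export). Total subunit mass must be conserved to $10^{-6}$ relative over
the whole trajectory or the integration errors out. A warning fires when
more than 0.1% of mass accumulates in the absorbing top species
(truncation artifact guard). Default truncation sizes follow the two use
cases: $n = 400$ for mass-photometry comparisons and $n = 2000$ for
scattering simulations.

Two independent oracles validate the deterministic core: a pure-R
implementation of the right-hand sides (`model_rhs()`), and an exact
Gillespie stochastic simulation (`gillespie_oracle()`, C) over the same
reaction network, whose ensemble mean must agree with the ODE solution
within Monte-Carlo error on small instances. The closed-form
detailed-balance steady state (`equilibrium_single_state()`) provides a
third, algebraic anchor for the single-state scheme.

## Mass-photometry observables

Mass photometry yields lists of single-particle masses. The package
converts between event lists and species concentrations through:

* **Gaussian mixture decomposition** of the resolved low-mass peaks
  (means constrained to ±25% of multiples of 42 kDa, SDs in (2, 30)
  kDa); the area under each component is that species' count.
  Decomposition rather than naive binning matters quantitatively: with
  8-kDa peaks, ~0.4% of the large monomer peak falls into the dimer
  bin, which is a substantial relative error on the much smaller dimer
  count.
* **42-kDa binning** for heavier, unresolved species, with half-open
  bins $[42i - 21, 42i + 21)$ — boundary events go to the upper bin
  (the published procedure states the spacing but not the edge
  convention).
* **Count bookkeeping**: subunit-weighted counts
  $N_{\mathrm{sub},i} = N_i \, i$ distribute the known total
  concentration; the reverse map rounds $N_{\mathrm{sub},i}/i$ with R's
  round-half-even rule. Primed and unprimed species are summed before
  conversion — the two states are indistinguishable by mass.
* **Landing-rate correction**: landing frequency scales with the
  diffusion coefficient, so detected counts are multiplied by
  $D_\mathrm{monomer}/D_i$ ("upscale") or divided ("downscale").
  Species up to the tetramer are treated as spheres,
  $D_i = D_1 i^{-1/3}$ with $D_1 = 7.9\times10^{-7}$ cm^2^ s^-1^;
  larger species as rigid rods of diameter 7 nm and length
  $i \times 2.7$ nm with the Tirado–García de la Torre formula
  $D = k_BT(\ln p + v)/(3\pi\eta L)$, $p = L/d$,
  $v = 0.312 + 0.565/p - 0.1/p^2$ (20 °C, water). The small sphere/rod
  discontinuity at $i = 4 \to 5$ is kept as published, not smoothed.
  Correction state is tracked by flags and double application is
  refused.
* **Detection efficiency**: monomers approach the instrument's
  detection limit; their counts are divided by the measured monomer
  true-positive efficiency 0.876. The published dimer efficiency (95%)
  is close enough to unity that no correction is applied there — the
  same choice as in the original analysis, and configurable.

## Bulk light scattering

The scattering contribution of an oligomer scales with concentration
times squared mass: the forward model is
$\mathrm{signal}(t) = s \sum_{i=\mathrm{sds}}^{n} i^2 [A_i](t)$, with a
detection floor `sds` (smallest detectable species; default 30 subunits,
an optimization parameter when fitting) and scale $s$. Simulated traces
are mapped onto experimental ones by matching the mean start and end
levels (default 10-point edge windows; the published procedure names the
levels but not a window length). The map is affine by default with a
pure-scale mode available, since the published text does not say whether
an offset was included.

## Synthetic data

`generate_mp_dataset()` inverts the analysis chain: integrate the model;
at each acquisition time (default 1, 5, 10, 15 min) convert
concentrations to expected counts; thin each species by
$D_i/D_\mathrm{monomer}$ (landing bias as independent thinning — the
simplest process consistent with the multiplicative count correction)
and monomers additionally by 0.876; draw the event composition from a
multinomial at the target event total; give each event a Gaussian mass
around $42i$ kDa. The peak noise is implemented as zero-mean Gaussian
with the fitted peak SD; describing it as Poissonian, as is sometimes
done for such peaks, is internally contradictory for a continuous mass
coordinate and does not match the symmetric histogram peaks. Peak SDs
default to 8 kDa (experimental per-peak values are not tabulated; this
is an assumption, stated as such). Event totals default to 900–2900 per
time point, one tenth of the experimental range, to keep test runtimes
short. Scattering traces get i.i.d. Gaussian noise of variance 1740
(squared arbitrary units, the noise scale such fits converge to for
this instrument class), on 1800 points at 2-s spacing; the scale
default $s = 1000$ puts the signal well above that noise floor, as in
experimental traces.

What the generator does *not* emulate: raw landing videos and the
contrast-to-mass calibration (instrument domain), the pre-measurement
dilution step (shown negligible in the original control), false-positive
events (5.6% for monomers; available as an optional uniform-mass
contaminant but off by default), and day-to-day variation of event
totals.

## Bayesian inference

The joint objective over the scattering (BLS) and mass-photometry (MP)
datasets is the Gaussian form

$$-\ln\mathcal{L} = \sum_{j} \Big( 2N_j \ln \sigma_j + N_j \ln 2\pi +
\sum_i \frac{(y_{i,j} - f_{i,j}(\theta))^2}{2\sigma_j^2} \Big),$$

with the normalization constants doubled relative to the textbook
Gaussian form, kept as such for comparability (with fixed $\sigma_j$
they cancel in all posterior ratios). The
per-technique noise scales $\sigma_j^2$ act as relative weights; they
are fixed by default, with a Neyman-$\chi^2$ per-bin-variance variant
available behind a flag for count data. For fits to the synthetic MP
fractions the package uses $\sigma^2_\mathrm{MP} = 2\times10^{-4}$ on
the subunit-mass-fraction scale — the multinomial sampling scale at
1000–3000 events per video including the heavy-tail weight noise (the
published value ~0.003 refers to a different, histogram-density scale).

Priors are uninformative: uniform on $[0, 10^5 \times
\mathrm{reference}]$ per fitted constant, anchored at published values.
Failed or non-finite forward evaluations map to $+\infty$ (sample
rejected). Sampling uses an affine-invariant ensemble: walkers start in
a Gaussian ball (1% relative SD) around the reference values, never
outside the prior, and propose moves from the complementary half of the
ensemble with a mixture of the differential-evolution move (80%,
$\gamma_0 = 2.38/\sqrt{2d}$ with small jitter) and the snooker move
(20%, $\gamma_s = 1.7$, with the $|x'-z|^{d-1}/|x-z|^{d-1}$ Metropolis
factor). Since no R implementation of this sampler family exists, it is
authored here and validated against exact moments of a correlated
Gaussian target.

Convergence is assessed by the integrated autocorrelation time
$\tau$, estimated from the walker-averaged autocorrelation function
under the self-consistent window rule $M = \min\{m : m \ge c\,\tau(m)\}$
with $c = 5$ (the window constant of the cited method is not specified
in the text; $c$ is configurable); a parameter is flagged unconverged
when the chain is shorter than $50\tau$. Model comparison uses
$\mathrm{AIC} = 2k - 2\ln\hat L$ and $\mathrm{BIC} = k\ln N - 2\ln\hat
L$ at the maximum sampled likelihood, and corner-plot marginals (1-D and
2-D normalized histograms) locate the best-fit region.

Desk-scale defaults are 16–32 walkers and a few hundred to a few
thousand steps; cluster-scale settings (100 walkers, hundreds of
thousands of samples) remain available through the configuration.
Chains are kept in memory and exported as columnar-text summaries and
marginal histograms.

### Identifiability of the transition rate

A practical caveat established with the synthetic generator: the
transition rate is only identifiable when its timescale is resolvable by
the acquisition grid. With measurements at 1–15 min, a transition at
0.3 s^-1^ is complete before the first observation, so only a lower
bound on $k_\mathrm{trans}$ is identified and, under the wide uniform
prior, the posterior accumulates at large values. The parameter-recovery
experiments therefore generate data at $k_\mathrm{trans} = 0.005$
s^-1^ (half-life ≈ 2.3 min), where both interval ends are data-driven.
This is a property of the experimental design, not of the sampler.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run everything at desk
scale, chosen as the package's own defaults: trajectories at
$n_\mathrm{max} = 400$ (scattering: 2000), SSA comparisons with 200 runs
of ~10^4^ molecules on 10-species networks, recovery fits with
16 walkers × 500 steps against an $n_\mathrm{max} = 50$ forward model
(truncating below ~0.1% of mass at 900 nM), and a 20-replicate coverage
experiment for the credible intervals. Passing these checks demonstrates
internal consistency of the full chain — simulation, observable
synthesis, analysis, inference — under the generator's assumptions; it
does not by itself validate the kinetic models against real actin data,
which requires the original instrument-domain calibrations.

## Known limitations

* Well-mixed, fragmentation-free schemes: no annealing, severing,
  length-dependent rates, or spatial structure.
* The truncation at $n_\mathrm{max}$ parks late-time mass in the
  absorbing species; metrics that depend on the far tail need the guard
  warning heeded.
* The free-energy-derived nucleation rate table of the original
  comparison model is not redistributable; its preset ships as a
  citation-only template to be filled by the user.
* Single-machine execution; the full published MCMC scale is supported
  in configuration but impractical without a cluster.
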