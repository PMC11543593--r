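---
title: "The reactor model, its calibration, and what the synthetic data can show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The reactor model, its calibration, and what the synthetic data can show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferronox)
```

## The scientific problem

Anoxygenic photoferrotrophs oxidize dissolved Fe(II) with light as the
energy source; nitrate-reducing Fe(II) oxidizers (NDFO cultures) oxidize the
same substrate using NO3- as electron acceptor. Where both guilds share an
anoxic, ferruginous habitat, the denitrifiers release reactive nitrogen
intermediates — nitric oxide (NO) and nitrous oxide (N2O) — and nanomolar
aqueous NO is enough to shut photoferrotrophy down. `ferronox` implements a
mechanistic batch-reactor model of this interaction, the calibration
workflow that estimates its parameters from incubation time series, and a
synthetic-data generator that makes every stage of the pipeline testable
with known ground truth.

## Model structure

All scenarios are well-mixed batch reactors with an aqueous volume
$V_w$ and headspace $V_g$ (defaults 0.05 L each: 50 ml of medium under a
50% headspace).

**Photoferrotrophy.** The phototroph (biomass density $X_{SW2}$, cells/L)
grows on Fe(II) by single-Monod kinetics, with light assumed non-limiting:

$$ r_{SW2} = \mu_{max}^{ph}\,\frac{C_{Fe}}{C_{Fe}+K_{Fe}^{ph}}\,X_{SW2},
\qquad \frac{dX_{SW2}}{dt} = r_{SW2},\qquad
\frac{dC_{Fe}}{dt} = -\frac{r_{SW2}}{Y_{SW2}} $$

**Two-step denitrification.** The NDFO culture (biomass $X_{KS}$) reduces
nitrate in two microbially mediated steps, NO3- → NO → ½ N2O, each dual-Monod
in the electron donor Fe(II) and the step's nitrogen acceptor:

$$ r_{KS}^{i} = \mu_{max}^{i}\,
  \frac{C_{Fe}}{C_{Fe}+K_{Fe}^{NDFO}}\,
  \frac{C_{N_i}}{C_{N_i}+K_{N_i}}\,X_{KS}, \quad i \in \{1,2\} $$

The chain stops at N2O (the culture is not assumed to reduce N2O to N2) and
no nitrite pool is carried (its conversion to NO is treated as fast; none is
observed in such incubations). Electron stoichiometry ties iron to nitrogen:
step 1 transfers three electrons per N (3 Fe per NO3-), step 2 one electron
per N (1 Fe per NO, producing ½ N2O), so complete reduction of 1 mM NO3-
through the model chain consumes 4 mM Fe(II), versus 5 mM for full
denitrification to N2. Both steps draw on one lumped biomass pool and there
is no KS decay term, so $X_{KS}$ is non-decreasing.

**Gas exchange and sampling.** NO and N2O partition between water and
headspace by a linear driving force towards Henry equilibrium,
$r_{tr} = k_{tr}(C - p/(RTH))$, with $H$ the dimensionless gas-over-aqueous
concentration ratio. Periodic sample withdrawal is modelled as continuous
first-order dilution of the headspace partial pressures at rate $Q_s/V_g$,
with $Q_s = 4.62\times10^{-9}$ L/s the experiment-averaged sampling rate.
Headspace flushes are instantaneous events that zero both partial pressures;
a 5-minute purge is short against the multi-day dynamics, so its duration is
not resolved.

**NO toxicity.** In the mixed scenario the phototroph balance gains an
NO-dependent decay term lumping lysis and dormancy:

$$ \frac{dX_{SW2}}{dt} = r_{SW2} - k_d\,(1 - f_{tox})\,X_{SW2},
\qquad f_{tox} = \frac{1}{1+(C_{NO}/K_I)^p} $$

$K_I$ is fixed at 12 nM ($1.2\times10^{-5}$ mM), the experimentally
determined half-effect NO concentration; $k_d$ (per day) and the steepness
exponent $p$ are the only free parameters of the mixed model.

### Units

Concentrations are in mM, which numerically equals mol m$^{-3}$, so the
Henry term $p/(RT)$ evaluated with $p$ in Pa, $R = 8.3145$ J mol$^{-1}$
K$^{-1}$ and $T = 298.15$ K yields mM directly with no hidden conversion
factor. Time is in days, biomass in cells per litre internally; the
`cells_per_ml` observable divides by $10^3$ to match how flow-cytometry
counts are reported.

## Numerical choices

The ODE systems are stiff — states span twelve orders of magnitude between
nanomolar NO and $10^{10}$ cells/L — and are integrated with `deSolve`'s
`lsoda` at rtol $10^{-8}$, atol $10^{-12}$. At these tolerances the nitrogen
inventory (aqueous NO3-/NO/N2O, headspace NO/N2O via the ideal gas law, and
the nitrogen removed by sampling and flushing, which the state tracks
explicitly) closes to better than $10^{-6}$ relative, which
`nitrogen_budget()` audits; budget violation is the designed alarm for a
right-hand-side or unit error. Rate laws clamp negative concentrations to
zero so that transient solver overshoot cannot create spurious negative
fluxes; the state itself is never clipped. Flushes are handled as solver
events rather than steep forcings.

## Calibration

Following common practice for kinetic constants that differ by orders of
magnitude, all fitting operates on $\log_{10}$ parameters, with box bounds
of ±3 decades around the starting values. The loss is the plain sum of
squared residuals, with each observable scaled by a characteristic value
(initial Fe(II) and nitrate, maximum observed cell count and partial
pressure) so millimolar and Pascal data contribute comparably. The
optimizer is `minpack.lm`'s bounded Levenberg–Marquardt, multi-started from
log-uniform perturbations (default ±0.5 decade) of the starting point; the
first start is always the supplied center, and the returned optimum is
never worse than it. One numerical detail matters: the finite-difference
step used for the Jacobian must sit well above the ODE integration noise,
otherwise the optimizer stalls on a noise-dominated gradient — `epsfcn` is
set to $10^{-6}$ (steps of roughly $10^{-3}$ in log space) for this reason.

The workflow mirrors the experimental design: `fit_sw2()` calibrates
$\{\mu_{max}^{ph}, K_{Fe}^{ph}, Y_{SW2}\}$ on phototroph-only data;
`fit_ks()` calibrates the eight denitrifier/gas parameters on
denitrifier-only data; `fit_mixed_toxicity()` then assembles the mixed
model from the two individual fits and frees only $\{k_d, p\}$, with $K_I$
pinned at 12 nM. Uncertainty comes from the Gauss–Newton residual
covariance $\sigma^2 (J^T J)^{-1}$ on the log scale — a deliberate,
documented simplification rather than a bootstrap — and
`local_sensitivity()` reports loss gradients, residual-Jacobian magnitudes
and a non-identifiability flag per parameter.

### Identifiability under the study conditions

Two structural facts limit what any estimator can recover from data
collected under the incubation design (triplicates, sampling every 2 days,
realistic noise):

* In the denitrifier fit, aqueous NO stays far below $K_{NO}$ and Fe(II)
  far above $K_{Fe}^{NDFO}$, so the data constrain flux combinations
  (e.g. $\mu_{max}^2 X/(K_{NO} Y_{KS,2})$) rather than each constant
  individually. Fits reproduce the trajectories essentially exactly while
  individual constants wander along the sloppy manifold; the test suite
  therefore asserts trajectory fidelity and the well-identified $k_{tr}$,
  not blanket parameter recovery.
* In the mixed fit, aqueous NO plateaus at ~13 nM — almost exactly $K_I$.
  At the inflection point the toxicity function's value is insensitive to
  its steepness, so $p$ is weakly identified at realistic noise even though
  it is recovered sharply from noise-free data. The decay rate $k_d$, and
  the effective decay $k_d(1-f_{tox})$ at the plateau NO level, are
  identified and are what the noisy-data checks assert.

Both limits are properties of the experiment being emulated, not of the
optimizer; the zero-noise recovery tests demonstrate the estimator itself
is unbiased and exact in the rich-information limit.

## The synthetic-data generator

`generate_observations()` emulates the incubation measurements: triplicate
vessels, a 30-day horizon, discrete sampling every 2 days, observables
Fe(II) (mM), NO3- (mM), total cells per ml, and headspace N2O — with NO
partial pressure reported only for the denitrifier-only scenario, mirroring
the parallel incubation in which NO was actually monitored. Noise is
multiplicative and applied to observations only (the model is
deterministic; there is no process noise): zero-truncated Gaussian for
concentrations and pressures, log-normal for cell counts, each
parameterized so the coefficient of variation equals the configured
relative sd. Defaults — Fe(II) 3%, NO3- 5%, cells 20%, gas 10% — are
instrument-class magnitudes chosen here as synthetic settings, not
measured values. Generation is a pure function of (config, parameters,
schedule, noise, seed) and leaves the caller's RNG untouched.

The packaged reference parameter set
(`inst/extdata/params_synthetic_default.yaml`) is itself synthetic: the
printed study conditions fix the initial concentrations (10 mM Fe(II);
0.4 or 1 mM NO3- for scenarios A/B), inocula ($2\times10^9$ and
$1\times10^9$ cells/L), geometry and sampling rate, while the kinetic
constants were chosen once so the simulated incubations land on the
reported milestones: complete photoferrotrophic oxidation near day 28,
nitrate exhaustion in about four days with ~4 mM Fe(II) oxidized, mixed
Fe(II) oxidation ceasing shortly after nitrate exhaustion at a 4–5 mM
plateau, and a nanomolar NO transient. Henry constants (NO ≈ 21.3,
N2O ≈ 1.7, dimensionless gas/aqueous at 298.15 K) are literature-plausible
configuration entries. Replays of this set are self-consistency checks of
the packaged conditions, not a re-derivation of any published calibration.

What passing tests on these data do show: the rate laws, stoichiometry,
budgets and event handling are implemented correctly; the estimator
recovers generating parameters where the data identify them. What they do
not show: anything about abiotic chemodenitrification (excluded from the
model class), nitrite dynamics, light limitation, mineral-surface effects,
or the quantitative values of the real cultures' kinetic constants.

## Operational definitions

"Fe(II) oxidation ceases" is operationalized as the first time, after the
rate maximum, that $|dC_{Fe}/dt|$ drops below 1% of its maximum; "complete
oxidation" as ≥99% of the initial Fe(II) consumed; "nitrate exhausted" as
NO3- below 1% of its initial value. These thresholds are package
conventions — the qualitative statements they quantify do not come with
printed cutoffs.

## A worked pass through the pipeline

```{r, eval = FALSE}
scen <- make_default_scenarios()
truth <- default_params()

# simulate the denitrifier-only incubation and audit it
traj <- simulate_reactor(scen$ks_only_B$config, truth)
nitrogen_budget(traj)$max_rel_dev
trajectory_summary(traj)

# synthetic observations and a parameter-recovery fit
obs <- generate_observations(scen$sw2_only$config, truth,
                             scen$sw2_only$schedule, seed = 1)
fit <- fit_sw2(obs, config = scen$sw2_only$config)
fit$estimates

# the full generate -> fit -> assemble -> predict -> audit loop
report <- run_replication(seed = 1)
report
```

The test suite runs the same loop at reduced problem sizes: fits use the
2-day sampling schedule over 30 days, multi-start counts of 1–3, and the
looser in-fit integration tolerance of $10^{-6}$, sizes chosen so a full
check completes in minutes on one core.

## Known limitations

* No N2 pool: the chain ends at N2O, so "full denitrification to N2" exists
  only as a stoichiometric reference ratio, not a simulated state.
* No abiotic Fe(II)–nitrite chemistry, no nitrite pool, no light limitation,
  no aqueous-volume loss from liquid sampling (only the headspace is
  diluted), and no spatial structure.
* The flush-versus-no-flush contrast in the model is small (the NO
  inventory is flux-dominated, so removing the headspace stock is quickly
  made good by ongoing production); the simulated benefit of flushing is
  strictly positive but far weaker than the experimentally observed
  recovery, which plausibly involves cumulative-exposure physiology the
  instantaneous toxicity function does not carry.
* Gauss–Newton standard errors understate uncertainty along sloppy
  directions; treat flagged parameters as order-of-magnitude only.
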