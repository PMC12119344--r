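---
title: "Multiscale modeling of cortical brain states: from AdEx neurons to whole-brain dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale modeling of cortical brain states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The modeling problem

Anesthetics and the neuromodulatory changes of NREM sleep act on membrane
receptors — single-molecule scale — yet their signatures (slow waves, loss
of responsiveness, functional connectivity reorganisation) are whole-brain
phenomena. `brainmf` implements a bottom-up chain that carries microscopic
parameters to macroscopic observables:

1. **Microscale** — adaptive exponential integrate-and-fire (AdEx) neurons
   with conductance-based synapses. The molecular dials are the synaptic
   decay times: GABAergic agents (e.g. propofol) prolong the inhibitory
   decay `tau_i`, NMDA blockers (e.g. ketamine) shorten the excitatory
   decay `tau_e`, and reduced acetylcholine in NREM sleep raises the
   spike-triggered adaptation `b_e`.
2. **Mesoscale, high-dimensional** — a sparse random network of 10,000 AdEx
   neurons (80% regular-spiking excitatory, 20% fast-spiking inhibitory,
   connection probability 5%) representing one cortical column.
3. **Mesoscale, low-dimensional** — a second-order mean-field (master
   equation formalism) for the population rates, their covariances and the
   mean adaptation current, built on a semi-analytic transfer function.
4. **Macroscale** — a network of mean-field nodes coupled by a weighted
   connectome with axonal conduction delays, from which BOLD signals,
   structure–function (SC–FC) correlation and the perturbational complexity
   index (PCI) are computed.

# Single cells and synapses

The membrane equation combines leak, an exponential spike-initiation term
with slope `delta`, an adaptation current `w`, and conductance-based
synaptic input; `w` relaxes with `tau_w = 500` ms and jumps by `b` at each
spike. RS cells use `E_L = -64` mV, `delta = 2` mV, `a = 0`; FS cells
`E_L = -65` mV, `delta = 0.5` mV and no adaptation. Synapses are decaying
exponentials with quantal conductances `Q_e = 1.5` nS, `Q_i = 5` nS and
reversal potentials 0 / −80 mV.

Numerical choices: forward Euler at `dt = 0.1` ms (the standard AdEx
working step); synaptic conductances decay by their **exact** exponential
factor each step, since that ODE is linear and the closed form removes
discretisation error; a spike is registered when `v` reaches 0 mV — above
`v_thr = -50` mV the exponential term diverges, so any ceiling well above
threshold gives the same spike times — after which `v` is clamped at the
reset for the 5-ms refractory period. The exponential argument is capped
(at 30) purely to avoid floating-point overflow in the step *before* the
reset is applied.

# The semi-analytic transfer function

The mean-field needs each cell type's stationary output rate as a function
of its excitatory/inhibitory input rates and adaptation,
`F(nu_e, nu_i, W)`. For conductance-based AdEx neurons no closed form
exists, so `F` is built semi-analytically: shot-noise theory maps the input
rates to the subthreshold voltage statistics (`mu_V`, `sigma_V`, `tau_V`),
and the output rate follows a Gaussian first-passage template,
`F = Erfc((V_thr_eff - mu_V) / (sqrt(2) sigma_V)) / (2 tau_V)`, whose
*effective threshold* is a second-order polynomial in the normalised
fluctuation variables. The ten polynomial coefficients are fitted to
simulations of a single neuron under Poissonian bombardment
(`fit_transfer_function()`), independently for RS and FS cells and for each
synaptic parameterization.

Three procedural choices matter and were made once, on methodological
grounds:

* **The adaptation axis is sampled, not extrapolated.** `W` enters the
  membrane equation exactly like a constant hyperpolarising current, so the
  grid of input rates is crossed with clamped adaptation currents
  (0, 40, 80, 160 pA). Without these points the polynomial's response to
  the adaptation shifts that decide the slow-wave bifurcation is pure
  extrapolation, and the critical adaptation estimate inherits its
  arbitrariness.
* **Low-rate points are measured to a fixed spike-count target.** The
  bistability structure of the network lives at the low-rate knee of the
  transfer function, where a fixed-duration measurement leaves Poisson
  noise of several tenths of a Hz — enough to move the critical adaptation
  by several pA between fitting seeds. Points firing below 25 Hz are
  therefore re-measured until ~1000 spikes are collected (capped at 300 s
  simulated), bringing the relative error to the few-percent level.
* **The refinement stage minimises `log(1 + rate)` residuals.** The Erfc
  template is only approximate in the strongly mean-driven (> 60 Hz)
  corner of the grid, where refractoriness dominates; plain least squares
  lets that corner distort the fluctuation-driven regime the mean-field
  actually visits. Relative residuals keep every decade of rate on equal
  footing.

Two printed-formula notes. The single-event voltage jump is implemented as
`U_s = (Q_s / mu_G) (E_s - mu_V)` — the form with the division is the only
dimensionally consistent reading of the voltage-fluctuation formulas. The
conductance-SD expression is reported exactly as the framework states it;
it is informational only, since the voltage SD is computed directly from
the event-jump form and the conductance SD never enters the dynamics.

# Mean-field dynamics and the slow-wave bifurcation

The first-order model integrates
`T dnu/dt = F(nu_e + nu_aff, nu_i, W) - nu` for both populations plus the
slow adaptation `dW/dt = -W/tau_w + b nu_e`; the second-order model adds
the rate covariances, whose finite-size source scales as `1/N`, and the
curvature correction to the rate equations (second derivatives of `F` by
central differences, step 0.01 Hz). `T = 5` ms is the relaxation time of
the population rate — the Markovian timescale of the underlying
master-equation construction; it is exposed in `mean_field_params()`.

The afferent drive is `nu_aff = nu_drive + sigma xi(t)` with `xi` an
Ornstein–Uhlenbeck process (`tau_OU = 5` ms, `sigma = 3.5`), clipped at
zero because rates cannot be negative. The unit-amplitude Wiener increment
is taken per **second** (stationary `sd(xi) ≈ 0.05`), giving drive
fluctuations of ~0.2 Hz around `nu_drive`; the millisecond convention
would produce ±5 Hz swings that drown a 0.3–0.6 Hz drive and, empirically,
push the wake-like whole-brain state into a saturated high-rate regime.

Fixed points of the autonomous module are found through the
one-dimensional reduction `H(nu_e) = F_e(nu_e, nu_i_bar(nu_e), W_eq)`,
with the inhibitory population at its stationary rate and the adaptation at
equilibrium `W = b nu_e tau_w`. Bistability (quiescent + self-sustained
states separated by a saddle) disappears at a critical adaptation
`b_crit`, computed by bisection on the fixed-point count
(`critical_adaptation()`). The scan grid is capped at 50 Hz — the domain
over which the transfer function is fitted — because outside it the
threshold polynomial extrapolates without constraint and can manufacture
spurious intersections. When a synaptic parameterization eliminates the
self-sustained branch even at `b = 0` (strong NMDA block does this),
`b_crit` is reported as 0 with a `degenerate` attribute: the transition
has already happened below any adaptation.

In the spiking network, self-sustainability is probed operationally: a
1-Hz, 120-ms Poisson-rate stimulus kick-starts the quiescent network and
the survival time of activity after stimulus offset is measured
(`survival_time()`), declaring extinction at the first 20-ms spike-free
gap — an unambiguous criterion for a finite network. Reduced networks used
in the validation suite keep the full column's synaptic in-degrees
(`N = 2500` with `p = 0.2`, so `K_e = 400`, `K_i = 100` as in the
`N = 10^4`, `p = 0.05` column): the mean-field sees only in-degrees, so
this preserves the correspondence while shrinking the simulation.

# Whole-brain model

Each region is a first-order mean-field module; only excitatory rates
couple between regions (inhibition stays local), weighted by the
connectome and delayed by tract length over conduction speed
(`v_c = 3` mm/ms, delays rounded to the integration step; the history
buffer is initialised at the initial rates). Connection weights are
rescaled to maximum 1 on load so the global coupling `G` carries the
overall magnitude. The diagonal is excluded from the coupling sum — the
region's own excitatory rate already enters its input explicitly.

The synthetic connectome generator (`synthetic_connectome()`) stands in
for tractography: centres uniform in a 70-mm sphere, tract lengths the
Euclidean distances (symmetric, triangle-inequality consistent by
construction), and symmetric log-normal weights at a requested density. It
emulates the size and sparsity of a cortical parcellation, not the
topology, hub structure or left–right symmetry of a real brain — results
on it demonstrate the machinery and the qualitative state contrasts, not
anatomical specificity.

The macroscale analyses in the test-suite use a frozen study
configuration: 20 regions, density 0.15, `G = 0.3`, stimulation delivered
to the strongest-connected node. Neither `G` nor `v_c` has a published
value for this model family; `G` was calibrated once, by scanning
0.1–0.8 for the largest coupling at which the wake-like preset remains a
stable asynchronous state while the slow-wave presets show coordinated
low-frequency bursting, and then frozen before any statistics were
collected.

The four brain-state presets (`state_presets()`) are, as
(`b_e` pA, `tau_i` ms, `tau_e` ms): wake (5, 5, 5), propofol (30, 7, 5),
NREM (120, 5, 5), ketamine (30, 5, 3.75), all with `nu_drive = 0.315` Hz
at the whole-brain scale.

# Observables

**BOLD.** Excitatory rates are downsampled to 250 Hz, convolved with the
first-order Volterra kernel of the Balloon–Windkessel hemodynamic model
and resampled at `TR = 2` s. The kernel is obtained by integrating the
hemodynamic ODEs for a small impulse (support 25 s) with the standard
constants: signal decay 0.65 s⁻¹, autoregulation 0.41 s⁻¹, transit time
0.98 s, Grubb exponent 0.32, resting extraction 0.34, venous volume
fraction 0.04. **FC** is the Pearson correlation matrix across regions;
**SC–FC correlation** the Pearson correlation of the off-diagonal upper
triangles.

**PCI.** A 1-Hz, 50-ms square stimulus is applied to one region's
excitatory input. Post-stimulus rates (300 ms) are z-scored against the
pre-stimulus interval per region; significance is thresholded at the 95th
percentile of a max-statistic null built from 500 phase-randomised
surrogates of the pre-stimulus traces (the max over regions and time
controls multiplicity; phase randomisation preserves each trace's
amplitude spectrum and hence its autocorrelation, while a plain circular
shift would leave the max statistic unchanged and the null degenerate). The binary matrix
`S` is scanned region-major; its LZ76 complexity is normalised by the
asymptotic value `L / log2(L)` and divided by the source entropy `H(S)`,
making values comparable across trial lengths. A trial with `H = 0` has no
defined complexity and is returned as `NA` with a diagnostic count; the
validation suite maps these to 0 under the explicit convention that an
undetectable response carries zero perturbational complexity. The raw
(unnormalised) ratio is reported alongside.

**Slow-wave frequency.** Population-rate traces in deep slow-wave regimes
are trains of sharp (~10 ms) UP events at a few Hz; the raw periodogram of
a pulse train concentrates power in the harmonics of the event rate, so
the spectral argmax can land on a harmonic. `dominant_frequency()`
therefore low-passes the trace (100-ms boxcar for slow-wave analyses)
before the smoothed periodogram; the pre-smoothing attenuates the
burst-shape harmonics without touching the slow-wave band.

# Problem sizes in the validation suite

The suite fits transfer functions for four synaptic parameterizations (a
few minutes total), runs the survival scan at `N = 2500` with 5 trials per
cell, the slow-wave comparison on 30–60 s simulations, and the macroscale
ensembles with 10 noise realizations per brain state (~2 minutes of
simulated activity each for SC–FC). These sizes were chosen as the
smallest at which the corresponding statistics are stable across seeds.

# Known limitations

* The effective-threshold polynomial is refit from scratch; published
  coefficient tables for related parameterizations are not reproduced, and
  quantities that depend on the *depth* of supercriticality (absolute
  `b_crit` values, burst amplitudes, and downstream macro observables such
  as the exact PCI and SC–FC contrasts between individual anesthetic
  presets) inherit that freedom. Qualitative structure — fixed-point
  counts, monotonicity of `b_crit` in the synaptic decays, the
  AI-to-slow-wave transition — is robust across fitting seeds.
* With the refit transfer functions, the propofol- and ketamine-like
  whole-brain states respond only weakly to the 1-Hz probe stimulus: their
  binarized responses are sparse, a regime where the normalised-complexity
  ratio is intrinsically unstable (a handful of fragmented significant
  samples is near-maximally complex for its size). The PCI contrast
  between wake and those two anesthesia presets is correspondingly
  fragile; wake versus NREM — where the stimulus ignites a strong,
  stereotyped wave — is robust. Likewise, the ketamine preset's deep
  supercriticality yields connectome-routed slow bursting and therefore an
  elevated SC–FC correlation rather than the wake-like value reported for
  the empirical condition.
* The mean-field assumes Poissonian input statistics; in the spiking
  network, shared presynaptic pools induce correlations that shift
  stationary rates by ~15% at the full column size (quantified in the
  suite) and more in small networks.
* The synthetic connectome carries no anatomy; empirical connectome
  bundles in the plain-text matrix dialect can be supplied via
  `read_connectome()`.
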