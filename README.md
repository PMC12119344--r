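# brainmf — multiscale brain simulation with biophysical mean-field models

`brainmf` simulates cortical dynamics across four scales — single adaptive
exponential integrate-and-fire (AdEx) neurons, sparse spiking networks, a
biophysically grounded mean-field, and connectome-coupled whole-brain
networks — so that molecular-scale parameter changes (synaptic decay times,
spike-frequency adaptation) can be traced to whole-brain observables. It is
aimed at computational neuroscientists studying brain-state transitions
such as anesthesia and NREM sleep.

## The model in brief

**Microscale.** AdEx membrane dynamics with conductance-based synapses:

    c_m dv/dt = g_L (E_L − v) + g_L Δ exp((v − v_thr)/Δ) − w + G_e(E_e − v) + G_i(E_i − v)
    τ_w dw/dt = a (v − E_L) − w,   w → w + b at each spike

Regular-spiking (RS, excitatory) cells carry spike-triggered adaptation
`b`; fast-spiking (FS, inhibitory) cells none. Anesthetics map onto the
synaptic decays: GABAergic agents raise `τ_i`, NMDA blockers lower `τ_e`;
NREM sleep raises `b_e`.

**Mesoscale.** A 10,000-neuron random network (80/20 RS/FS, connection
probability 5%) and its mean-field reduction

    T dν_μ/dt = F_μ(ν_e + ν_aff, ν_i, W) − ν_μ,   dW/dt = −W/τ_w + b ν_e

where the transfer function `F` is semi-analytic: shot-noise voltage
statistics (μ_V, σ_V, τ_V) feed an Erfc first-passage formula,
`F = Erfc((V_eff − μ_V)/(√2 σ_V))/(2 τ_V)`, whose effective threshold is a
fitted second-order polynomial (`fit_transfer_function()`). Fixed-point
analysis of `H(ν_e) = F_e(ν_e, ν̄_i, W_eq)` yields the bistability structure
and the critical adaptation `b_crit` at which the self-sustained state — and
with it, asynchronous activity — gives way to slow-wave UP/DOWN dynamics.

**Macroscale.** Mean-field nodes coupled by a weighted connectome with
conduction delays (`simulate_whole_brain()`), plus the emergent-state
observables: simulated BOLD (Balloon–Windkessel kernel), functional
connectivity and SC–FC correlation, and the perturbational complexity
index (PCI = normalised Lempel–Ziv complexity of the significance-binarized
evoked response, divided by its source entropy).

## Worked example

Fit the transfer functions for the baseline synapses, locate the fixed
points of the cortical module, and find the critical adaptation:

```r
library(brainmf)

syn  <- synapse_params()                       # tau_e = tau_i = 5 ms
tf_e <- fit_transfer_function(neuron_params("RS"), syn, seed = 11)
tf_i <- fit_transfer_function(neuron_params("FS"), syn, seed = 511)

find_fixed_points(tf_e, tf_i, b_e = 5)
#>   nu_e_star nu_i_star   W_star stable
#> 1 0.0000000 0.0000000 0.000000   TRUE
#> 2 0.7192006 0.8386566 1.798001  FALSE
#> 3 2.9587308 6.8989304 7.396827   TRUE

critical_adaptation(tf_e, tf_i)
#> [1] 12.45117
```

Three fixed points at wake-like adaptation (`b_e = 5` pA): a stable
quiescent state, an unstable saddle, and a stable self-sustained state near
3 Hz. Raising `b_e` past `b_crit ≈ 12` pA destroys the self-sustained
state; with the slow adaptation current this produces UP/DOWN slow waves:

```r
p  <- mean_field_params(b_e = 120, nu_drive = 0.4)   # NREM-like
tr <- simulate_mean_field(p, tf_e, tf_i, duration = 60000, seed = 3)
dominant_frequency(tr$nu_e[tr$time > 5000], dt_ms = 1, smooth_ms = 100)
#> [1] 2.929688
```

a ~3-Hz slow-wave rhythm. Whole-brain states use the four presets of
`state_presets()` (wake, propofol, NREM, ketamine) on a connectome — either
a plain-text bundle via `read_connectome()` (`weights.txt`,
`tract_lengths.txt`, optional `centres.txt`, TVB-style dialect) or the
built-in `synthetic_connectome()`.

A command-line front end over the same functions ships in
`inst/cli/brainmf.R` (subcommands `fit-tf`, `fixed-points`, `bcrit-scan`,
`simulate-meanfield`, `simulate-network`, `scan-survival`,
`simulate-brain`, `bold`, `scfc`, `pci`, `make-connectome`; every run
writes a manifest with its seed and options).

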