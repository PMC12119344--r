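#' Initial state of a single AdEx neuron
#'
#' @param params `neuron_params` giving the rest values.
#' @param v,w,g_e,g_i optional initial membrane potential (mV), adaptation
#'   current (pA) and synaptic conductances (nS).
#' @return A list of class `neuron_state` with fields `v`, `w`,
#'   `refractory_until` (ms) and `g_e`, `g_i`.
#' @export
neuron_state <- function(params, v = params$E_L, w = 0, g_e = 0, g_i = 0) {
  stopifnot(g_e >= 0, g_i >= 0)
  structure(list(v = v, w = w, refractory_until = -Inf, g_e = g_e, g_i = g_i),
            class = "neuron_state")
}

#' Advance a single AdEx neuron by one Euler step
#'
#' Forward-Euler update of the membrane potential and adaptation current with
#' conductance-based synaptic input. Synaptic conductances decay by their
#' exact exponential factor over the step (the conductance ODE is linear, so
#' no discretisation error is introduced there). A spike is registered when
#' the membrane potential reaches 0 mV (the exponential term diverges above
#' `v_thr`, so the precise ceiling is immaterial); the voltage is then reset
#' to `v_rest`, clamped there for `t_refr` ms, and the adaptation current is
#' incremented by `b`.
#'
#' This scalar R implementation is the readable reference used by the tests;
#' the network and transfer-function simulators run the same dynamics in
#' compiled code.
#'
#' @param state a `neuron_state`.
#' @param params a `neuron_params`.
#' @param syn a `synapse_params`.
#' @param dt time step (ms).
#' @param t current time (ms).
#' @return list with elements `state` (updated `neuron_state`) and `spiked`.
#' @examples
#' p <- neuron_params("RS"); s <- synapse_params()
#' st <- neuron_state(p)
#' step_neuron(st, p, s, dt = 0.1, t = 0)
#' @export
step_neuron <- function(state, params, syn, dt, t) {
  stopifnot(dt > 0)
  if (!all(is.finite(c(state$v, state$w, state$g_e, state$g_i))))
    stop("non-finite neuron state: integration failure")
  g_e <- state$g_e * exp(-dt / syn$tau_e)
  g_i <- state$g_i * exp(-dt / syn$tau_i)
  spiked <- FALSE
  if (t < state$refractory_until) {
    v <- params$v_rest
    w <- state$w + dt * (params$a * (v - params$E_L) - state$w) / params$tau_w
  } else {
    ex <- pmin((state$v - params$v_thr) / params$delta, 30)
    i_syn <- g_e * (syn$E_e - state$v) + g_i * (syn$E_i - state$v)
    dv <- (params$g_L * (params$E_L - state$v) +
             params$g_L * params$delta * exp(ex) - state$w + i_syn) / params$c_m
    v <- state$v + dt * dv
    w <- state$w + dt * (params$a * (state$v - params$E_L) - state$w) / params$tau_w
    if (v >= 0) {
      spiked <- TRUE
      v <- params$v_rest
      w <- w + params$b
      state$refractory_until <- t + dt + params$t_refr
    }
  }
  state$v <- v
  state$w <- w
  state$g_e <- g_e
  state$g_i <- g_i
  list(state = state, spiked = spiked)
}

#' Exponential synaptic conductance from a spike train
#'
#' Each presynaptic spike increments the conductance by the quantal value `Q`
#' and decays exponentially with time constant `tau`:
#' \eqn{G(t) = Q \sum_k \Theta(t - t_k)\, e^{-(t - t_k)/\tau}}.
#'
#' @param spike_times presynaptic spike times (ms).
#' @param t evaluation time(s) (ms); vectorised.
#' @param Q quantal conductance (nS).
#' @param tau decay time constant (ms).
#' @return Conductance (nS) at each `t`.
#' @examples
#' synaptic_conductance(c(0, 10), t = 12, Q = 1.5, tau = 5)
#' @export
synaptic_conductance <- function(spike_times, t, Q, tau) {
  stopifnot(tau > 0)
  vapply(t, function(tt) {
    dt <- tt - spike_times
    sum(Q * exp(-dt[dt >= 0] / tau))
  }, numeric(1))
}

#' Simulate one AdEx neuron under Poissonian synaptic bombardment
#'
#' Drives a single neuron with independent excitatory and inhibitory Poisson
#' spike trains whose total arrival rates are `nu_e * K_e` and `nu_i * K_i`
#' (presynaptic population rate times in-degree), and measures the stationary
#' output rate together with the subthreshold membrane-potential moments.
#' This is the numerical experiment from which the transfer function is
#' fitted.
#'
#' @param neuron a `neuron_params`.
#' @param syn a `synapse_params`.
#' @param nu_e,nu_i presynaptic population rates (Hz).
#' @param K_e,K_i synaptic in-degrees.
#' @param duration total simulated time (ms).
#' @param dt integration step (ms).
#' @param discard initial transient excluded from measurement (ms).
#' @param W adaptation current (pA); with `clamp_W = TRUE` it is held fixed,
#'   entering the membrane equation as a constant hyperpolarising current
#'   (how the transfer function is sampled along its adaptation axis).
#' @param clamp_W hold `W` constant instead of evolving it.
#' @param seed optional RNG seed.
#' @return list with `rate` (Hz), `n_spikes`, `mu_V` and `sigma_V` (mV).
#' @export
simulate_single_neuron <- function(neuron, syn, nu_e, nu_i,
                                   K_e = 400, K_i = 100,
                                   duration = 11000, dt = 0.1,
                                   discard = 1000, W = 0, clamp_W = FALSE,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cpp_single_neuron(unclass(neuron), unclass(syn),
                    rate_e = nu_e * K_e, rate_i = nu_i * K_i,
                    duration = duration, dt = dt, discard = discard,
                    w_init = W, clamp_w = clamp_W)
}
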