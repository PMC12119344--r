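#' Single-cell AdEx parameters
#'
#' Constructs and validates the parameter set of an adaptive exponential
#' integrate-and-fire (AdEx) neuron. The defaults reproduce the two cortical
#' cell classes used throughout the package: regular-spiking (RS) excitatory
#' pyramidal cells and fast-spiking (FS) inhibitory interneurons. RS cells
#' carry spike-frequency adaptation (`b`, pA) with a slow time constant
#' `tau_w`; FS cells have none (`a = b = 0`).
#'
#' @param type cell class, `"RS"` or `"FS"`; sets the class defaults.
#' @param b spike-triggered adaptation increment (pA). Varies across brain
#'   states (e.g. 5 pA in wake-like, 120 pA in NREM-like conditions).
#' @param c_m membrane capacitance (pF).
#' @param g_L leak conductance (nS).
#' @param E_L leak reversal potential (mV); -64 mV for RS, -65 mV for FS.
#' @param delta exponential spike-initiation slope (mV); 2 mV RS, 0.5 mV FS.
#' @param v_thr spike-initiation threshold of the exponential term (mV).
#' @param v_rest post-spike reset voltage (mV).
#' @param t_refr absolute refractory period (ms).
#' @param a subthreshold adaptation conductance (nS).
#' @param tau_w adaptation time constant (ms).
#' @return A named list of class `neuron_params`.
#' @examples
#' rs <- neuron_params("RS", b = 60)
#' fs <- neuron_params("FS")
#' @export
neuron_params <- function(type = c("RS", "FS"), b = NULL,
                          c_m = 200, g_L = 10,
                          E_L = NULL, delta = NULL, v_thr = -50,
                          v_rest = -65, t_refr = 5, a = 0, tau_w = 500) {
  type <- match.arg(type)
  if (is.null(E_L)) E_L <- if (type == "RS") -64 else -65
  if (is.null(delta)) delta <- if (type == "RS") 2 else 0.5
  if (is.null(b)) b <- if (type == "RS") 0 else 0
  if (type == "FS") { a <- 0; b <- 0 }
  p <- list(type = type, c_m = c_m, g_L = g_L, E_L = E_L, delta = delta,
            v_thr = v_thr, v_rest = v_rest, t_refr = t_refr,
            a = a, b = b, tau_w = tau_w)
  validate_neuron_params(p)
  structure(p, class = "neuron_params")
}

validate_neuron_params <- function(p) {
  stopifnot(p$c_m > 0, p$g_L > 0, p$delta > 0, p$t_refr >= 0,
            p$tau_w > 0, p$v_rest <= p$v_thr)
  invisible(p)
}

#' Conductance-based synapse parameters
#'
#' Quantal conductances, decay time constants and reversal potentials of the
#' exponential conductance-based synapses. The decay times are the molecular
#' dials of the model: GABAergic anesthetics prolong `tau_i`, NMDA blockers
#' shorten `tau_e`.
#'
#' @param Q_e,Q_i excitatory/inhibitory quantal conductances (nS).
#' @param tau_e,tau_i excitatory/inhibitory decay time constants (ms).
#' @param E_e,E_i excitatory/inhibitory reversal potentials (mV).
#' @return A named list of class `synapse_params`.
#' @examples
#' syn_propofol <- synapse_params(tau_i = 7)
#' @export
synapse_params <- function(Q_e = 1.5, Q_i = 5, tau_e = 5, tau_i = 5,
                           E_e = 0, E_i = -80) {
  stopifnot(Q_e > 0, Q_i > 0, tau_e > 0, tau_i > 0, E_i < E_e)
  structure(list(Q_e = Q_e, Q_i = Q_i, tau_e = tau_e, tau_i = tau_i,
                 E_e = E_e, E_i = E_i),
            class = "synapse_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("AdEx %s cell: c_m=%g pF, g_L=%g nS, E_L=%g mV, delta=%g mV,\n",
              x$type, x$c_m, x$g_L, x$E_L, x$delta))
  cat(sprintf("  v_thr=%g mV, v_rest=%g mV, t_refr=%g ms, a=%g nS, b=%g pA, tau_w=%g ms\n",
              x$v_thr, x$v_rest, x$t_refr, x$a, x$b, x$tau_w))
  invisible(x)
}

#' @export
print.synapse_params <- function(x, ...) {
  cat(sprintf("Synapses: Q_e=%g nS (tau_e=%g ms, E_e=%g mV), Q_i=%g nS (tau_i=%g ms, E_i=%g mV)\n",
              x$Q_e, x$tau_e, x$E_e, x$Q_i, x$tau_i, x$E_i))
  invisible(x)
}

#' Brain-state parameter presets
#'
#' The four brain-state conditions studied with the whole-brain model, each a
#' combination of excitatory spike-triggered adaptation `b_e` (pA) and
#' synaptic decay times (ms): wake (5, 5, 5), propofol anesthesia (30, 7, 5),
#' NREM sleep (120, 5, 5) and ketamine anesthesia (30, 5, 3.75) as
#' (b_e, tau_i, tau_e). `nu_drive` is the afferent drive used in whole-brain
#' runs (Hz).
#'
#' @return Named list of `state_preset` lists with fields `name`, `b_e`,
#'   `tau_e`, `tau_i`, `nu_drive`.
#' @examples
#' state_presets()$propofol
#' @export
state_presets <- function() {
  mk <- function(name, b_e, tau_i, tau_e) {
    structure(list(name = name, b_e = b_e, tau_e = tau_e, tau_i = tau_i,
                   nu_drive = 0.315),
              class = "state_preset")
  }
  list(wake     = mk("wake",     b_e = 5,   tau_i = 5, tau_e = 5),
       propofol = mk("propofol", b_e = 30,  tau_i = 7, tau_e = 5),
       NREM     = mk("NREM",     b_e = 120, tau_i = 5, tau_e = 5),
       ketamine = mk("ketamine", b_e = 30,  tau_i = 5, tau_e = 3.75))
}

#' Look up a single brain-state preset by name
#'
#' @param name one of `"wake"`, `"propofol"`, `"NREM"`, `"ketamine"`.
#' @return A `state_preset` list.
#' @export
state_preset <- function(name) {
  ps <- state_presets()
  if (!name %in% names(ps))
    stop("unknown state preset '", name, "'; available: ",
         paste(names(ps), collapse = ", "))
  ps[[name]]
}

#' @export
print.state_preset <- function(x, ...) {
  cat(sprintf("State preset '%s': b_e=%g pA, tau_e=%g ms, tau_i=%g ms, nu_drive=%g Hz\n",
              x$name, x$b_e, x$tau_e, x$tau_i, x$nu_drive))
  invisible(x)
}
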