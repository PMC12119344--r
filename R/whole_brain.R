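#' Focal stimulation of one brain region
#'
#' A square-wave increment of the excitatory input rate of a single node,
#' used for the evoked-response (PCI) protocol.
#'
#' @param node target node index (1-based).
#' @param amplitude amplitude (Hz).
#' @param onset onset time (ms).
#' @param duration duration (ms).
#' @return list of class `region_stimulus`.
#' @export
region_stimulus <- function(node, amplitude = 1, onset = 0, duration = 50) {
  stopifnot(amplitude >= 0, duration > 0, node >= 1)
  structure(list(node = as.integer(node), amplitude = amplitude,
                 onset = onset, duration = duration),
            class = "region_stimulus")
}

#' Simulate a whole-brain network of mean-field nodes
#'
#' Every region is a first-order excitatory/inhibitory mean-field module.
#' Regions are coupled through their excitatory rates only (inhibition stays
#' local to each region): node k receives
#' \eqn{\nu_e^{input}(k) = \nu_e(k) + \nu_{aff}(k) + G\sum_j C_{jk}\,
#' \nu_e(j, t - \|j-k\|/v_c)}, with conduction delays from the tract lengths
#' (rounded to integer multiples of `dt`; the history buffer starts at the
#' initial rates). Each node has an independent OU afferent drive with a
#' deterministic per-node sub-stream of the seed.
#'
#' @param con a `connectome`.
#' @param preset a `state_preset` (or name) fixing `b_e` and `nu_drive`; the
#'   synaptic decay times of the preset must match those the TFs were fitted
#'   with (checked).
#' @param tf_e,tf_i fitted `tf` objects for the preset's synapse parameters.
#' @param duration simulated time (ms).
#' @param dt integration step (ms).
#' @param stimulus optional `region_stimulus`.
#' @param seed RNG seed.
#' @param record_every record every this many steps (default 4 ms at
#'   dt = 0.1, i.e. a 250 Hz native sampling for the BOLD stage).
#' @param sigma OU amplitude (overrides the default 3.5 when given).
#' @param T_mf,tau_w mean-field and adaptation time constants (ms).
#' @param init_rate initial rates for all nodes (Hz).
#' @return list of class `brain_trajectory`: `time` (ms), matrices `nu_e`,
#'   `nu_i`, `W` (time x nodes), `sample_ms`, plus the run settings.
#' @export
simulate_whole_brain <- function(con, preset, tf_e, tf_i, duration = 10000,
                                 dt = 0.1, stimulus = NULL, seed = 1,
                                 record_every = 40, sigma = 3.5,
                                 T_mf = 5, tau_w = 500, init_rate = 1) {
  stopifnot(inherits(con, "connectome"), inherits(tf_e, "tf"),
            inherits(tf_i, "tf"))
  if (is.character(preset)) preset <- state_preset(preset)
  if (abs(tf_e$synapse$tau_e - preset$tau_e) > 1e-9 ||
      abs(tf_e$synapse$tau_i - preset$tau_i) > 1e-9)
    stop("transfer function was fitted for tau_e=", tf_e$synapse$tau_e,
         ", tau_i=", tf_e$synapse$tau_i, " but preset '", preset$name,
         "' needs tau_e=", preset$tau_e, ", tau_i=", preset$tau_i)
  n <- con$n_regions
  w <- con$weights
  diag(w) <- 0                       # self-input is the local nu_e term
  edges <- which(w > 0, arr.ind = TRUE)
  delay_steps <- as.integer(round(con$tract_lengths[edges] / con$v_c / dt))
  if (any(!is.finite(delay_steps)))
    stop("configuration error: non-finite conduction delays")
  stim_node <- -1L; stim_onset <- 0; stim_dur <- 0; stim_amp <- 0
  if (!is.null(stimulus)) {
    stopifnot(inherits(stimulus, "region_stimulus"),
              stimulus$node <= n)
    stim_node <- stimulus$node - 1L
    stim_onset <- stimulus$onset; stim_dur <- stimulus$duration
    stim_amp <- stimulus$amplitude
  }
  set.seed(seed)
  out <- cpp_simulate_whole_brain(tf_e, tf_i, n,
                                  as.integer(edges[, 1] - 1L),
                                  as.integer(edges[, 2] - 1L),
                                  con$G * w[edges], delay_steps,
                                  preset$b_e, 0, tau_w, tf_e$neuron$E_L,
                                  T_mf, duration, dt, preset$nu_drive,
                                  sigma, 5, stim_node, stim_onset, stim_dur,
                                  stim_amp, as.integer(record_every),
                                  init_rate, init_rate, rate_cap = 400)
  if (out$diverged) stop("whole-brain rate divergence: instability signal")
  k <- out$n_recorded
  structure(list(time = out$time[1:k],
                 nu_e = out$nu_e[1:k, , drop = FALSE],
                 nu_i = out$nu_i[1:k, , drop = FALSE],
                 W = out$W[1:k, , drop = FALSE],
                 sample_ms = record_every * dt,
                 preset = preset, seed = seed, stimulus = stimulus,
                 region_labels = con$region_labels),
            class = "brain_trajectory")
}

#' @export
print.brain_trajectory <- function(x, ...) {
  cat(sprintf("brain_trajectory: %d nodes, %g ms at %g-ms samples, preset '%s', seed %d\n",
              ncol(x$nu_e), max(x$time), x$sample_ms, x$preset$name, x$seed))
  invisible(x)
}

#' Ensemble of whole-brain runs differing only in seed
#'
#' Repeats a whole-brain simulation under a brain-state preset for several
#' noise realizations (the paper-style technical-replicate design).
#'
#' @param con a `connectome`.
#' @param preset `state_preset` or name (`wake`, `propofol`, `NREM`,
#'   `ketamine`).
#' @param tf_e,tf_i fitted `tf` objects for the preset's synapses.
#' @param n_seeds number of realizations.
#' @param duration per-run simulated time (ms).
#' @param base_seed seeds are `base_seed + 0:(n_seeds-1)`.
#' @param ... passed to [simulate_whole_brain()].
#' @return named list of `brain_trajectory`, keyed by seed.
#' @export
run_state_ensemble <- function(con, preset, tf_e, tf_i, n_seeds = 10,
                               duration = 10000, base_seed = 1, ...) {
  if (is.character(preset)) preset <- state_preset(preset)
  seeds <- base_seed + seq_len(n_seeds) - 1L
  out <- lapply(seeds, function(s)
    simulate_whole_brain(con, preset, tf_e, tf_i, duration = duration,
                         seed = s, ...))
  names(out) <- as.character(seeds)
  out
}
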