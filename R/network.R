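#' Configuration of a two-population spiking network
#'
#' A randomly connected (Erdos-Renyi) network of AdEx neurons, 80% RS
#' excitatory and 20% FS inhibitory by default, with connection probability
#' `p_conn` between every ordered pair. External input arrives as a Poisson
#' train representing an afferent population of size `drive_size` firing at
#' `drive_rate`.
#'
#' @param n_total total neuron count.
#' @param frac_inh inhibitory fraction in (0, 1).
#' @param p_conn connection probability in (0, 1].
#' @param drive_rate baseline afferent rate (Hz).
#' @param drive_size afferent population size (number of external synapses
#'   per neuron); `NULL` means `p_conn * n_exc`, the recurrent excitatory
#'   in-degree.
#' @param seed RNG seed used when the adjacency is built.
#' @return list of class `network_config`.
#' @export
network_config <- function(n_total = 10000, frac_inh = 0.2, p_conn = 0.05,
                           drive_rate = 0, drive_size = NULL, seed = 1) {
  stopifnot(n_total >= 2, frac_inh > 0, frac_inh < 1,
            p_conn >= 0, p_conn <= 1, drive_rate >= 0)
  n_inh <- round(n_total * frac_inh)
  n_exc <- n_total - n_inh
  if (is.null(drive_size)) drive_size <- p_conn * n_exc
  structure(list(n_total = n_total, n_exc = n_exc, n_inh = n_inh,
                 frac_inh = frac_inh, p_conn = p_conn,
                 drive_rate = drive_rate, drive_size = drive_size,
                 seed = seed),
            class = "network_config")
}

#' Build the random adjacency of a spiking network
#'
#' Directed Erdos-Renyi graph: every ordered pair (j, k), j != k, is connected
#' independently with probability `p_conn`. Neurons `1..n_exc` are RS
#' (excitatory), the remainder FS (inhibitory). The adjacency is stored in
#' compressed sparse row form over presynaptic neurons.
#'
#' @param cfg a `network_config`.
#' @return list of class `network` with the CSR adjacency (`targets`, `ptr`,
#'   0-based), the population labels `is_inh` and the originating config.
#' @examples
#' net <- build_network(network_config(n_total = 200, seed = 42))
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  set.seed(cfg$seed)
  n <- cfg$n_total
  targets <- vector("list", n)
  if (cfg$p_conn > 0) {
    for (j in seq_len(n)) {
      m <- rbinom(1, n - 1, cfg$p_conn)
      if (m > 0) {
        tg <- sample.int(n - 1, m)       # among the n-1 non-self candidates
        tg <- ifelse(tg >= j, tg + 1L, tg)
        targets[[j]] <- tg - 1L          # 0-based for the compiled core
      } else targets[[j]] <- integer(0)
    }
  } else {
    for (j in seq_len(n)) targets[[j]] <- integer(0)
  }
  lens <- lengths(targets)
  structure(list(targets = unlist(targets, use.names = FALSE),
                 ptr = c(0L, cumsum(lens)),
                 is_inh = seq_len(n) > cfg$n_exc,
                 config = cfg),
            class = "network")
}

#' @export
print.network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("AdEx network: %d neurons (%d RS, %d FS), p=%g, %d synapses\n",
              cfg$n_total, cfg$n_exc, cfg$n_inh, cfg$p_conn,
              length(x$targets)))
  invisible(x)
}

#' External stimulus protocol
#'
#' A square increment of the afferent Poisson rate.
#'
#' @param amplitude stimulus amplitude (Hz, added to the afferent rate).
#' @param onset stimulus onset (ms).
#' @param duration stimulus duration (ms).
#' @return list of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(amplitude = 1, onset = 0, duration = 120) {
  stopifnot(duration > 0, amplitude >= 0, onset >= 0)
  structure(list(amplitude = amplitude, onset = onset, duration = duration),
            class = "stimulus_protocol")
}

#' Simulate a two-population AdEx spiking network
#'
#' Full spiking simulation (forward Euler, exact exponential conductance
#' decay) of the recurrent RS/FS network under a Poissonian external drive.
#' Every neuron receives an independent external Poisson train with total
#' rate `nu_aff(t) * drive_size`, where `nu_aff(t)` is the baseline
#' `drive` plus any stimulus. Initial membrane potentials are drawn uniformly
#' in `[E_L, v_thr]` to avoid synchronisation artifacts.
#'
#' @param net a `network` from [build_network()].
#' @param neuron_e,neuron_i `neuron_params` for RS and FS cells.
#' @param syn a `synapse_params`.
#' @param drive baseline afferent rate (Hz); overrides the config value when
#'   not `NULL`.
#' @param duration simulated time (ms).
#' @param dt integration step (ms).
#' @param stimulus optional `stimulus_protocol` added to the drive.
#' @param seed RNG seed (fixed seed implies a bit-identical record).
#' @param rate_bin width of the population-rate bins (ms).
#' @param record_w record the population-average RS adaptation current
#'   (1-ms samples).
#' @return list of class `spike_record`: `spike_times` (ms), `spike_ids`
#'   (1-based), `rate_e`, `rate_i` (Hz, per `rate_bin`), `rate_bin`, `time`
#'   (bin centres), optionally `w_trace` (pA), and the inputs used.
#' @export
simulate_network <- function(net, neuron_e = neuron_params("RS"),
                             neuron_i = neuron_params("FS"),
                             syn = synapse_params(), drive = NULL,
                             duration = 1000, dt = 0.1, stimulus = NULL,
                             seed = 1, rate_bin = 5, record_w = FALSE) {
  stopifnot(inherits(net, "network"), duration > 0, dt > 0)
  cfg <- net$config
  if (is.null(drive)) drive <- cfg$drive_rate
  nstep <- ceiling(duration / dt)
  ext <- rep(drive, nstep)
  if (!is.null(stimulus)) {
    tt <- (seq_len(nstep) - 1) * dt
    on <- tt >= stimulus$onset & tt < stimulus$onset + stimulus$duration
    ext[on] <- ext[on] + stimulus$amplitude
  }
  set.seed(seed)
  out <- cpp_simulate_network(net$targets, net$ptr, net$is_inh,
                              unclass(neuron_e), unclass(neuron_i),
                              unclass(syn), ext, cfg$drive_size,
                              dt, rate_bin, TRUE, record_w)
  if (!all(is.finite(out$rate_e)))
    stop("non-finite network state: integration failure")
  structure(list(spike_times = out$spike_times,
                 spike_ids = out$spike_ids + 1L,
                 rate_e = out$rate_e, rate_i = out$rate_i,
                 rate_bin = out$rate_bin,
                 time = (seq_along(out$rate_e) - 0.5) * out$rate_bin,
                 w_trace = out$w_trace,
                 is_inh = net$is_inh, duration = duration, seed = seed,
                 drive = drive, stimulus = stimulus),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("spike_record: %d spikes over %g ms; mean rates E=%.2f Hz, I=%.2f Hz\n",
              length(x$spike_times), x$duration,
              mean(x$rate_e), mean(x$rate_i)))
  invisible(x)
}

#' Smoothed population-rate traces
#'
#' Boxcar smoothing of the binned population rates (display helper; analyses
#' use the raw bins).
#'
#' @param rec a `spike_record`.
#' @param width boxcar width (ms).
#' @return data.frame with `time`, `rate_e`, `rate_i`.
#' @export
smoothed_rates <- function(rec, width = 20) {
  k <- max(1, round(width / rec$rate_bin))
  box <- rep(1 / k, k)
  sm <- function(r) as.numeric(stats::filter(r, box, sides = 2))
  data.frame(time = rec$time, rate_e = sm(rec$rate_e), rate_i = sm(rec$rate_i))
}

#' Survival time of network activity after a stimulus
#'
#' Implements the self-sustain protocol: the network starts quiescent (no
#' baseline drive), a short Poisson-rate stimulus kick-starts it, and the
#' time from stimulus offset until the network falls silent is measured. The
#' network is considered extinguished at the start of the first inter-spike
#' gap exceeding 20 ms across both populations; if activity persists to
#' `t_max` the value is censored at `t_max - offset`.
#'
#' @param net a `network`.
#' @param neuron_e,neuron_i,syn model parameters as in [simulate_network()].
#' @param stim a `stimulus_protocol` (must end before `t_max`).
#' @param t_max simulation horizon (ms).
#' @param seed RNG seed.
#' @param gap silent-gap length declaring extinction (ms).
#' @return survival time (ms) with attribute `censored`.
#' @export
survival_time <- function(net, neuron_e = neuron_params("RS"),
                          neuron_i = neuron_params("FS"),
                          syn = synapse_params(),
                          stim = stimulus_protocol(), t_max = 2000,
                          seed = 1, gap = 20) {
  offset <- stim$onset + stim$duration
  stopifnot(offset < t_max)
  rec <- simulate_network(net, neuron_e, neuron_i, syn, drive = 0,
                          duration = t_max, stimulus = stim, seed = seed)
  st <- sort(rec$spike_times[rec$spike_times >= offset])
  if (length(st) == 0) {
    out <- 0
  } else {
    gaps <- diff(c(offset, st, t_max))
    idx <- which(gaps > gap)
    if (length(idx) == 0) {
      out <- t_max - offset
      attr(out, "censored") <- TRUE
      return(out)
    }
    # time of last spike before the first long gap (offset if gap is first)
    out <- c(offset, st)[idx[1]] - offset
  }
  attr(out, "censored") <- FALSE
  out
}

#' Survival-time map over adaptation and synaptic decay
#'
#' Scans the spike-triggered adaptation `b_e` against one synaptic decay time
#' (`tau_e` or `tau_i`), running several stimulation trials per cell and
#' averaging the survival times (censored values enter as `t_max - offset`).
#'
#' @param net a `network` (topology reused across cells and trials).
#' @param b_e_grid adaptation values (pA).
#' @param tau_grid synaptic decay values (ms).
#' @param which_tau `"i"` or `"e"`: which decay time the grid varies.
#' @param trials trials per cell.
#' @param t_max simulation horizon per trial (ms).
#' @param stim stimulation protocol.
#' @param seed base seed; trial seeds are derived deterministically.
#' @param syn baseline `synapse_params` (the non-scanned decay time is taken
#'   from here).
#' @return list of class `survival_map`: `mean` matrix
#'   (length(b_e_grid) x length(tau_grid)), the grids, and the per-trial
#'   array `trials`.
#' @export
scan_survival <- function(net, b_e_grid, tau_grid, which_tau = c("i", "e"),
                          trials = 20, t_max = 2000,
                          stim = stimulus_protocol(), seed = 1,
                          syn = synapse_params()) {
  which_tau <- match.arg(which_tau)
  stopifnot(length(b_e_grid) > 0, length(tau_grid) > 0)
  res <- array(NA_real_, dim = c(length(b_e_grid), length(tau_grid), trials))
  for (it in seq_along(tau_grid)) {
    s <- syn
    if (which_tau == "i") s$tau_i <- tau_grid[it] else s$tau_e <- tau_grid[it]
    for (ib in seq_along(b_e_grid)) {
      ne <- neuron_params("RS", b = b_e_grid[ib])
      for (tr in seq_len(trials)) {
        res[ib, it, tr] <- as.numeric(
          survival_time(net, ne, neuron_params("FS"), s, stim,
                        t_max = t_max,
                        seed = seed + 1000L * (tr - 1L) + 17L * ib + it))
      }
    }
  }
  m <- apply(res, c(1, 2), mean)
  dimnames(m) <- list(b_e = b_e_grid, tau = tau_grid)
  structure(list(mean = m, b_e_grid = b_e_grid, tau_grid = tau_grid,
                 which_tau = which_tau, trials = res, t_max = t_max),
            class = "survival_map")
}

#' Export a spike record as a columnar data frame
#'
#' @param rec a `spike_record`.
#' @return data.frame with `neuron` and `time_ms`, sorted by time.
#' @export
spike_table <- function(rec) {
  data.frame(neuron = rec$spike_ids, time_ms = rec$spike_times)
}
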