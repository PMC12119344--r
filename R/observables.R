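#' Linearized Balloon-Windkessel hemodynamic kernel
#'
#' First-order Volterra kernel of the Balloon-Windkessel hemodynamic model,
#' obtained by integrating the model's ODEs (vasodilatory signal, inflow,
#' venous volume, deoxyhemoglobin) for a small impulse of neural activity and
#' scaling by its amplitude. Standard hemodynamic constants: signal decay
#' kappa = 0.65 1/s, autoregulation gamma = 0.41 1/s, transit time tau0 =
#' 0.98 s, Grubb exponent alpha = 0.32, resting oxygen extraction E0 = 0.34,
#' resting venous volume fraction V0 = 0.04.
#'
#' @param fs sampling rate of the kernel (Hz).
#' @param t_max kernel support (s).
#' @return numeric kernel sampled at `fs`, with attributes `fs` and `time`.
#' @export
bold_kernel <- function(fs = 250, t_max = 25) {
  kappa <- 0.65; gam <- 0.41; tau0 <- 0.98; alpha <- 0.32
  E0 <- 0.34; V0 <- 0.04
  k1 <- 7 * E0; k2 <- 2; k3 <- 2 * E0 - 0.2
  eps <- 1e-4
  deriv <- function(t, y, parms) {
    s <- y[1]; f <- y[2]; v <- y[3]; q <- y[4]
    u <- if (t < 1 / fs) eps * fs else 0      # one-sample impulse of area eps
    Ef <- 1 - (1 - E0)^(1 / f)
    list(c(u - kappa * s - gam * (f - 1),
           s,
           (f - v^(1 / alpha)) / tau0,
           (f * Ef / E0 - v^(1 / alpha) * q / v) / tau0))
  }
  times <- seq(0, t_max, by = 1 / fs)
  sol <- deSolve::ode(y = c(s = 0, f = 1, v = 1, q = 1), times = times,
                      func = deriv, parms = NULL, method = "ode45")
  vq <- sol[, c("v", "q")]
  y <- V0 * (k1 * (1 - vq[, "q"]) + k2 * (1 - vq[, "q"] / vq[, "v"]) +
               k3 * (1 - vq[, "v"]))
  kern <- y / eps
  attr(kern, "fs") <- fs
  attr(kern, "time") <- times
  kern
}

#' BOLD signal from firing-rate traces
#'
#' Downsamples the per-node excitatory rates to 250 Hz (block averaging),
#' convolves each node with the linearized Balloon-Windkessel kernel, and
#' downsamples the result to one sample per repetition time `TR`. The kernel
#' transient (one kernel support) is discarded.
#'
#' @param rates numeric matrix (time x nodes) or vector of firing rates (Hz).
#' @param native_rate sampling rate of `rates` (Hz).
#' @param TR repetition time of the output series (s).
#' @param kernel optional precomputed [bold_kernel()].
#' @return list of class `bold_series`: `bold` (matrix, time x nodes), `TR`,
#'   `time` (s).
#' @export
bold_from_rates <- function(rates, native_rate, TR = 2, kernel = NULL) {
  if (is.null(dim(rates))) rates <- matrix(rates, ncol = 1)
  if (is.null(kernel)) kernel <- bold_kernel()
  fs <- attr(kernel, "fs")
  if (native_rate < fs)
    stop("input error: rate trace sampled below the 250 Hz working rate")
  dec <- round(native_rate / fs)
  nt <- nrow(rates)
  if (nt < dec * length(kernel))
    stop("input error: trace shorter than the hemodynamic kernel support")
  nds <- floor(nt / dec)
  idx <- rep(seq_len(nds), each = dec)
  x <- apply(rates[seq_len(nds * dec), , drop = FALSE], 2,
             function(col) tapply(col, idx, mean))
  conv1 <- function(col) {
    out <- stats::convolve(col, rev(kernel), type = "open")[seq_along(col)]
    out / fs                                    # Riemann sum of the kernel
  }
  y <- apply(x, 2, conv1)
  skip <- length(kernel)                        # kernel-support transient
  y <- y[-seq_len(min(skip, nrow(y) - 1)), , drop = FALSE]
  step <- round(TR * fs)
  keep <- seq(1, nrow(y), by = step)
  structure(list(bold = y[keep, , drop = FALSE], TR = TR,
                 time = (keep - 1) / fs),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("bold_series: %d samples x %d regions, TR=%g s\n",
              nrow(x$bold), ncol(x$bold), x$TR))
  invisible(x)
}

#' Functional connectivity matrix
#'
#' Pearson correlation matrix of the per-region BOLD time series. Regions
#' with zero variance cannot be correlated; they are flagged and returned as
#' `NA` rows/columns with a warning.
#'
#' @param bold a `bold_series` or a numeric matrix (time x regions).
#' @return symmetric correlation matrix with unit diagonal; attribute
#'   `excluded` lists zero-variance regions.
#' @export
functional_connectivity <- function(bold) {
  m <- if (inherits(bold, "bold_series")) bold$bold else as.matrix(bold)
  if (nrow(m) < 2) stop("need at least two time points per region")
  v <- apply(m, 2, stats::var)
  bad <- which(v <= 0 | !is.finite(v))
  fc <- suppressWarnings(stats::cor(m))
  if (length(bad) > 0) {
    warning("zero-variance regions excluded from FC: ",
            paste(bad, collapse = ", "))
    fc[bad, ] <- NA
    fc[, bad] <- NA
  }
  diag(fc) <- 1
  attr(fc, "excluded") <- bad
  fc
}

#' Structure-function correlation
#'
#' Pearson correlation between the off-diagonal upper triangles of the
#' functional and structural connectivity matrices.
#'
#' @param fc functional connectivity matrix.
#' @param sc structural weights matrix (same shape).
#' @return Pearson r.
#' @export
sc_fc_correlation <- function(fc, sc) {
  fc <- as.matrix(fc); sc <- as.matrix(sc)
  if (!all(dim(fc) == dim(sc))) stop("shape mismatch between FC and SC")
  ut <- upper.tri(fc)
  stats::cor(fc[ut], sc[ut], use = "complete.obs")
}

#' Significance-binarize an evoked response
#'
#' Implements the binarization stage of the perturbational-complexity
#' pipeline for one trial. The post-stimulus activity of each region is
#' z-scored against the mean and SD of its own pre-stimulus interval. A null
#' distribution of the maximum absolute z (max-statistic across regions and
#' time, which controls multiplicity) is built from `n_shuffles` surrogate
#' matrices obtained by phase-randomising each region's pre-stimulus trace
#' (amplitude spectrum preserved, so the surrogates keep the autocorrelation
#' structure; a plain circular shift would leave the per-region value sets
#' -- and hence the maximum -- unchanged, making the null degenerate). The
#' threshold is the `1 - alpha` quantile of that null. Entries of the
#' returned matrix `S` (regions x post-stimulus time) are 1 where `|z|`
#' exceeds the threshold.
#'
#' @param trial numeric matrix (time x regions) spanning the pre- and
#'   post-stimulus windows contiguously.
#' @param onset_index first row of the post-stimulus window.
#' @param pre_points,post_points window lengths in samples; default: all
#'   rows before/after `onset_index`.
#' @param n_shuffles surrogates for the null distribution.
#' @param alpha significance level.
#' @param seed RNG seed (binarization is reproducible given inputs + seed).
#' @return list of class `binary_response`: `S` (regions x time, 0/1),
#'   `threshold`, `z` (the post-stimulus z matrix, regions x time),
#'   `excluded` (regions with zero pre-stimulus variance).
#' @export
binarize_response <- function(trial, onset_index, pre_points = NULL,
                              post_points = NULL, n_shuffles = 500,
                              alpha = 0.05, seed = 1) {
  trial <- as.matrix(trial)
  nt <- nrow(trial); nr <- ncol(trial)
  if (is.null(pre_points)) pre_points <- onset_index - 1
  if (is.null(post_points)) post_points <- nt - onset_index + 1
  stopifnot(pre_points >= 10, post_points >= 1,
            onset_index + post_points - 1 <= nt)
  pre <- trial[(onset_index - pre_points):(onset_index - 1), , drop = FALSE]
  post <- trial[onset_index:(onset_index + post_points - 1), , drop = FALSE]
  mu <- colMeans(pre)
  sd0 <- apply(pre, 2, stats::sd)
  excluded <- which(sd0 <= 0 | !is.finite(sd0))
  ok <- setdiff(seq_len(nr), excluded)
  if (length(ok) == 0) stop("all regions have zero pre-stimulus variance")
  z <- sweep(sweep(post[, ok, drop = FALSE], 2, mu[ok]), 2, sd0[ok], "/")
  zpre <- sweep(sweep(pre[, ok, drop = FALSE], 2, mu[ok]), 2, sd0[ok], "/")
  set.seed(seed)
  npre <- nrow(zpre)
  fts <- apply(zpre, 2, stats::fft)
  phase_surrogate <- function(ft) {
    n <- length(ft)
    half <- floor((n - 1) / 2)
    ph <- stats::runif(half, 0, 2 * pi)
    rot <- rep(1 + 0i, n)
    rot[2:(half + 1)] <- exp(1i * ph)
    rot[n:(n - half + 1)] <- Conj(rot[2:(half + 1)])
    Re(stats::fft(ft * rot, inverse = TRUE)) / n
  }
  null_max <- vapply(seq_len(n_shuffles), function(s) {
    max(abs(vapply(seq_along(ok), function(j) phase_surrogate(fts[, j]),
                   numeric(npre))))
  }, numeric(1))
  thr <- stats::quantile(null_max, 1 - alpha, names = FALSE, type = 8)
  S <- matrix(0L, nr, post_points)
  S[ok, ] <- t(abs(z) > thr) * 1L
  structure(list(S = S, threshold = thr, z = t(z), ok_regions = ok,
                 excluded = excluded, alpha = alpha,
                 n_shuffles = n_shuffles),
            class = "binary_response")
}

#' Lempel-Ziv (LZ76) complexity of a binary matrix
#'
#' Number of phrases in the LZ76 exhaustive history of the binary sequence
#' obtained by scanning the matrix region-major (each region's time course
#' concatenated in row order). Vectors are scanned as given.
#'
#' @param S binary matrix (regions x time) or binary vector.
#' @return integer phrase count.
#' @examples
#' lempel_ziv_complexity(rep(0, 100))  # 2
#' @export
lempel_ziv_complexity <- function(S) {
  if (is.matrix(S)) S <- as.integer(t(S))   # row-major = region-major scan
  S <- as.integer(S)
  if (length(S) == 0) stop("empty sequence")
  if (!all(S %in% c(0L, 1L))) stop("sequence must be binary")
  cpp_lz76(S)
}

#' Spatial source entropy of a binary response
#'
#' Binary entropy of the fraction of ones:
#' \eqn{H(S) = -p_0\log_2 p_0 - p_1\log_2 p_1}, with \eqn{0\log 0 := 0}.
#'
#' @param S binary matrix or vector.
#' @return entropy in bits per sample.
#' @export
source_entropy <- function(S) {
  s <- as.integer(S)
  if (length(s) == 0) stop("empty sequence")
  p1 <- mean(s)
  p0 <- 1 - p1
  h <- 0
  if (p0 > 0) h <- h - p0 * log2(p0)
  if (p1 > 0) h <- h - p1 * log2(p1)
  h
}

#' Perturbational complexity of binarized responses
#'
#' Combines binarization, LZ76 complexity and source entropy into the
#' perturbational complexity index for each trial:
#' \deqn{PCI = \frac{LZ(S)\,\log_2 L / L}{H(S)}}
#' where `L` is the number of binary samples -- the LZ count is normalised by
#' its asymptotic value for a random sequence so that values are comparable
#' across trial lengths, then divided by the source entropy. The raw
#' (unnormalised) ratio `LZ/H` is reported alongside. A trial with no
#' significant samples (or fully saturated ones) has H = 0 and its PCI is
#' undefined: it is returned as `NA` and counted in `n_undefined` rather than
#' silently zeroed.
#'
#' @param trials list of trial matrices (time x regions), or a single matrix.
#' @param onset_index first post-stimulus row (shared across trials).
#' @param n_shuffles,alpha,seed passed to [binarize_response()] (per-trial
#'   seeds derived from `seed`).
#' @param ... further arguments to [binarize_response()].
#' @return list of class `pci_result`: per-trial vectors `pci`, `lz`,
#'   `lz_normalized`, `entropy`, `p1`, `pci_raw`, plus `n_undefined` and the
#'   settings.
#' @export
compute_pci <- function(trials, onset_index, n_shuffles = 500, alpha = 0.05,
                        seed = 1, ...) {
  if (!is.list(trials)) trials <- list(trials)
  stopifnot(length(trials) >= 1)
  res <- lapply(seq_along(trials), function(i) {
    br <- binarize_response(trials[[i]], onset_index,
                            n_shuffles = n_shuffles, alpha = alpha,
                            seed = seed + i - 1L, ...)
    S <- br$S
    L <- length(S)
    H <- source_entropy(S)
    if (H == 0)
      return(list(pci = NA_real_, lz = NA_real_, lzn = NA_real_,
                  H = H, p1 = mean(S), raw = NA_real_))
    lz <- lempel_ziv_complexity(S)
    lzn <- lz * log2(L) / L
    list(pci = lzn / H, lz = lz, lzn = lzn, H = H, p1 = mean(S),
         raw = lz / H)
  })
  pci <- vapply(res, `[[`, numeric(1), "pci")
  structure(list(pci = pci,
                 lz = vapply(res, `[[`, numeric(1), "lz"),
                 lz_normalized = vapply(res, `[[`, numeric(1), "lzn"),
                 entropy = vapply(res, `[[`, numeric(1), "H"),
                 p1 = vapply(res, `[[`, numeric(1), "p1"),
                 pci_raw = vapply(res, `[[`, numeric(1), "raw"),
                 n_undefined = sum(is.na(pci)),
                 alpha = alpha, n_shuffles = n_shuffles, seed = seed),
            class = "pci_result")
}

#' @export
print.pci_result <- function(x, ...) {
  ok <- !is.na(x$pci)
  cat(sprintf("pci_result: %d trials (%d undefined); median PCI %.3f\n",
              length(x$pci), x$n_undefined,
              if (any(ok)) stats::median(x$pci[ok]) else NA))
  invisible(x)
}

#' Evoked-response trials from the whole-brain model
#'
#' Runs the stimulation protocol behind the perturbational complexity index:
#' for each seed, the whole-brain model is simulated under the given preset,
#' a square-wave stimulus (1 Hz, 50 ms) is applied to the excitatory
#' population of one region after a settling period, and the excitatory rates
#' in a window around the stimulus are returned.
#'
#' @param con a `connectome`.
#' @param preset `state_preset` or name.
#' @param tf_e,tf_i fitted `tf` objects matching the preset's synapses.
#' @param n_trials number of noise realizations.
#' @param stim_node stimulated region (default 1, standing in for a frontal
#'   node of the parcellation).
#' @param window pre/post window length (ms).
#' @param settle settling time before the stimulus (ms).
#' @param base_seed first seed.
#' @param record_every recording stride in integration steps (default 10 =
#'   1-ms samples at dt = 0.1 ms).
#' @param ... passed to [simulate_whole_brain()].
#' @return list with `trials` (list of time x regions matrices spanning
#'   `[-window, +window]` around onset) and `onset_index`.
#' @export
evoked_trials <- function(con, preset, tf_e, tf_i, n_trials = 10,
                          stim_node = 1, window = 300, settle = 2000,
                          base_seed = 1, record_every = 10, ...) {
  if (is.character(preset)) preset <- state_preset(preset)
  onset <- settle + window
  dur <- onset + window + 10
  trials <- lapply(seq_len(n_trials), function(i) {
    tr <- simulate_whole_brain(con, preset, tf_e, tf_i, duration = dur,
                               stimulus = region_stimulus(stim_node,
                                                          amplitude = 1,
                                                          onset = onset,
                                                          duration = 50),
                               seed = base_seed + i - 1L,
                               record_every = record_every, ...)
    keep <- tr$time >= onset - window & tr$time < onset + window
    tr$nu_e[keep, , drop = FALSE]
  })
  onset_index <- window / (record_every * 0.1) + 1
  list(trials = trials, onset_index = as.integer(round(onset_index)),
       stim_node = stim_node, window = window)
}
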