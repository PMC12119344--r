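#' Conductance moments under Poissonian input
#'
#' Mean and standard deviation of the synaptic conductances received by a
#' neuron whose excitatory/inhibitory presynaptic populations fire at
#' `nu_e`/`nu_i` with in-degrees `K_e`/`K_i`, assuming Poissonian spike
#' statistics: \eqn{\mu_{Gs} = \nu_s K_s \tau_s Q_s},
#' \eqn{\sigma_{Gs} = \sqrt{\nu_s K_s \tau_s^2 Q_s}}.
#'
#' @param nu_e,nu_i presynaptic rates (Hz); vectorised.
#' @param syn a `synapse_params`.
#' @param K_e,K_i synaptic in-degrees.
#' @return data.frame with `mu_Ge`, `mu_Gi`, `sigma_Ge`, `sigma_Gi` (nS).
#' @examples
#' conductance_moments(1, 1, synapse_params())$mu_Ge  # 3 nS
#' @export
conductance_moments <- function(nu_e, nu_i, syn = synapse_params(),
                                K_e = 400, K_i = 100) {
  if (any(nu_e < 0) || any(nu_i < 0)) stop("rates must be non-negative")
  ne <- nu_e * 1e-3  # 1/ms
  ni <- nu_i * 1e-3
  data.frame(
    mu_Ge = ne * K_e * syn$tau_e * syn$Q_e,
    mu_Gi = ni * K_i * syn$tau_i * syn$Q_i,
    sigma_Ge = sqrt(ne * K_e * syn$tau_e^2 * syn$Q_e),
    sigma_Gi = sqrt(ni * K_i * syn$tau_i^2 * syn$Q_i))
}

#' Membrane fluctuation statistics
#'
#' Gaussian characterisation of the subthreshold membrane potential under
#' Poissonian conductance bombardment: total mean conductance
#' \eqn{\mu_G = \mu_{Ge} + \mu_{Gi} + g_L}, effective membrane time
#' \eqn{\tau_m^{eff} = C_m/\mu_G}, mean voltage
#' \eqn{\mu_V = (\mu_{Ge} E_e + \mu_{Gi} E_i + g_L E_L - W)/\mu_G}, and the
#' shot-noise voltage SD and autocorrelation time built from the single-event
#' voltage jumps \eqn{U_s = (Q_s/\mu_G)(E_s - \mu_V)}.
#'
#' @param nu_e,nu_i presynaptic rates (Hz); vectorised.
#' @param W adaptation current (pA); vectorised.
#' @param neuron a `neuron_params`.
#' @param syn a `synapse_params`.
#' @param K_e,K_i synaptic in-degrees.
#' @return data.frame with `mu_Ge`, `mu_Gi`, `sigma_Ge`, `sigma_Gi`, `mu_G`
#'   (nS), `tau_m_eff` (ms), `mu_V` (mV), `sigma_V` (mV), `tau_V` (ms) and
#'   the dimensionless `tau_V_N = tau_V g_L / C_m`.
#' @examples
#' membrane_stats(0, 0, 0, neuron_params("RS"), synapse_params())
#' @export
membrane_stats <- function(nu_e, nu_i, W = 0, neuron = neuron_params("RS"),
                           syn = synapse_params(), K_e = 400, K_i = 100) {
  if (any(nu_e < 0) || any(nu_i < 0)) stop("rates must be non-negative")
  n <- max(length(nu_e), length(nu_i), length(W))
  nu_e <- rep_len(nu_e, n); nu_i <- rep_len(nu_i, n); W <- rep_len(W, n)
  cm <- conductance_moments(nu_e, nu_i, syn, K_e, K_i)
  mu_G <- cm$mu_Ge + cm$mu_Gi + neuron$g_L
  tau_m <- neuron$c_m / mu_G
  mu_V <- (cm$mu_Ge * syn$E_e + cm$mu_Gi * syn$E_i +
             neuron$g_L * neuron$E_L - W) / mu_G
  U_e <- (syn$Q_e / mu_G) * (syn$E_e - mu_V)
  U_i <- (syn$Q_i / mu_G) * (syn$E_i - mu_V)
  ne <- nu_e * 1e-3; ni <- nu_i * 1e-3
  a_e <- K_e * ne * (U_e * syn$tau_e)^2
  a_i <- K_i * ni * (U_i * syn$tau_i)^2
  sigma_V <- sqrt(a_e / (2 * (tau_m + syn$tau_e)) +
                  a_i / (2 * (tau_m + syn$tau_i)))
  den <- a_e / (tau_m + syn$tau_e) + a_i / (tau_m + syn$tau_i)
  tau_V <- ifelse(den > 0, (a_e + a_i) / den, tau_m)
  cbind(cm, data.frame(mu_G = mu_G, tau_m_eff = tau_m, mu_V = mu_V,
                       sigma_V = sigma_V, tau_V = tau_V,
                       tau_V_N = tau_V * neuron$g_L / neuron$c_m))
}

#' Transfer-function coefficient container
#'
#' Bundles the fitted effective-threshold polynomial with everything needed
#' to evaluate the semi-analytic transfer function: the single-cell and
#' synaptic constants, the synaptic in-degrees and the fiducial normalisation
#' of the fluctuation variables.
#'
#' @param coefficients numeric(10), ordered `P0, P_mu, P_sig, P_tau, P_mumu,
#'   P_musig, P_mutau, P_sigsig, P_sigtau, P_tautau`.
#' @param neuron a `neuron_params`.
#' @param syn a `synapse_params`.
#' @param K_e,K_i synaptic in-degrees.
#' @param fiducials numeric(6): `mu_V0, dmu_V0, sigma_V0, dsigma_V0, tau_VN0,
#'   dtau_VN0` (mV / mV / dimensionless).
#' @param fit optional list of fit diagnostics.
#' @return list of class `tf`.
#' @export
tf_coefficients <- function(coefficients, neuron, syn, K_e = 400, K_i = 100,
                            fiducials = tf_fiducials(), fit = NULL) {
  coefficients <- as.numeric(coefficients)
  stopifnot(length(coefficients) == 10, all(is.finite(coefficients)),
            length(fiducials) == 6, all(fiducials[c(2, 4, 6)] != 0))
  names(coefficients) <- c("P0", "P_mu", "P_sig", "P_tau", "P_mumu",
                           "P_musig", "P_mutau", "P_sigsig", "P_sigtau",
                           "P_tautau")
  structure(list(coefficients = coefficients, neuron = unclass(neuron),
                 synapse = unclass(syn), K_e = K_e, K_i = K_i,
                 fiducials = fiducials, fit = fit),
            class = "tf")
}

#' Fiducial normalisation constants of the fluctuation regime
#'
#' @return named numeric(6): `mu_V0` = -60 mV, `dmu_V0` = 0.001 mV,
#'   `sigma_V0` = 0.004 mV, `dsigma_V0` = 0.006 mV, `tau_VN0` = 0.5,
#'   `dtau_VN0` = 1. These only define the coordinate system in which the
#'   threshold polynomial lives; fitting and evaluation use the same set.
#' @export
tf_fiducials <- function() {
  c(mu_V0 = -60, dmu_V0 = 0.001, sigma_V0 = 0.004, dsigma_V0 = 0.006,
    tau_VN0 = 0.5, dtau_VN0 = 1)
}

#' @export
print.tf <- function(x, ...) {
  cat(sprintf("Semi-analytic transfer function (%s cell), K_e=%g, K_i=%g\n",
              x$neuron$type, x$K_e, x$K_i))
  cat("  P0 =", signif(x$coefficients[1], 4), "mV\n")
  if (!is.null(x$fit))
    cat(sprintf("  fit: RMS error %.3f Hz over %d grid points\n",
                x$fit$rms, x$fit$n_points))
  invisible(x)
}

tf_scaled_vars <- function(mu_V, sigma_V, tau_V_N, fid) {
  cbind((mu_V - fid[1]) / fid[2],
        (sigma_V - fid[3]) / fid[4],
        (tau_V_N - fid[5]) / fid[6])
}

tf_design <- function(x) {
  cbind(1, x[, 1], x[, 2], x[, 3],
        x[, 1]^2, x[, 1] * x[, 2], x[, 1] * x[, 3],
        x[, 2]^2, x[, 2] * x[, 3], x[, 3]^2)
}

#' Effective spike threshold (second-order polynomial)
#'
#' Evaluates the phenomenological threshold
#' \eqn{V_{thr}^{eff} = P_0 + \sum_x P_x \tilde x + \sum_{xy} P_{xy} \tilde x
#' \tilde y} in the normalised fluctuation coordinates
#' \eqn{\tilde x = (x - x_0)/\delta x_0}.
#'
#' @param mu_V,sigma_V,tau_V_N fluctuation statistics (mV, mV,
#'   dimensionless); vectorised.
#' @param coeffs a `tf` object (its coefficients and fiducials are used).
#' @return effective threshold (mV).
#' @export
effective_threshold <- function(mu_V, sigma_V, tau_V_N, coeffs) {
  stopifnot(inherits(coeffs, "tf"))
  if (!all(is.finite(c(mu_V, sigma_V, tau_V_N))))
    stop("non-finite fluctuation statistics")
  X <- tf_design(tf_scaled_vars(mu_V, sigma_V, tau_V_N, coeffs$fiducials))
  as.numeric(X %*% coeffs$coefficients)
}

#' Semi-analytic transfer function: output rate
#'
#' Composes the fluctuation statistics, the fitted effective threshold and
#' the Gaussian first-passage formula
#' \eqn{\nu_{out} = \frac{1}{2\tau_V}\,\mathrm{Erfc}\!\left(
#' \frac{V_{thr}^{eff} - \mu_V}{\sqrt{2}\sigma_V}\right)}. The output is
#' bounded by \eqn{1/\tau_V} and is zero in the zero-fluctuation limit.
#'
#' @param tf a `tf` object.
#' @param nu_e,nu_i presynaptic rates (Hz); vectorised. Negative values are
#'   rejected.
#' @param W adaptation current (pA).
#' @return output firing rate (Hz).
#' @export
transfer_rate <- function(tf, nu_e, nu_i, W = 0) {
  stopifnot(inherits(tf, "tf"))
  if (any(nu_e < 0) || any(nu_i < 0)) stop("rates must be non-negative")
  n <- max(length(nu_e), length(nu_i), length(W))
  st <- membrane_stats(rep_len(nu_e, n), rep_len(nu_i, n), rep_len(W, n),
                       tf$neuron, tf$synapse, tf$K_e, tf$K_i)
  if (any(st$tau_V <= 0)) stop("non-positive tau_V: numerical domain error")
  out <- numeric(n)
  ok <- st$sigma_V > 1e-10
  if (any(ok)) {
    veff <- effective_threshold(st$mu_V[ok], st$sigma_V[ok], st$tau_V_N[ok], tf)
    z <- (veff - st$mu_V[ok]) / (sqrt(2) * st$sigma_V[ok])
    # Erfc via the normal tail: erfc(z) = 2*pnorm(-sqrt(2) z)
    out[ok] <- pmax(0, 1e3 * (0.5 / st$tau_V[ok]) * 2 *
                      stats::pnorm(-sqrt(2) * z))
  }
  out
}

erfcinv <- function(x) -stats::qnorm(x / 2) / sqrt(2)

#' Fit the transfer function of one cell type
#'
#' Simulates a single neuron under Poissonian conductance bombardment on a
#' log-spaced grid of presynaptic rates crossed with a grid of clamped
#' adaptation currents, measures the stationary output rate, and fits the
#' ten coefficients of the effective-threshold polynomial so that the Erfc
#' template reproduces the measurements. Two stages: (1) the measured rates
#' are inverted through the Erfc formula to effective thresholds and fitted
#' by linear least squares; (2) the coefficients are refined by nonlinear
#' least squares on the rates, with square-root (variance-stabilising)
#' residuals so that the Poisson-limited low-rate region -- which controls
#' the network's bistability structure -- is weighted on equal footing with
#' the high-rate region.
#'
#' The adaptation current is clamped during the grid simulations (it enters
#' the membrane equation exactly like a constant current), so its effect on
#' the output rate is sampled rather than extrapolated; at evaluation time
#' the mean-field supplies whatever `W` its dynamics produce and the
#' template's dependence goes through the mean-voltage equation.
#'
#' @param neuron a `neuron_params` (fit is per cell type).
#' @param syn a `synapse_params`.
#' @param K_e,K_i synaptic in-degrees (defaults: 0.05 x 8000 and 0.05 x 2000).
#' @param rate_grid list with `nu_e` and `nu_i` grid vectors (Hz); default
#'   12 x 12 log-spaced in [0.1, 50] Hz.
#' @param W_grid clamped adaptation currents (pA); default `0` for cells
#'   without adaptation (FS), `c(0, 40, 80, 160)` otherwise.
#' @param sim_duration measured time per grid point (ms), after `discard`.
#'   Points firing below 25 Hz are re-measured with an extended duration
#'   targeting `min_spikes` events (capped at `max_duration`): the low-rate
#'   knee of the transfer function controls the network's bistability
#'   structure, so its measurement noise is kept at the few-percent level.
#' @param min_spikes spike-count target for the adaptive extension.
#' @param max_duration cap on the extended measurement (ms).
#' @param discard transient excluded from measurement (ms).
#' @param dt integration step (ms).
#' @param seed RNG seed for the grid simulations.
#' @param measurements optional data.frame with columns `nu_e`, `nu_i`, `W`
#'   and `rate` (Hz): fit these precomputed rates instead of simulating
#'   (used e.g. for self-consistency checks).
#' @return a `tf` object with fit diagnostics (`rms` in Hz, `n_points`,
#'   `measured`, `predicted`, grid, seed).
#' @export
fit_transfer_function <- function(neuron, syn = synapse_params(),
                                  K_e = 400, K_i = 100, rate_grid = NULL,
                                  W_grid = NULL,
                                  sim_duration = 20000, min_spikes = 1000,
                                  max_duration = 300000, discard = 1000,
                                  dt = 0.1, seed = 1, measurements = NULL) {
  if (!is.null(measurements)) {
    stopifnot(all(c("nu_e", "nu_i", "W", "rate") %in% names(measurements)))
    grid <- measurements[c("nu_e", "nu_i", "W")]
    meas <- measurements$rate
  } else {
    if (is.null(rate_grid))
      rate_grid <- list(nu_e = exp(seq(log(0.1), log(50), length.out = 12)),
                        nu_i = exp(seq(log(0.1), log(50), length.out = 12)))
    if (is.null(W_grid))
      W_grid <- if (neuron$type == "FS") 0 else c(0, 40, 80, 160)
    grid <- expand.grid(nu_e = rate_grid$nu_e, nu_i = rate_grid$nu_i,
                        W = W_grid)
    set.seed(seed)
    sim_point <- function(i, dur) {
      cpp_single_neuron(unclass(neuron), unclass(syn),
                        rate_e = grid$nu_e[i] * K_e,
                        rate_i = grid$nu_i[i] * K_i,
                        duration = dur + discard, dt = dt, discard = discard,
                        w_init = grid$W[i], clamp_w = TRUE)
    }
    first <- lapply(seq_len(nrow(grid)), sim_point, dur = sim_duration)
    meas <- vapply(seq_len(nrow(grid)), function(i) {
      r <- first[[i]]
      if (r$rate > 0.001 && r$rate < 25 && r$n_spikes < min_spikes) {
        extra <- min(max_duration,
                     ceiling(1e3 * min_spikes / max(r$rate, 0.5)))
        r2 <- sim_point(i, extra)
        # pool both measurements: total spikes over total time
        (r$n_spikes + r2$n_spikes) / ((sim_duration + extra) * 1e-3)
      } else r$rate
    }, numeric(1))
  }
  st <- membrane_stats(grid$nu_e, grid$nu_i, grid$W, neuron, syn, K_e, K_i)
  X <- tf_design(tf_scaled_vars(st$mu_V, st$sigma_V, st$tau_V_N,
                                tf_fiducials()))

  # stage 1: invert the Erfc formula where defined, linear least squares
  arg <- 2 * st$tau_V * meas * 1e-3            # in (0, 2)
  ok <- meas > 0.05 & arg < 1.999 & st$sigma_V > 1e-10
  if (sum(ok) < 12) stop("fit failure: too few active grid points")
  veff_data <- st$mu_V[ok] + sqrt(2) * st$sigma_V[ok] * erfcinv(arg[ok])
  p0 <- tryCatch(stats::lm.fit(X[ok, , drop = FALSE], veff_data)$coefficients,
                 error = function(e) stop("fit failure: singular design matrix"))
  p0[!is.finite(p0)] <- 0

  # stage 2: nonlinear refinement on the rates. Residuals on log(1 + rate):
  # relative errors, so the fluctuation-driven low-rate regime (which sets
  # the bistability structure) is not dominated by the mean-driven
  # high-rate corner where the Erfc template is only approximate.
  predict_rates <- function(p) {
    veff <- as.numeric(X %*% p)
    z <- (veff - st$mu_V) / (sqrt(2) * st$sigma_V)
    ifelse(st$sigma_V > 1e-10,
           pmax(0, 1e3 * (0.5 / st$tau_V) * 2 * stats::pnorm(-sqrt(2) * z)),
           0)
  }
  fit2 <- minpack.lm::nls.lm(par = p0,
                             fn = function(p) log1p(predict_rates(p)) - log1p(meas),
                             control = minpack.lm::nls.lm.control(maxiter = 300))
  p <- fit2$par
  pred <- predict_rates(p)
  rms <- sqrt(mean((pred - meas)^2))
  tf_coefficients(p, neuron, syn, K_e, K_i,
                  fit = list(rms = rms, n_points = nrow(grid),
                             measured = meas, predicted = pred,
                             grid = grid, seed = seed,
                             sim_duration = sim_duration))
}

#' Serialise a fitted transfer function to JSON
#'
#' @param tf a `tf` object.
#' @param path output file.
#' @export
write_tf_json <- function(tf, path) {
  stopifnot(inherits(tf, "tf"))
  obj <- list(coefficients = as.list(tf$coefficients),
              fiducials = as.list(tf$fiducials),
              neuron = tf$neuron, synapse = tf$synapse,
              K_e = tf$K_e, K_i = tf$K_i,
              fit = if (!is.null(tf$fit))
                list(rms = tf$fit$rms, n_points = tf$fit$n_points,
                     seed = tf$fit$seed))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a transfer function from JSON
#'
#' @param path file written by [write_tf_json()].
#' @return a `tf` object.
#' @export
read_tf_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  neuron <- structure(as.list(obj$neuron), class = "neuron_params")
  syn <- structure(as.list(obj$synapse), class = "synapse_params")
  tf_coefficients(unlist(obj$coefficients), neuron, syn,
                  K_e = obj$K_e, K_i = obj$K_i,
                  fiducials = unlist(obj$fiducials),
                  fit = obj$fit)
}
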