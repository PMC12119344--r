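#' Ornstein-Uhlenbeck afferent-noise trace
#'
#' Euler-Maruyama path of the OU process
#' \eqn{d\xi = -\xi\,dt/\tau_{OU} + dW_t} (unit-amplitude Wiener process,
#' time measured in seconds, so the stationary SD of \eqn{\xi} is
#' \eqn{\sqrt{\tau_{OU}/2}} with \eqn{\tau_{OU}} in seconds). The afferent
#' rate is \eqn{\nu_{aff}(t) = \nu_{drive} + \sigma \xi(t)}, clipped at zero
#' (rates cannot be negative).
#'
#' @param nu_drive mean afferent rate (Hz).
#' @param sigma noise amplitude (Hz per unit \eqn{\xi}).
#' @param tau_OU OU time constant (ms).
#' @param duration trace length (ms).
#' @param dt time step (ms); must be much smaller than `tau_OU`.
#' @param seed optional RNG seed.
#' @return data.frame with `time` (ms), `xi` (the raw OU path) and `nu_aff`
#'   (Hz, clipped).
#' @export
ou_noise <- function(nu_drive, sigma = 3.5, tau_OU = 5, duration = 1000,
                     dt = 0.1, seed = NULL) {
  stopifnot(tau_OU > 0, sigma >= 0, dt < tau_OU)
  if (!is.null(seed)) set.seed(seed)
  n <- ceiling(duration / dt)
  eta <- stats::rnorm(n, sd = sqrt(dt * 1e-3))
  xi <- numeric(n + 1)
  decay <- dt / tau_OU
  for (k in seq_len(n)) xi[k + 1] <- xi[k] - xi[k] * decay + eta[k]
  data.frame(time = (0:n) * dt, xi = xi,
             nu_aff = pmax(0, nu_drive + sigma * xi))
}

#' Parameters of a mean-field module
#'
#' @param T_mf relaxation time constant of the population rates (ms).
#' @param b_e,a_e spike-triggered (pA) and subthreshold (nS) adaptation of
#'   the excitatory population.
#' @param tau_w adaptation time constant (ms).
#' @param N_e,N_i population sizes (enter the finite-size term of the
#'   second-order covariance dynamics).
#' @param nu_drive,sigma,tau_OU afferent drive: mean rate (Hz), OU amplitude
#'   and OU time constant (ms).
#' @return list of class `mean_field_params`.
#' @export
mean_field_params <- function(T_mf = 5, b_e = 5, a_e = 0, tau_w = 500,
                              N_e = 8000, N_i = 2000,
                              nu_drive = 0.4, sigma = 3.5, tau_OU = 5) {
  stopifnot(T_mf > 0, tau_w > 0, tau_OU > 0, sigma >= 0, nu_drive >= 0)
  structure(list(T_mf = T_mf, b_e = b_e, a_e = a_e, tau_w = tau_w,
                 N_e = N_e, N_i = N_i, nu_drive = nu_drive, sigma = sigma,
                 tau_OU = tau_OU),
            class = "mean_field_params")
}

#' Simulate the two-population mean-field model
#'
#' Integrates the rate equations
#' \eqn{T\,\dot\nu_e = F_e(\nu_e + \nu_{aff}, \nu_i, W) - \nu_e},
#' \eqn{T\,\dot\nu_i = F_i(\nu_e + \nu_{aff}, \nu_i) - \nu_i},
#' \eqn{\dot W = -W/\tau_w + b\,\nu_e}
#' with forward Euler (Euler-Maruyama for the OU drive). At `order = 2` the
#' rate covariances are evolved as well and the rate equations carry the
#' curvature correction \eqn{\frac12 c_{\lambda\eta}\,\partial^2 F /
#' \partial\nu_\lambda\partial\nu_\eta} (second derivatives by central finite
#' differences, step 0.01 Hz); the finite-size source term scales as
#' \eqn{1/N_\lambda}, so the second-order trajectory converges to the
#' first-order one as the populations grow.
#'
#' @param params a `mean_field_params`.
#' @param tf_e,tf_i fitted `tf` objects for the excitatory and inhibitory
#'   populations. `b_e` of `params` overrides the adaptation scenario (the
#'   TF itself is fitted once per cell type).
#' @param duration simulated time (ms).
#' @param dt integration step (ms).
#' @param order 1 (rates + adaptation) or 2 (adds covariances).
#' @param seed RNG seed.
#' @param record_every record every this many steps.
#' @param init named list with optional `nu_e`, `nu_i`, `W` initial values.
#' @return data.frame of class `mean_field_trajectory` with `time` (ms),
#'   `nu_e`, `nu_i` (Hz), `W` (pA), `nu_aff`, and at order 2 `c_ee`, `c_ei`,
#'   `c_ii` (Hz^2).
#' @export
simulate_mean_field <- function(params, tf_e, tf_i, duration = 10000,
                                dt = 0.1, order = 1, seed = 1,
                                record_every = 10,
                                init = list(nu_e = 1, nu_i = 5, W = 0)) {
  stopifnot(inherits(params, "mean_field_params"),
            inherits(tf_e, "tf"), inherits(tf_i, "tf"),
            order %in% c(1, 2), duration > 0, dt > 0)
  set.seed(seed)
  out <- cpp_simulate_mean_field(tf_e, tf_i, params$b_e, params$a_e,
                                 params$tau_w, tf_e$neuron$E_L, params$T_mf,
                                 duration, dt, params$nu_drive, params$sigma,
                                 params$tau_OU, as.integer(order),
                                 params$N_e, params$N_i,
                                 as.integer(record_every),
                                 init$nu_e %||% 1, init$nu_i %||% 5,
                                 init$W %||% 0, rate_cap = 400)
  if (out$diverged)
    stop("mean-field rate divergence: instability signal")
  n <- out$n_recorded
  df <- data.frame(time = out$time[1:n], nu_e = out$nu_e[1:n],
                   nu_i = out$nu_i[1:n], W = out$W[1:n],
                   nu_aff = out$nu_aff[1:n])
  if (order == 2) {
    df$c_ee <- out$c_ee[1:n]; df$c_ei <- out$c_ei[1:n]; df$c_ii <- out$c_ii[1:n]
  }
  class(df) <- c("mean_field_trajectory", class(df))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stationary inhibitory rate given the excitatory rate
#'
#' Solves the scalar self-consistency \eqn{\bar\nu_i = F_i(\nu_e, \bar\nu_i)}
#' (the first-order inhibitory nullcline) by bracketing and bisection, with a
#' damped fixed-point fallback.
#'
#' @param tf_i inhibitory `tf`.
#' @param nu_e excitatory rate (Hz), scalar.
#' @param tol convergence tolerance (Hz).
#' @param nu_max upper bracket (Hz).
#' @return the stationary inhibitory rate (Hz).
#' @export
stationary_inhibitory <- function(tf_i, nu_e, tol = 1e-8, nu_max = 500) {
  stopifnot(nu_e >= 0)
  g <- function(nu_i) cpp_tf_rate(tf_i, nu_e, nu_i, 0) - nu_i
  g0 <- g(0)
  if (g0 <= 0) return(0)
  if (g(nu_max) >= 0)
    stop("root failure: inhibitory nullcline not bracketed by [0, nu_max]")
  r <- stats::uniroot(g, c(0, nu_max), tol = tol)
  root <- r$root
  if (abs(g(root)) > 1e-6) {
    for (k in 1:200) {              # damped fallback
      step <- g(root)
      root <- max(0, root + 0.5 * step)
      if (abs(step) < tol) break
    }
    if (abs(g(root)) > 1e-6) stop("root failure: no convergence")
  }
  root
}

#' The one-dimensional fixed-point map H
#'
#' Evaluates \eqn{H(\nu_e) = F_e(\nu_e, \bar\nu_i(\nu_e), W)} with the
#' inhibitory population at its stationary rate and the adaptation current at
#' equilibrium, \eqn{W = b_e\,\nu_e\,\tau_w}. No external input acts on the
#' system; fixed points of the autonomous network are the intersections of
#' `H` with the bisector.
#'
#' @param nu_e excitatory rate(s) (Hz).
#' @param tf_e,tf_i fitted `tf` objects.
#' @param b_e spike-triggered adaptation (pA).
#' @param tau_w adaptation time constant (ms).
#' @return H(nu_e) (Hz), same length as `nu_e`.
#' @export
h_function <- function(nu_e, tf_e, tf_i, b_e, tau_w = 500) {
  vapply(nu_e, function(ne) {
    ni <- stationary_inhibitory(tf_i, ne)
    W <- b_e * ne * 1e-3 * tau_w
    cpp_tf_rate(tf_e, ne, ni, W)
  }, numeric(1))
}

#' Locate the fixed points of the mean-field map
#'
#' Scans \eqn{H(\nu_e) - \nu_e} over a grid (origin plus log-spaced points),
#' refines every sign change by bisection, and classifies stability by the
#' map criterion \eqn{H'(\nu^*) < 1}.
#'
#' @param tf_e,tf_i fitted `tf` objects.
#' @param b_e spike-triggered adaptation (pA).
#' @param tau_w adaptation time constant (ms).
#' @param grid scan grid (Hz); default origin + 400 log-spaced points in
#'   [0.01, 50] -- the domain over which the transfer function is fitted
#'   (outside it the threshold polynomial extrapolates without constraint
#'   and can produce spurious intersections).
#' @param tol bisection tolerance (Hz).
#' @return data.frame with `nu_e_star`, `nu_i_star`, `W_star`, `stable`,
#'   one row per fixed point (ordered by rate).
#' @export
find_fixed_points <- function(tf_e, tf_i, b_e, tau_w = 500, grid = NULL,
                              tol = 1e-5) {
  if (is.null(grid))
    grid <- c(0, exp(seq(log(0.01), log(50), length.out = 400)))
  stopifnot(length(grid) > 1)
  f <- function(ne) h_function(ne, tf_e, tf_i, b_e, tau_w) - ne
  fv <- vapply(grid, f, numeric(1))
  roots <- numeric(0)
  # a grid value that is (numerically) exactly a root
  exact <- which(abs(fv) < tol)
  roots <- c(roots, grid[exact])
  sgn <- sign(fv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    lo <- grid[i]; hi <- grid[i + 1]
    flo <- fv[i]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  roots <- sort(roots)
  if (length(roots) > 1)   # merge duplicates within tolerance
    roots <- roots[c(TRUE, diff(roots) > 10 * tol + 1e-3 * roots[-length(roots)])]
  if (length(roots) == 0) return(
    data.frame(nu_e_star = numeric(0), nu_i_star = numeric(0),
               W_star = numeric(0), stable = logical(0)))
  h <- pmax(1e-3, 1e-3 * roots)
  hp <- vapply(seq_along(roots), function(i) {
    lo <- max(0, roots[i] - h[i])
    (h_function(roots[i] + h[i], tf_e, tf_i, b_e, tau_w) -
       h_function(lo, tf_e, tf_i, b_e, tau_w)) / (roots[i] + h[i] - lo)
  }, numeric(1))
  data.frame(
    nu_e_star = roots,
    nu_i_star = vapply(roots, function(ne) stationary_inhibitory(tf_i, ne),
                       numeric(1)),
    W_star = b_e * roots * 1e-3 * tau_w,
    stable = hp < 1)
}

#' Critical adaptation strength of the slow-wave transition
#'
#' Bisects the spike-triggered adaptation `b_e` for the value at which the
#' fixed-point count drops from three (quiescent + unstable + self-sustained)
#' to one (quiescent only) -- the point where the self-sustained UP state
#' disappears and periodic UP/DOWN dynamics can emerge.
#'
#' @param tf_e,tf_i fitted `tf` objects (fit them with the synaptic decay
#'   times of interest).
#' @param b_range numeric(2) bracketing the transition (pA).
#' @param tau_w adaptation time constant (ms).
#' @param tol bisection tolerance (pA).
#' @param grid fixed-point scan grid passed on to [find_fixed_points()].
#' @return critical adaptation `b_crit` (pA). When the synaptic parameters
#'   eliminate the self-sustained state even without adaptation (no
#'   bistability at the lower end of `b_range`), the transition has already
#'   happened below any adaptation and 0 is returned with attribute
#'   `degenerate = TRUE`.
#' @export
critical_adaptation <- function(tf_e, tf_i, b_range = c(0, 300), tau_w = 500,
                                tol = 0.5, grid = NULL) {
  count <- function(b) nrow(find_fixed_points(tf_e, tf_i, b, tau_w, grid))
  lo <- b_range[1]; hi <- b_range[2]
  clo <- count(lo); chi <- count(hi)
  if (clo < 3) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (chi > 1)
    stop("search failure: b_range does not bracket the 3-to-1 transition ",
         sprintf("(counts %d at %g pA, %d at %g pA)", clo, lo, chi, hi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (count(mid) >= 3) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Dominant frequency of a rate trace
#'
#' Peak of the smoothed periodogram above a floor frequency; used to verify
#' that UP/DOWN regimes oscillate in the slow-wave band (< 4 Hz).
#'
#' Population-rate traces in burst-like slow-wave regimes are trains of
#' sharp (~10 ms) UP events recurring at a few Hz; the raw periodogram of
#' such a pulse train spreads power over the harmonics of the burst rate,
#' so the argmax can land on a harmonic rather than the rhythm itself.
#' `smooth_ms` low-passes the trace with a boxcar of that width first,
#' attenuating the burst-shape harmonics while leaving the slow-wave band
#' essentially untouched; 100 ms (the scale of the slow oscillation's own
#' period structure) is used by the slow-wave analyses.
#'
#' @param x rate samples (regularly spaced).
#' @param dt_ms sampling interval (ms).
#' @param f_min ignore frequencies below this floor (Hz).
#' @param smooth_ms boxcar pre-smoothing width (ms); 0 disables.
#' @return dominant frequency (Hz).
#' @export
dominant_frequency <- function(x, dt_ms, f_min = 0.1, smooth_ms = 0) {
  if (smooth_ms > 0) {
    k <- max(1, round(smooth_ms / dt_ms))
    x <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
    x <- x[!is.na(x)]
  }
  x <- x - mean(x)
  sp <- stats::spec.pgram(stats::ts(x, deltat = dt_ms * 1e-3),
                          spans = c(15, 15), plot = FALSE, detrend = TRUE)
  keep <- sp$freq >= f_min
  sp$freq[keep][which.max(sp$spec[keep])]
}
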