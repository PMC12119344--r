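test_that("OU afferent noise: degenerate case, stationary law, timescale", {
  z <- ou_noise(2, sigma = 0, duration = 100, seed = 1)
  expect_true(all(z$nu_aff == 2))
  o <- ou_noise(0.4, sigma = 3.5, tau_OU = 5, duration = 200000, dt = 0.1,
                seed = 7)
  # stationary sd of xi is sqrt(tau_OU/2) with tau_OU in seconds
  expect_lt(abs(sd(o$xi) / sqrt(0.005 / 2) - 1), 0.2)
  # autocorrelation time (1/e crossing) recovers tau_OU within 20%
  ac <- acf(o$xi, lag.max = 200, plot = FALSE)$acf
  tau_est <- (which(ac < exp(-1))[1] - 1) * 0.1
  expect_lt(abs(tau_est - 5) / 5, 0.2)
  # mean of the raw (unclipped) afferent rate converges to nu_drive
  expect_lt(abs(mean(0.4 + 3.5 * o$xi) - 0.4), 0.05)
})

test_that("mean-field simulation is reproducible and regime-correct", {
  f <- cached_fits("base")
  p <- mean_field_params(b_e = 5, nu_drive = 0.4)
  t1 <- simulate_mean_field(p, f$e, f$i, duration = 3000, seed = 5)
  t2 <- simulate_mean_field(p, f$e, f$i, duration = 3000, seed = 5)
  expect_identical(t1$nu_e, t2$nu_e)
  expect_true(all(t1$nu_e >= 0) && all(t1$nu_i >= 0))
})

test_that("second-order dynamics converge to first order as populations grow", {
  f <- cached_fits("base")
  # a clearly damped operating point (at the low-drive wake point the module
  # sits at the edge of stability, where the covariance dynamics are
  # marginal by construction); start from the relaxed state so the
  # covariance sources (F - nu)^2 are small from the outset
  p_inf <- mean_field_params(b_e = 5, nu_drive = 1.5, sigma = 0,
                             N_e = 1e9, N_i = 1e9)
  warm <- simulate_mean_field(p_inf, f$e, f$i, duration = 4000, seed = 1)
  st <- list(nu_e = tail(warm$nu_e, 1), nu_i = tail(warm$nu_i, 1),
             W = tail(warm$W, 1))
  o1 <- simulate_mean_field(p_inf, f$e, f$i, duration = 2000, order = 1,
                            seed = 1, init = st)
  o2 <- simulate_mean_field(p_inf, f$e, f$i, duration = 2000, order = 2,
                            seed = 1, init = st)
  expect_lt(max(abs(o1$nu_e - o2$nu_e)), 0.05)
  # at finite size the covariances are positive and scale roughly as 1/N
  p_fin <- mean_field_params(b_e = 5, nu_drive = 1.5, sigma = 0)
  o2f <- simulate_mean_field(p_fin, f$e, f$i, duration = 2000, order = 2,
                             seed = 1, init = st)
  c_small <- mean(o2f$c_ee[o2f$time > 500])
  expect_gt(c_small, 0)
  p_quarter <- mean_field_params(b_e = 5, nu_drive = 1.5, sigma = 0,
                                 N_e = 2000, N_i = 500)
  o2q <- simulate_mean_field(p_quarter, f$e, f$i, duration = 2000, order = 2,
                             seed = 1, init = st)
  expect_gt(mean(o2q$c_ee[o2q$time > 500]) / c_small, 2)
})

test_that("stationary inhibitory rate satisfies its self-consistency contract", {
  f <- cached_fits("base")
  for (ne in c(0, 2, 5, 10)) {
    ni <- stationary_inhibitory(f$i, ne)
    expect_lt(abs(transfer_rate(f$i, ne, ni) - ni), 1e-6)
  }
  nis <- vapply(c(0, 1, 2, 4, 8, 16), function(ne)
    stationary_inhibitory(f$i, ne), numeric(1))
  expect_true(all(diff(nis) >= -1e-8))  # non-decreasing in nu_e
})

test_that("H-function: quiescent origin, adaptation lowers it, Erfc bound", {
  f <- cached_fits("base")
  expect_lt(h_function(0, f$e, f$i, b_e = 5), 0.2)
  ne <- c(2, 5, 10)
  h_lo <- h_function(ne, f$e, f$i, b_e = 5)
  h_hi <- h_function(ne, f$e, f$i, b_e = 60)
  expect_true(all(h_hi < h_lo))
  st <- membrane_stats(ne, vapply(ne, function(x)
    stationary_inhibitory(f$i, x), numeric(1)), 0, neuron_params("RS"))
  expect_true(all(h_lo <= 1e3 / st$tau_V))
})

test_that("bisection contract of the critical adaptation search", {
  f <- cached_fits("base")
  bc <- critical_adaptation(f$e, f$i, b_range = c(0, 300), tol = 0.5)
  expect_gt(bc, 0)
  expect_equal(nrow(find_fixed_points(f$e, f$i, bc - 1)), 3L)
  expect_equal(nrow(find_fixed_points(f$e, f$i, bc + 1)), 1L)
})

test_that("instability of the rate integration raises an error, not silent junk", {
  f <- cached_fits("base")
  p <- mean_field_params(b_e = 5, nu_drive = 0.4)
  expect_error(
    simulate_mean_field(p, f$e, f$i, duration = 1000, seed = 1,
                        init = list(nu_e = 1e6, nu_i = 1, W = 0)),
    "divergence|instability")
})
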