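test_that("conductance moments: zeros, printed-parameter value, scaling laws", {
  z <- conductance_moments(0, 0)
  expect_equal(unlist(z), c(mu_Ge = 0, mu_Gi = 0, sigma_Ge = 0, sigma_Gi = 0))
  expect_equal(conductance_moments(1, 1)$mu_Ge, 3)  # 1 Hz x 400 x 5 ms x 1.5 nS
  m1 <- conductance_moments(2, 2)
  m4 <- conductance_moments(8, 8)
  expect_equal(m4$mu_Ge / m1$mu_Ge, 4)        # mean linear in rate
  expect_equal(m4$sigma_Ge / m1$sigma_Ge, 2)  # SD goes as sqrt(rate)
  expect_error(conductance_moments(-1, 0), "non-negative")
})

test_that("membrane statistics reduce analytically at rest and in limits", {
  rs <- neuron_params("RS")
  st0 <- membrane_stats(0, 0, 0, rs)
  expect_equal(st0$mu_V, -64)
  expect_equal(st0$mu_G, 10)
  expect_equal(st0$tau_m_eff, 20)
  # adaptation hyperpolarises at fixed rates
  stW <- membrane_stats(c(5, 5), c(5, 5), c(0, 100), rs)
  expect_lt(stW$mu_V[2], stW$mu_V[1])
  # strong inhibition pulls mu_V toward E_i = -80 mV
  sti <- membrane_stats(1, 5000, 0, rs)
  expect_lt(abs(sti$mu_V - (-80)), 1.5)
  expect_true(all(membrane_stats(c(0, 1, 10), c(0, 1, 10), 0, rs)$mu_G >= 10))
})

test_that("membrane statistics agree with long single-neuron simulations", {
  # the Poissonian-statistics assumption check: mu_V within 2 mV,
  # sigma_V within 30% on a 3x3 rate grid. The theory describes the free
  # subthreshold membrane, so the simulated neuron has its spike mechanism
  # disabled (threshold far above reach, vanishing exponential slope).
  rs <- neuron_params("RS")
  passive <- neuron_params("RS", v_thr = 500, delta = 0.01)
  syn <- synapse_params()
  grid <- expand.grid(nu_e = c(1, 3, 6), nu_i = c(4, 8, 16))
  pred <- membrane_stats(grid$nu_e, grid$nu_i, 0, rs, syn)
  set.seed(31)
  for (i in seq_len(nrow(grid))) {
    sim <- simulate_single_neuron(passive, syn, grid$nu_e[i], grid$nu_i[i],
                                  duration = 11000, clamp_W = TRUE)
    expect_lt(abs(sim$mu_V - pred$mu_V[i]), 2)
    expect_lt(abs(sim$sigma_V - pred$sigma_V[i]) / pred$sigma_V[i], 0.3)
  }
})

test_that("effective threshold is the centered second-order polynomial", {
  rs <- neuron_params("RS")
  fid <- tf_fiducials()
  p <- c(-45, 1, 2, 3, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  tf <- tf_coefficients(p, rs, synapse_params())
  # at the fiducial point every scaled coordinate is 0: P0 exactly
  expect_equal(effective_threshold(fid[1], fid[3], fid[5], tf), -45)
  # all higher coefficients zero: constant P0
  tf0 <- tf_coefficients(c(-50, rep(0, 9)), rs, synapse_params())
  expect_equal(effective_threshold(-70, 4, 0.9, tf0), -50)
  # one fiducial step in mu_V adds P_mu plus its quadratic term
  v1 <- effective_threshold(fid[1] + fid[2], fid[3], fid[5], tf)
  expect_equal(v1, -45 + 1 + 0.1)
})

test_that("transfer rate is bounded, monotone in excitation, and matches the compiled path", {
  f <- cached_fits("base")
  nu_e <- seq(0.5, 30, length.out = 40)
  r <- transfer_rate(f$e, nu_e, 8)
  expect_true(all(r >= 0))
  st <- membrane_stats(nu_e, 8, 0, neuron_params("RS"))
  expect_true(all(r <= 1e3 / st$tau_V + 1e-9))
  expect_true(all(diff(r) > 0))
  # R evaluation equals the compiled evaluation used inside the integrators
  rcpp <- brainmf:::cpp_tf_rate(f$e, nu_e, rep(8, 40), rep(0, 40))
  expect_equal(r, rcpp, tolerance = 1e-10)
  expect_error(transfer_rate(f$e, -1, 0), "non-negative")
})

test_that("fit is self-consistent: refitting template-generated rates recovers them", {
  f <- cached_fits("base")
  grid <- expand.grid(nu_e = exp(seq(log(0.2), log(40), length.out = 10)),
                      nu_i = exp(seq(log(0.2), log(40), length.out = 10)),
                      W = c(0, 60))
  grid$rate <- transfer_rate(f$e, grid$nu_e, grid$nu_i, grid$W)
  refit <- fit_transfer_function(neuron_params("RS"), synapse_params(),
                                 measurements = grid)
  expect_lt(refit$fit$rms, 0.05)
  pred <- transfer_rate(refit, grid$nu_e, grid$nu_i, grid$W)
  expect_equal(pred, grid$rate, tolerance = 0.02)
})

test_that("transfer-function JSON serialisation round-trips", {
  f <- cached_fits("base")
  path <- tempfile(fileext = ".json")
  write_tf_json(f$e, path)
  back <- read_tf_json(path)
  expect_equal(back$coefficients, f$e$coefficients, tolerance = 1e-12)
  expect_equal(back$fiducials, f$e$fiducials)
  expect_equal(back$synapse$tau_i, 5)
  nu <- c(1, 5, 20)
  expect_equal(transfer_rate(back, nu, 5), transfer_rate(f$e, nu, 5),
               tolerance = 1e-9)
})
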