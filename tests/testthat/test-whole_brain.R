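test_that("decoupled nodes reproduce the isolated mean-field statistics", {
  f <- cached_fits("base")
  con <- synthetic_connectome(5, density = 0.5, seed = 3, G = 0)
  tr <- simulate_whole_brain(con, "wake", f$e, f$i, duration = 8000, seed = 2)
  p <- mean_field_params(b_e = 5, nu_drive = 0.315)
  iso <- simulate_mean_field(p, f$e, f$i, duration = 8000, seed = 2)
  m_nodes <- colMeans(tr$nu_e[tr$time > 2000, ])
  m_iso <- mean(iso$nu_e[iso$time > 2000])
  expect_true(all(abs(m_nodes - m_iso) / m_iso < 0.25))
})

test_that("a symmetric two-node network without noise stays exactly symmetric", {
  f <- cached_fits("base")
  w <- matrix(c(0, 1, 1, 0), 2)
  con <- connectome(w, matrix(30, 2, 2) - diag(30, 2), G = 0.2)
  tr <- simulate_whole_brain(con, "wake", f$e, f$i, duration = 3000,
                             seed = 1, sigma = 0)
  expect_equal(tr$nu_e[, 1], tr$nu_e[, 2], tolerance = 1e-12)
})

test_that("conduction delay shifts the coupled response by length / v_c", {
  f <- cached_fits("base")
  # one-way coupling, nodes 60 mm apart at v_c = 3 mm/ms: 20-ms delay.
  # The weak G keeps both nodes at the isolated wake working point so the
  # pulse arrival is unambiguous.
  w <- matrix(0, 2, 2); w[1, 2] <- 1   # node 1 projects to node 2
  con <- connectome(w, matrix(c(0, 60, 60, 0), 2), v_c = 3, G = 0.05)
  stim <- region_stimulus(1, amplitude = 20, onset = 3000, duration = 20)
  tr <- simulate_whole_brain(con, "wake", f$e, f$i, duration = 4000,
                             seed = 1, sigma = 0, record_every = 10,
                             stimulus = stim)
  # identical noiseless control run isolates the evoked deviation from any
  # residual settling drift
  ctl <- simulate_whole_brain(con, "wake", f$e, f$i, duration = 4000,
                              seed = 1, sigma = 0, record_every = 10)
  dev <- abs(tr$nu_e - ctl$nu_e)
  onset1 <- tr$time[which(dev[, 1] > 0.01 * max(dev[, 1]))[1]]
  onset2 <- tr$time[which(dev[, 2] > 0.01 * max(dev[, 2]))[1]]
  lag <- onset2 - onset1
  expect_gt(lag, 15)
  expect_lt(lag, 27)
})

test_that("zero tract lengths and full symmetry admit the homogeneous solution", {
  f <- cached_fits("base")
  n <- 4
  w <- matrix(1, n, n) - diag(n)
  con <- connectome(w, matrix(0, n, n), G = 0.1)
  tr <- simulate_whole_brain(con, "wake", f$e, f$i, duration = 3000,
                             seed = 1, sigma = 0)
  spread <- apply(tr$nu_e, 1, function(r) diff(range(r)))
  expect_lt(max(spread), 1e-9)
})

test_that("state ensembles are reproducible and preset-checked", {
  f <- cached_fits("base")
  con <- synthetic_connectome(5, density = 0.5, seed = 3, G = 0.1)
  e1 <- run_state_ensemble(con, "wake", f$e, f$i, n_seeds = 2,
                           duration = 1000, base_seed = 9)
  e2 <- run_state_ensemble(con, "wake", f$e, f$i, n_seeds = 2,
                           duration = 1000, base_seed = 9)
  expect_identical(e1[["9"]]$nu_e, e2[["9"]]$nu_e)
  expect_false(identical(e1[["9"]]$nu_e, e1[["10"]]$nu_e))
  # synapse/preset mismatch is rejected (propofol needs tau_i = 7 fits)
  expect_error(simulate_whole_brain(con, "propofol", f$e, f$i, duration = 100),
               "tau_i")
})
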