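test_that("parameter constructors enforce their invariants", {
  expect_error(neuron_params("RS", c_m = -1))
  expect_error(neuron_params("RS", tau_w = 0))
  expect_error(synapse_params(tau_i = 0))
  expect_error(synapse_params(E_i = 10, E_e = 0))
  fs <- neuron_params("FS", b = 99, a = 3)
  expect_equal(fs$b, 0)  # FS cells carry no adaptation
  expect_equal(fs$a, 0)
})

test_that("resting RS neuron stays subthreshold over 100 ms without input", {
  p <- neuron_params("RS")
  s <- synapse_params()
  # analytic sign of dv/dt at v = E_L: leak term zero, exponential term > 0
  dv0 <- p$g_L * p$delta * exp((p$E_L - p$v_thr) / p$delta) / p$c_m
  expect_gt(dv0, 0)
  st <- neuron_state(p)
  spiked_any <- FALSE
  for (k in 0:999) {
    out <- step_neuron(st, p, s, dt = 0.1, t = k * 0.1)
    st <- out$state
    spiked_any <- spiked_any || out$spiked
  }
  expect_false(spiked_any)
  # settles at the (shifted) rest point, still well below threshold
  expect_lt(st$v, p$v_thr - 2 * p$delta)
})

test_that("spike reset, adaptation increment and refractory clamp", {
  p <- neuron_params("RS", b = 60)
  s <- synapse_params()
  st <- neuron_state(p, v = -0.5)    # just below the numerical ceiling
  st$g_e <- 10                       # strong drive pushes it over
  out <- step_neuron(st, p, s, dt = 0.1, t = 0)
  expect_true(out$spiked)
  expect_equal(out$state$v, p$v_rest)
  expect_equal(out$state$w, st$w + 60, tolerance = 1e-6)
  # refractory: voltage pinned at v_rest regardless of input
  st2 <- out$state
  st2$g_e <- 100
  out2 <- step_neuron(st2, p, s, dt = 0.1, t = 0.1)
  expect_false(out2$spiked)
  expect_equal(out2$state$v, p$v_rest)
})

test_that("membrane relaxes monotonically toward E_L without adaptation", {
  p <- neuron_params("RS", b = 0)
  s <- synapse_params()
  st <- neuron_state(p, v = -80)
  vs <- numeric(500)
  for (k in seq_len(500)) {
    st <- step_neuron(st, p, s, dt = 0.1, t = (k - 1) * 0.1)$state
    vs[k] <- st$v
  }
  expect_true(all(diff(vs) > -1e-12))
  expect_lt(abs(vs[500] - p$E_L), 1.5)  # near E_L (exponential term shifts it slightly)
})

test_that("synaptic conductance kernel: closed form and linearity", {
  expect_equal(synaptic_conductance(numeric(0), 5, Q = 1.5, tau = 5), 0)
  expect_equal(synaptic_conductance(10, 10, Q = 1.5, tau = 5), 1.5)
  expect_equal(synaptic_conductance(0, 5, Q = 1.5, tau = 5), 1.5 * exp(-1))
  # superposition of single-spike kernels to machine precision
  sp <- c(0, 3, 7, 7.5, 12)
  tt <- seq(0, 30, by = 0.5)
  sum_single <- rowSums(vapply(sp, function(t0)
    synaptic_conductance(t0, tt, Q = 5, tau = 5), numeric(length(tt))))
  expect_equal(synaptic_conductance(sp, tt, Q = 5, tau = 5), sum_single,
               tolerance = 1e-12)
  # causality
  expect_equal(synaptic_conductance(10, 9.9, Q = 1.5, tau = 5), 0)
})

test_that("single-neuron rate is monotone in excitatory drive", {
  p <- neuron_params("RS")
  s <- synapse_params()
  rates <- vapply(c(1, 2, 4), function(ne)
    simulate_single_neuron(p, s, ne, 2, duration = 6000, seed = 3)$rate,
    numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("non-finite neuron state raises an integration-failure error", {
  p <- neuron_params("RS")
  s <- synapse_params()
  st <- neuron_state(p)
  st$v <- NaN
  expect_error(step_neuron(st, p, s, 0.1, 0), "integration failure")
})
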