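test_that("network construction: population split, edge statistics, empty graph", {
  cfg <- network_config(n_total = 10000, frac_inh = 0.2, p_conn = 0.05)
  expect_equal(cfg$n_inh, 2000)
  expect_equal(cfg$n_exc, 8000)
  expect_equal(cfg$drive_size, 400)   # K_ext = p * N_e

  net0 <- build_network(network_config(n_total = 50, p_conn = 0, seed = 1))
  expect_equal(length(net0$targets), 0L)

  net <- build_network(network_config(n_total = 100, p_conn = 0.05, seed = 9))
  m <- 100 * 99 * 0.05
  expect_lt(abs(length(net$targets) - m), 3 * sqrt(m * 0.95))
  expect_false(any(net$targets == rep(seq_len(100) - 1L, diff(net$ptr))))  # no self-loops
})

test_that("identical seed gives a bit-identical spike record", {
  net <- build_network(network_config(n_total = 300, p_conn = 0.1, seed = 4))
  r1 <- simulate_network(net, drive = 8, duration = 500, seed = 77)
  r2 <- simulate_network(net, drive = 8, duration = 500, seed = 77)
  expect_gt(length(r1$spike_times), 0)
  expect_identical(r1$spike_times, r2$spike_times)
  expect_identical(r1$spike_ids, r2$spike_ids)
  expect_identical(r1$rate_e, r2$rate_e)
  r3 <- simulate_network(net, drive = 8, duration = 500, seed = 78)
  expect_false(identical(r1$spike_times, r3$spike_times))
})

test_that("no drive and resting start gives zero spikes; rates bounded by 1/T_refr", {
  net <- build_network(network_config(n_total = 200, p_conn = 0.05, seed = 2))
  r <- simulate_network(net, drive = 0, duration = 300, seed = 1)
  expect_equal(length(r$spike_times), 0L)
  ra <- simulate_network(net, drive = 10, duration = 1000, seed = 1)
  expect_true(all(ra$rate_e >= 0))
  expect_lt(mean(ra$rate_e), 200)  # refractory ceiling on mean rates
  expect_lt(mean(ra$rate_i), 200)
})

test_that("survival protocol: isolated neurons die within a few synaptic time constants", {
  net <- build_network(network_config(n_total = 200, p_conn = 0, seed = 3))
  sv <- survival_time(net, stim = stimulus_protocol(amplitude = 1, duration = 120),
                      t_max = 1000, seed = 5)
  expect_lt(as.numeric(sv), 60)
  expect_false(attr(sv, "censored"))
})

test_that("survival map has the requested shape and censoring convention", {
  net <- build_network(network_config(n_total = 400, p_conn = 0.1, seed = 6))
  sm <- scan_survival(net, b_e_grid = c(5, 200), tau_grid = 5, trials = 2,
                      t_max = 600, seed = 1)
  expect_equal(dim(sm$mean), c(2L, 1L))
  expect_equal(sm$mean[1, 1], mean(sm$trials[1, 1, ]))
  expect_true(all(sm$trials <= 600 - 120))
})

test_that("spike table export is columnar and time-consistent", {
  net <- build_network(network_config(n_total = 200, p_conn = 0.1, seed = 8))
  r <- simulate_network(net, drive = 3, duration = 400, seed = 2)
  tab <- spike_table(r)
  expect_named(tab, c("neuron", "time_ms"))
  expect_equal(nrow(tab), length(r$spike_times))
  expect_true(all(tab$neuron >= 1 & tab$neuron <= 200))
})
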