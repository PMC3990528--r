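test_that("the synaptic kernel is zero before onset and peaks at the analytic argmax", {
  sp <- synapse_params()
  expect_equal(synaptic_kernel(c(-1, 0, sp$latency), "ee", sp), c(0, 0, 0))
  for (cl in c("ee", "ie", "ei", "ii")) {
    tpk <- kernel_peak_time(cl, sp)
    expect_equal(synaptic_kernel(tpk, cl, sp), 1, tolerance = 1e-12)
    ## peak is a maximum: neighbours are below
    expect_lt(synaptic_kernel(tpk - 0.05, cl, sp), 1)
    expect_lt(synaptic_kernel(tpk + 0.05, cl, sp), 1)
  }
  expect_lt(synaptic_kernel(1e4, "ee", sp), 1e-12)
  expect_error(synaptic_kernel(1, "ee", synapse_params(
    rise = c(ee = 3, ie = 0.25, ei = 0.2, ii = 0.25))), "rise")
})

test_that("external spike trains are Poisson with the configured rate and seeded", {
  sc <- sim_config(duration = 1000, ext_rate = 1.5, seed = 7)
  trains <- generate_external_spikes(sc, 100)
  counts <- lengths(trains)
  expect_lt(abs(mean(counts) - 1500), 3 * sqrt(1500 / 100))
  expect_true(all(unlist(trains) > 0 & unlist(trains) <= 1000))
  expect_identical(trains, generate_external_spikes(sc, 100))
  expect_equal(lengths(generate_external_spikes(
    sim_config(duration = 1000, ext_rate = 0, seed = 1), 5)), rep(0L, 5))
})

test_that("rest is a fixed point and pure leak decay matches the closed form", {
  net <- generate_fixture_network("toy_ffi")
  sc <- sim_config(duration = 100, ext_rate = 0, seed = 1,
                   record = c("spikes", "v"), burn_in = 0)
  res <- simulate_network(net, sc = sc)
  expect_equal(nrow(res$spikes), 0)
  expect_true(all(res$v == 0))
  ## V(0) = 10 mV, no input: V(t) = 10 exp(-t/tau_m)
  res <- simulate_network(net, sc = sc, v_init = c(10, 10, 10))
  tt <- res$meta$sample_times
  for (node in c("1", "3")) {   # an E neuron and the I neuron
    tau <- if (node == "1") 20 else 10
    expect_lt(max(abs(res$v[, node] - 10 * exp(-tt / tau)) /
                    (10 * exp(-tt / tau))), 1e-3)
  }
})

test_that("single-spike response matches the independent fine-step oracle", {
  skip_if_not_installed("deSolve")
  np <- neuron_params(); sp <- synapse_params()
  ## one E->E input spike at t = 10 ms onto an isolated neuron
  n <- 3L
  net <- generate_fixture_network("toy_ffi")
  net$adj <- methods::as(methods::as(Matrix::sparseMatrix(
    i = 1, j = 2, dims = c(3, 3)), "nMatrix"), "CsparseMatrix")
  ## drive node 1 over threshold with a large v_init so it spikes once
  sc <- sim_config(duration = 60, ext_rate = 0, seed = 1,
                   record = c("spikes", "v"), burn_in = 0)
  res <- simulate_network(net, sc = sc, v_init = c(19, 0, 0))
  expect_equal(nrow(res$spikes), 1L)
  t_spike <- res$spikes$time_ms[1]
  oracle <- subthreshold_oracle(np, input_times = t_spike, edge_class = "ee",
                                target = "E", times = seq(0, 60, 0.05),
                                sp = sp)
  v_sim <- res$v[, "2"]
  v_orc <- oracle$v[match(round(res$meta$sample_times, 6),
                          round(oracle$time_ms, 6))]
  expect_lt(abs(max(v_sim) - max(v_orc, na.rm = TRUE)) / max(v_orc, na.rm = TRUE),
            0.01)
})

test_that("responses superpose in the frozen-driving-force limit", {
  skip_if_not_installed("deSolve")
  np <- neuron_params()
  ## with a tiny efficacy the driving force stays ~v_rev, so the response
  ## to two spikes equals the sum of the single-spike responses
  t1 <- subthreshold_oracle(np, 10, "ee", "E", efficacy = 1e-5,
                            times = seq(0, 80, 0.1))
  t2 <- subthreshold_oracle(np, 40, "ee", "E", efficacy = 1e-5,
                            times = seq(0, 80, 0.1))
  t12 <- subthreshold_oracle(np, c(10, 40), "ee", "E", efficacy = 1e-5,
                             times = seq(0, 80, 0.1))
  expect_lt(max(abs(t12$v - (t1$v + t2$v))) / max(t12$v), 5e-3)
})

test_that("shunting inhibition keeps a resting neuron at rest and drive is bounded by the reversal", {
  ## only inhibitory input onto a node at rest: V stays exactly 0
  net <- generate_fixture_network("toy_eei")  # has I -> node 1
  sc <- sim_config(duration = 100, ext_rate = 0, seed = 1,
                   record = c("spikes", "v"), burn_in = 0)
  res <- simulate_network(net, sc = sc, v_init = c(0, 0, 17.9))
  expect_true(all(abs(res$v[, "1"]) < 1e-9))
  ## saturating external drive: V never exceeds the excitatory reversal
  net2 <- make_bernoulli_net(3, 1, 0, seed = 1)
  res2 <- simulate_network(net2, sc = sim_config(duration = 200,
                                                 ext_rate = 50, seed = 2,
                                                 record = c("spikes", "v"),
                                                 burn_in = 0))
  expect_true(all(res2$v < 70))
})

test_that("refractory periods bound rates at 500 (E) and 1000 (I) spikes/s", {
  np <- neuron_params()
  ## analytic ceilings
  expect_equal(1000 / np$refrac_exc, 500)
  expect_equal(1000 / np$refrac_inh, 1000)
  ## saturated drive: disconnected neurons under massive external input
  net <- make_bernoulli_net(2, 2, 0, seed = 1)
  res <- simulate_network(net, sc = sim_config(duration = 1000,
                                               ext_rate = 400, seed = 3,
                                               burn_in = 0))
  rates <- firing_rates(res, c(0, 1000))
  expect_true(all(rates[1:2] <= 500))
  expect_true(all(rates[3:4] <= 1000))
  expect_gt(min(rates), 400)          # the drive really is saturating
  for (node in 1:4) {
    isi <- diff(res$spikes$time_ms[res$spikes$node == node])
    expect_true(all(isi >= ifelse(node <= 2, np$refrac_exc, np$refrac_inh)))
  }
})

test_that("identical seeds give identical rasters, different seeds differ", {
  net <- build_random_fixed_indegree(tiny_topo())
  sc <- sim_config(duration = 500, ext_rate = 2.4, seed = 5)
  a <- simulate_network(net, sc = sc)
  b <- simulate_network(net, sc = sc)
  expect_identical(a$spikes, b$spikes)
  sc2 <- sc; sc2$seed <- 6L
  c_ <- simulate_network(net, sc = sc2)
  expect_false(identical(a$spikes, c_$spikes))
})

test_that("latency must be a multiple of dt and bad record nodes error", {
  net <- generate_fixture_network("toy_ffi")
  expect_error(simulate_network(net, sp = synapse_params(latency = 0.33),
                                sc = sim_config(duration = 10, burn_in = 0)),
               "multiple")
  expect_error(simulate_network(net, sc = sim_config(duration = 10,
                                                     burn_in = 0,
                                                     record_nodes = 99L)),
               "range")
})
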