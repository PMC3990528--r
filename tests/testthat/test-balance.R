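test_that("the LFP is the summed absolute current into E neurons", {
  ## two E neurons with constant currents (+2, -3) and (+1, 0), one I neuron
  ## (ignored): LFP = |2| + |-3| + |1| + |0| = 6 at every sample
  ns <- 5L
  i_ext <- cbind(rep(2, ns), rep(1, ns), rep(9, ns))
  i_exc <- cbind(rep(0, ns), rep(0, ns), rep(9, ns))
  i_inh <- cbind(rep(-3, ns), rep(0, ns), rep(9, ns))
  res <- fake_result(i_ext = i_ext, i_exc = i_exc, i_inh = i_inh)
  lfp <- compute_lfp(res)
  expect_s3_class(lfp, "lfp_trace")
  expect_equal(lfp$values, rep(6, ns))
  expect_equal(compute_lfp(res, constant = 2.5)$values, rep(15, ns))
  expect_true(all(lfp$values >= 0))
  expect_error(compute_lfp(fake_result(v = matrix(0, 3, 3))), "current")
})

test_that("recorded and recomputed LFP agree when all E neurons are recorded", {
  net <- build_random_fixed_indegree(tiny_topo())
  res <- simulate_network(net, sc = sim_config(duration = 500, ext_rate = 2.4,
                                               seed = 2,
                                               record = c("spikes", "lfp",
                                                          "currents")))
  expect_equal(compute_lfp(res)$values, res$lfp$values, tolerance = 1e-12)
})

test_that("a constant LFP yields a single downstate and no upstates", {
  lfp <- lfp_trace(rep(3, 2000), dt_sample = 1)
  st <- detect_up_down_states(lfp)
  expect_equal(nrow(st$intervals), 1L)
  expect_equal(st$intervals$state, "down")
  expect_equal(st$summary$n_switches, 0L)
})

test_that("the two-pass detector recovers synthetic two-level boundaries within one fine window", {
  set.seed(42)
  dts <- 1
  block <- 500                       # ms per level
  levels <- rep(rep(c(1, 10), 6), each = block)
  x <- levels * exp(rnorm(length(levels), 0, 0.05))   # small jitter
  st <- detect_up_down_states(lfp_trace(x, dts))
  ups <- st$intervals[st$intervals$state == "up" & !st$intervals$censored, ]
  true_starts <- (which(diff(levels) > 0)) * dts
  true_ends <- (which(diff(levels) < 0)) * dts
  for (k in seq_len(nrow(ups))) {
    expect_lt(min(abs(ups$start_ms[k] - true_starts)), 5)
    expect_lt(min(abs(ups$end_ms[k] - true_ends)), 5)
    expect_lt(abs(ups$duration_ms[k] - block), 10)
  }
  ## intervals tile the trace
  expect_equal(sum(st$intervals$duration_ms), length(x) * dts)
  expect_true(all(diff(match(st$intervals$state, c("down", "up"))) != 0))
})

test_that("the detector is invariant to positive rescaling of the LFP", {
  set.seed(1)
  x <- rep(rep(c(1, 8), 4), each = 400) * exp(rnorm(3200, 0, 0.1))
  a <- detect_up_down_states(lfp_trace(x, 1))
  b <- detect_up_down_states(lfp_trace(1000 * x, 1))
  expect_equal(a$intervals[, c("state", "start_ms", "end_ms")],
               b$intervals[, c("state", "start_ms", "end_ms")])
})

test_that("raising the detection threshold never increases upstate time", {
  set.seed(2)
  x <- rep(rep(c(1, 6), 5), each = 300) * exp(rnorm(3000, 0, 0.3))
  up_time <- vapply(c(2, 3, 4, 6), function(k) {
    st <- detect_up_down_states(lfp_trace(x, 1), k_sd = k)
    sum(st$intervals$duration_ms[st$intervals$state == "up"])
  }, numeric(1))
  expect_true(all(diff(up_time) <= 0))
})

test_that("upstate geometric means exceed downstate geometric means", {
  set.seed(3)
  x <- rep(rep(c(1, 9), 4), each = 400) * exp(rnorm(3200, 0, 0.2))
  st <- detect_up_down_states(lfp_trace(x, 1))
  iv <- st$intervals
  expect_gt(min(iv$geo_mean[iv$state == "up"]),
            max(iv$geo_mean[iv$state == "down"]))
})

test_that("neuron states follow the high/low/neutral rules with high priority", {
  ## 3 nodes, 20 one-ms bins; node 1 spikes at 5 ms -> high through 19.99 ms
  v <- matrix(0, 20, 3)
  v[, 2] <- -8            # below the low threshold
  v[, 3] <- 2             # above it
  spikes <- data.frame(time_ms = c(5, 10), node = c(1L, 2L))
  res <- fake_result(v = v, spikes = spikes)
  ns <- classify_neuron_states(res, low_v_threshold = -5, high_window = 15)
  expect_equal(unname(ns[6, 1]), 1L)                 # spiked 1 ms ago: high
  expect_equal(unname(ns[19, 1]), 1L)                # 14 ms ago: still high
  expect_equal(unname(ns[20, 1]), 2L)                # window (t-15, t]
  expect_equal(unname(ns[4, 1]), 2L)                 # before its spike
  ## node 2 is low except where its own spike makes it high
  expect_equal(unname(ns[5, 2]), 3L)
  expect_equal(unname(ns[11, 2]), 1L)                # high overrides low
  expect_true(all(ns[, 3] == 2L))                    # silent, above thr
})

test_that("highly-active classification uses strict class thresholds", {
  ## interval of 1000 ms; E threshold 4/s, I threshold 30/s
  spikes <- data.frame(
    time_ms = c(seq(100, 900, length.out = 5),    # E node 1: 5 spikes/s
                seq(100, 900, length.out = 4),    # E node 2: 4/s (boundary)
                seq(50, 950, length.out = 30)),   # I node 3: exactly 30/s
    node = rep(1:3, c(5, 4, 30)))
  flags <- classify_highly_active(spikes, c(0, 1000),
                                  ei_label = c("E", "E", "I"))
  expect_identical(unname(flags), c(TRUE, FALSE, FALSE))
  expect_error(classify_highly_active(spikes, c(5, 5),
                                      ei_label = c("E", "E", "I")),
               "interval")
})

test_that("functional in-degree counts active origins of the requested class", {
  ## 5-node crafted network: origins 1, 2, 4 project to node 3
  net <- make_bernoulli_net(3, 2, 0, seed = 1)
  net$adj <- methods::as(methods::as(Matrix::sparseMatrix(
    i = c(1, 2, 4, 5), j = c(3, 3, 3, 1), dims = c(5, 5)),
    "nMatrix"), "CsparseMatrix")
  active <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  expect_equal(functional_in_degree(net, active, "all"),
               c(0L, 0L, 2L, 0L, 0L))
  expect_equal(functional_in_degree(net, active, "E"),
               c(0L, 0L, 1L, 0L, 0L))
  expect_equal(functional_in_degree(net, active, "I"),
               c(0L, 0L, 1L, 0L, 0L))
  expect_equal(functional_in_degree(net, rep(FALSE, 5), "all"), rep(0L, 5))
  ## with everything active, counts equal the structural in-degrees
  rnd <- build_random_fixed_indegree(tiny_topo())
  expect_equal(functional_in_degree(rnd, rep(TRUE, 50), "E"),
               rep(8L, 50))
})

test_that("class summaries give exact rates on a crafted raster", {
  spikes <- data.frame(time_ms = c(rep(500, 3), 600, 700),
                       node = c(1L, 2L, 3L, 1L, 4L))
  res <- fake_result(v = matrix(10, 10, 4), spikes = spikes,
                     n_exc = 3L, n_inh = 1L, dt_sample = 100,
                     duration = 1000)
  res$meta$struct_class <- c(1L, 1L, 2L, 1L)
  summ <- class_rate_and_conductance_summary(res, interval = c(0, 1000))
  ## E1: nodes 1, 2 -> (2 + 1)/2 spikes per second
  expect_equal(summ$mean_rate[summ$class == "E1"], 1.5)
  expect_equal(summ$mean_rate[summ$class == "E2"], 1)
  expect_equal(summ$mean_rate[summ$class == "I1"], 1)
  expect_setequal(summ$class, c("E1", "E2", "I1"))
})

test_that("unrewired lattice summaries cover only Class 1", {
  lat <- generate_fixture_network("mini_lattice_16_4")
  res <- simulate_network(lat, sc = sim_config(duration = 300, ext_rate = 1,
                                               seed = 1))
  summ <- class_rate_and_conductance_summary(res, lat)
  expect_setequal(summ$class, c("E1", "I1"))
})
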