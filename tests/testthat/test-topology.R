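test_that("configuration invariants are enforced", {
  expect_error(topology_config(n_exc = 40, n_inh = 10, k_from_exc = 7,
                               k_from_inh = 2), "even")
  expect_error(topology_config(n_exc = 40, n_inh = 10, k_from_exc = 40,
                               k_from_inh = 2), "smaller")
  expect_error(topology_config(n_exc = 45, n_inh = 10, k_from_exc = 8,
                               k_from_inh = 2), "multiple")
  expect_error(rewire_config(p2 = 1.2))
  expect_error(modular_config(n_exc = 400, module_size = 99))
  expect_error(modular_config(n_exc = 400, n_inh = 100, module_size = 100,
                              mean_p_ee = 0.5, ratio_ee = 30), "outside")
})

test_that("all fixed-in-degree constructors give exactly constant in-degrees and no self-edges", {
  cfg <- small_topo(seed = 7)
  nets <- list(random = build_random_fixed_indegree(cfg),
               lattice = build_ring_lattice(cfg),
               rewired = rewire_lattice(build_ring_lattice(cfg),
                                        rewire_config(p2 = 0.075, p3 = 0.05,
                                                      seed = 3)))
  for (nm in names(nets)) {
    net <- nets[[nm]]
    expect_silent(validate_network(net))
    deg <- balancenet:::indegree_by_origin(net)
    expect_true(all(deg$from_exc == 160), info = nm)
    expect_true(all(deg$from_inh == 40), info = nm)
    expect_true(all(Matrix::diag(net$adj) == 0), info = nm)
  }
})

test_that("ring lattice matches the hand-enumerated symmetric windows", {
  lat <- build_ring_lattice(topology_config(n_exc = 16, n_inh = 4,
                                            k_from_exc = 4, k_from_inh = 2))
  ## E node 0 receives E edges from 1, 2, 14, 15 (0-based)
  e_origins <- which(lat$adj[, 1]) - 1L
  expect_setequal(e_origins[e_origins < 16], c(1, 2, 14, 15))
  ## its I origins are the +/-1 window around block 0 of the I ring
  expect_setequal(e_origins[e_origins >= 16] - 16L, c(1, 3))
  ## E-E submatrix is symmetric: every E-E edge is reciprocated
  ee <- as.matrix(lat$adj[1:16, 1:16])
  expect_identical(ee, t(ee))
  ## deterministic: no RNG involved
  expect_identical(as.matrix(lat$adj),
                   as.matrix(build_ring_lattice(
                     topology_config(n_exc = 16, n_inh = 4, k_from_exc = 4,
                                     k_from_inh = 2, seed = 99))$adj))
})

test_that("out-edge totals are conserved exactly", {
  ## every node takes k_from_exc E-origins, so the mean E out-degree is
  ## k_from_exc * n_nodes / n_exc in every realization
  for (seed in 1:5) {
    net <- build_random_fixed_indegree(tiny_topo(seed))
    out_e <- Matrix::rowSums(net$adj[1:40, ])
    expect_equal(mean(out_e), 8 * 50 / 40)
  }
})

test_that("rewiring at zero probabilities is the identity", {
  lat <- build_ring_lattice(tiny_topo())
  rw <- rewire_lattice(lat, rewire_config(p2 = 0, p3 = 0, seed = 5))
  expect_identical(as.matrix(rw$adj), as.matrix(lat$adj))
  expect_true(all(rw$struct_class == 1L))
})

test_that("Class 2 rewiring replaces inhibitory origins with disjoint ones", {
  lat <- build_ring_lattice(small_topo())
  rw <- rewire_lattice(lat, rewire_config(p2 = 1, p3 = 0, seed = 5))
  expect_true(all(rw$struct_class == 2L))
  ## excitatory sub-adjacency unchanged
  expect_identical(as.matrix(rw$adj[1:800, ]), as.matrix(lat$adj[1:800, ]))
  ## new I origins disjoint from lattice I origins, for every node
  old <- balancenet:::incoming_origins(lat$adj)
  new <- balancenet:::incoming_origins(rw$adj)
  disjoint <- vapply(seq_len(1000), function(t) {
    length(intersect(old[[t]][old[[t]] > 800], new[[t]][new[[t]] > 800])) == 0
  }, logical(1))
  expect_true(all(disjoint))
})

test_that("Class 2 fraction matches the rewiring probability", {
  fr <- vapply(1:30, function(s) {
    rw <- rewire_lattice(build_ring_lattice(small_topo()),
                         rewire_config(p2 = 0.075, p3 = 0, seed = s))
    mean(rw$struct_class == 2L)
  }, numeric(1))
  ## binomial error of the mean over 30 x 1000 nodes
  se <- sqrt(0.075 * 0.925 / (30 * 1000))
  expect_lt(abs(mean(fr) - 0.075), 4 * se)
})

test_that("rewired networks are reproducible under the seed", {
  lat <- build_ring_lattice(small_topo())
  rc <- rewire_config(p2 = 0.1, p3 = 0.1, seed = 42)
  a <- rewire_lattice(lat, rc); b <- rewire_lattice(lat, rc)
  expect_identical(as.matrix(a$adj), as.matrix(b$adj))
  expect_identical(a$struct_class, b$struct_class)
})

test_that("rewiring rejects impossible origin pools", {
  ## k_from_inh = n_inh - 2: excluding the ~k lattice origins leaves too few
  lat <- build_ring_lattice(topology_config(n_exc = 40, n_inh = 10,
                                            k_from_exc = 8, k_from_inh = 8))
  expect_error(rewire_lattice(lat, rewire_config(p2 = 1, p3 = 0, seed = 1)),
               "pool")
})

test_that("embedded modular network has the configured densities", {
  mc <- modular_config(n_exc = 400, n_inh = 100, module_size = 100,
                       mean_p_ee = 0.2, ratio_ee = 3, p_inh = 0.2, seed = 1)
  expect_gt(mc$p_in, mc$p_out)
  dens <- vapply(1:20, function(s) {
    mc$seed <- s
    net <- build_embedded_modular(mc)
    sum(net$adj[1:400, 1:400]) / (400 * 399)
  }, numeric(1))
  se <- sd(dens) / sqrt(length(dens))
  expect_lt(abs(mean(dens) - 0.2), 3 * se + 1e-6)
  ## provenance records the Bernoulli (non-constant in-degree) nature
  net <- build_embedded_modular(mc)
  expect_false(net$provenance$constant_indegree)
  ## within-module density exceeds between-module density
  m1 <- 1:100; m2 <- 101:200
  expect_gt(sum(net$adj[m1, m1]) / (100 * 99),
            sum(net$adj[m1, m2]) / (100 * 100))
})

test_that("one-module and ratio-1 degenerate modular cases collapse correctly", {
  mc1 <- modular_config(n_exc = 200, n_inh = 50, module_size = 200,
                        mean_p_ee = 0.15, ratio_ee = 1, p_inh = 0.1, seed = 2)
  expect_equal(mc1$p_in, mc1$p_out)
  expect_equal(mc1$p_in, 0.15)
})

test_that("in-degree profile reports the 20% rule and constant totals", {
  rw <- rewire_lattice(build_ring_lattice(small_topo()),
                       rewire_config(p2 = 0.075, p3 = 0.05, seed = 3))
  prof <- in_degree_profile(rw)
  ei <- prof[prof$grouping == "ei", ]
  from_i <- ei[ei$origin == "I", ]
  ## mean in-degree from the whole I population is 20% of the I class size
  expect_true(all(abs(from_i$in_mean / 200 - 0.2) < 1e-12))
  expect_true(all(from_i$in_min == from_i$in_max))
  from_e <- ei[ei$origin == "E", ]
  expect_true(all(from_e$in_mean == 160))
})
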