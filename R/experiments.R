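#' Derive independent component seeds from a master seed
#'
#' Counter-based expansion of one master seed into reproducible per-component
#' streams (topology, rewiring, external drive, ...). Derived seeds stay
#' below 2^31.
#'
#' @param master Integer master seed.
#' @param n Number of seeds.
#' @return Integer vector of length \code{n}.
#' @export
derive_seeds <- function(master, n) {
  a <- 1103515245; c <- 12345; m <- 2^31 - 1
  s <- as.numeric(master) %% m
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- (a * s + c + i) %% m
    out[i] <- as.integer(s)
  }
  out
}

#' Experiment configuration
#'
#' Bundles a topology choice with neuron, synapse, simulation and analysis
#' settings under a single master seed, from which per-component seeds
#' (network realisation, rewiring, external drive) are derived and recorded.
#'
#' @param topology One of \code{"random"}, \code{"lattice"},
#'   \code{"rewired_lattice"}, \code{"embedded_modular"}.
#' @param topo A \code{\link{topology_config}} or
#'   \code{\link{modular_config}}.
#' @param rewire A \code{\link{rewire_config}} (rewired lattice only).
#' @param neuron,synapse Model parameters.
#' @param sim A \code{\link{sim_config}}.
#' @param analysis List of analysis settings passed to
#'   \code{\link{detect_up_down_states}}.
#' @param motifs Whether \code{\link{run_experiment}} also computes motif
#'   counts (quadratic-ish in network size; default on for small networks).
#' @param seed Master seed.
#' @return A list of class \code{experiment_config}.
#' @export
experiment_config <- function(topology = c("random", "lattice",
                                           "rewired_lattice",
                                           "embedded_modular"),
                              topo = topology_config(),
                              rewire = rewire_config(),
                              neuron = neuron_params(),
                              synapse = synapse_params(),
                              sim = sim_config(duration = 5100),
                              analysis = list(coarse_window = 100,
                                              fine_window = 5, k_sd = 3),
                              motifs = topo$n_exc <= 1000,
                              seed = 1L) {
  topology <- match.arg(topology)
  seeds <- derive_seeds(seed, 3)
  topo$seed <- seeds[1]
  rewire$seed <- seeds[2]
  sim$seed <- seeds[3]
  structure(list(topology = topology, topo = topo, rewire = rewire,
                 neuron = neuron, synapse = synapse, sim = sim,
                 analysis = analysis, motifs = isTRUE(motifs),
                 seed = as.integer(seed), derived_seeds = seeds),
            class = "experiment_config")
}

build_topology <- function(cfg) {
  switch(cfg$topology,
         random = build_random_fixed_indegree(cfg$topo),
         lattice = build_ring_lattice(cfg$topo),
         rewired_lattice = rewire_lattice(build_ring_lattice(cfg$topo),
                                          cfg$rewire),
         embedded_modular = build_embedded_modular(cfg$topo))
}

#' Run a seeded end-to-end experiment
#'
#' Builds the network, simulates it, runs the LFP and up/down-state
#' analyses (and optionally the motif counters), and writes all artifacts
#' plus a manifest with the configuration and derived seeds to
#' \code{out_dir}. Identical configurations and seeds produce byte-identical
#' artifacts.
#'
#' Artifacts: \code{network.mtx} / \code{network.nodes.tsv},
#' \code{spikes.tsv} (time_ms, node_id), \code{lfp.tsv},
#' \code{intervals.tsv}, \code{class_summary.tsv}, optional
#' \code{motifs.tsv}, and \code{manifest.json}.
#'
#' @param cfg An \code{\link{experiment_config}}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory \code{network},
#'   \code{result}, \code{states} and the output directory.
#' @export
run_experiment <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(what, expr)
    tryCatch(expr, error = function(e)
      stop("experiment stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))

  net <- stage("topology", build_topology(cfg))
  write_network(net, file.path(out_dir, "network"))

  res <- stage("simulate",
               simulate_network(net, cfg$neuron, cfg$synapse, cfg$sim))
  write.table(data.frame(time_ms = res$spikes$time_ms,
                         node_id = res$spikes$node - 1L),
              file.path(out_dir, "spikes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  states <- NULL
  if (!is.null(res$lfp)) {
    lfp <- recorded_lfp(res)
    write.table(data.frame(time_ms = lfp$time_ms, lfp = lfp$values),
                file.path(out_dir, "lfp.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    states <- stage("states", do.call(detect_up_down_states,
                                      c(list(lfp = lfp,
                                             skip_ms = cfg$sim$burn_in),
                                        cfg$analysis)))
    write.table(states$intervals, file.path(out_dir, "intervals.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summ <- stage("summary", class_rate_and_conductance_summary(res, net))
  write.table(summ, file.path(out_dir, "class_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  if (cfg$motifs) {
    mot <- stage("motifs", {
      rc <- reciprocal_counts(net)
      data.frame(node_id = rc$node - 1L, ei_label = rc$ei,
                 reciprocal_positive = rc$reciprocal_positive,
                 reciprocal_negative = rc$reciprocal_negative,
                 ffi = ffi_counts(net),
                 cycle_eei = cycle_counts(net, "eei"),
                 cycle_eee = cycle_counts(net, "eee"))
    })
    write.table(mot, file.path(out_dir, "motifs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(package = "balancenet",
                   version = as.character(packageVersion("balancenet")),
                   topology = cfg$topology,
                   master_seed = cfg$seed,
                   derived_seeds = cfg$derived_seeds,
                   config = list(topo = unclass(cfg$topo),
                                 rewire = unclass(cfg$rewire),
                                 neuron = unclass(cfg$neuron),
                                 synapse = as.list(unclass(cfg$synapse)),
                                 sim = unclass(cfg$sim),
                                 analysis = cfg$analysis))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(network = net, result = res, states = states,
                 out_dir = out_dir))
}

#' Rewiring-probability sweep
#'
#' For every grid point (p2, p3) and network realisation: build a rewired
#' lattice, simulate, and record the time-averaged fraction of each
#' structural class in the per-neuron high and low states. The low-state
#' membrane threshold is derived per realisation from a seed-matched
#' random-network run.
#'
#' @param topo A \code{\link{topology_config}}.
#' @param p2_grid,p3_grid Numeric grids in [0, 1].
#' @param n_realizations Network realisations per grid point.
#' @param sim A \code{\link{sim_config}} template (must record \code{"v"}).
#' @param neuron,synapse Model parameters.
#' @param seed Master seed for the realisation-level seed streams.
#' @return A data frame with columns \code{p2}, \code{p3},
#'   \code{realization}, \code{class}, \code{n}, \code{frac_high},
#'   \code{frac_low}, \code{mean_rate}.
#' @export
sweep_rewiring <- function(topo, p2_grid, p3_grid = 0, n_realizations = 3,
                           sim = sim_config(duration = 2100,
                                            record = c("spikes", "v")),
                           neuron = neuron_params(),
                           synapse = synapse_params(), seed = 1L) {
  stopifnot(all(p2_grid >= 0 & p2_grid <= 1), all(p3_grid >= 0 & p3_grid <= 1))
  if (!"v" %in% sim$record)
    stop("the sweep needs membrane traces; include \"v\" in sim$record")
  grid <- expand.grid(p2 = p2_grid, p3 = p3_grid)
  out <- list()
  for (r in seq_len(n_realizations)) {
    seeds <- derive_seeds(seed + r, 3)
    ## low-state threshold from a matched random-network run
    topo_r <- topo; topo_r$seed <- seeds[1]
    sim_r <- sim; sim_r$seed <- seeds[3]
    ref <- simulate_network(build_random_fixed_indegree(topo_r),
                            neuron, synapse, sim_r)
    low_thr <- low_state_threshold(ref)
    lat <- build_ring_lattice(topo_r)
    for (g in seq_len(nrow(grid))) {
      rw <- rewire_lattice(lat, rewire_config(p2 = grid$p2[g],
                                              p3 = grid$p3[g],
                                              seed = seeds[2]))
      res <- simulate_network(rw, neuron, synapse, sim_r)
      summ <- class_rate_and_conductance_summary(res, rw,
                                                 low_v_threshold = low_thr)
      out[[length(out) + 1L]] <- data.frame(
        p2 = grid$p2[g], p3 = grid$p3[g], realization = r,
        class = summ$class, n = summ$n,
        frac_high = summ$frac_high, frac_low = summ$frac_low,
        mean_rate = summ$mean_rate)
    }
  }
  do.call(rbind, out)
}

#' Tiny deterministic fixture networks
#'
#' A catalogue of small networks with known structure, used throughout the
#' test suite and handy for exploring the motif counters by hand.
#'
#' \describe{
#'   \item{toy_ffi}{3 nodes (2 E, 1 I): E1->x, E1->I, I->x with x = E2 —
#'     one FFI instance converging on x.}
#'   \item{toy_recip}{3 nodes (2 E, 1 I): E1<->E2 and E1<->I reciprocal
#'     pairs.}
#'   \item{toy_eei}{3 nodes (2 E, 1 I): the cycle x->E->I->x with x = E1.}
#'   \item{mini_lattice_16_4}{20-node deterministic ring lattice (16 E, 4 I,
#'     in-degrees 4 from E and 2 from I).}
#'   \item{mini_random}{30-node random network (24 E, 6 I, in-degrees 6/2,
#'     seed 42).}
#' }
#'
#' @param name Fixture name.
#' @return A \code{directed_network}.
#' @export
generate_fixture_network <- function(name) {
  edge_net <- function(edges, n_exc, n_inh) {
    n <- n_exc + n_inh
    origins <- split(edges[, 1], factor(edges[, 2], levels = seq_len(n)))
    new_directed_network(lapply(origins, as.integer), n_exc, n_inh,
                         rep(1L, n),
                         provenance = list(topology = paste0("fixture:", name),
                                           constant_indegree = FALSE))
  }
  switch(name,
    ## nodes: 1 = E1, 2 = E2 (reference x), 3 = I
    toy_ffi = edge_net(rbind(c(1, 2), c(1, 3), c(3, 2)), 2, 1),
    toy_recip = edge_net(rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1)), 2, 1),
    ## x = node 1: x->E(2), E->I(3), I->x
    toy_eei = edge_net(rbind(c(1, 2), c(2, 3), c(3, 1)), 2, 1),
    mini_lattice_16_4 = build_ring_lattice(
      topology_config(n_exc = 16, n_inh = 4, k_from_exc = 4,
                      k_from_inh = 2)),
    mini_random = build_random_fixed_indegree(
      topology_config(n_exc = 24, n_inh = 6, k_from_exc = 6,
                      k_from_inh = 2, seed = 42)),
    stop("unknown fixture name: ", name))
}
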