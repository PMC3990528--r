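## Shared small-scale study conditions: same 20% in-degree rule and 4:1
## E:I ratio as the full-scale defaults, at 1/5 linear scale.
small_topo <- function(seed = 1L)
  topology_config(n_exc = 800, n_inh = 200, k_from_exc = 160,
                  k_from_inh = 40, seed = seed)

tiny_topo <- function(seed = 1L)
  topology_config(n_exc = 40, n_inh = 10, k_from_exc = 8, k_from_inh = 2,
                  seed = seed)

## Bernoulli directed E/I network (no self-edges), for motif tests.
make_bernoulli_net <- function(n_exc, n_inh, p, seed) {
  n <- n_exc + n_inh
  set.seed(seed)
  m <- matrix(runif(n * n) < p, n, n)
  diag(m) <- FALSE
  adj <- methods::as(Matrix::Matrix(m, sparse = TRUE), "nMatrix")
  structure(list(adj = methods::as(adj, "CsparseMatrix"),
                 ei = rep(c("E", "I"), c(n_exc, n_inh)),
                 struct_class = rep(1L, n),
                 n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 provenance = list(topology = "bernoulli",
                                   constant_indegree = FALSE)),
            class = "directed_network")
}

## Minimal sim_result skeleton for analysis-function unit tests.
fake_result <- function(v = NULL, spikes = data.frame(time_ms = numeric(0),
                                                      node = integer(0)),
                        i_ext = NULL, i_exc = NULL, i_inh = NULL,
                        n_exc = 2L, n_inh = 1L, dt_sample = 1,
                        n_samples = if (!is.null(v)) nrow(v) else
                          nrow(i_ext),
                        duration = n_samples * dt_sample, burn_in = 0) {
  n <- n_exc + n_inh
  rec <- seq_len(n)
  structure(list(
    spikes = spikes, lfp = NULL, v = v,
    i_ext = i_ext, i_exc = i_exc, i_inh = i_inh,
    g_ext = NULL, g_exc = NULL, g_inh = NULL,
    meta = list(n_nodes = n, n_exc = n_exc, n_inh = n_inh,
                ei = rep(c("E", "I"), c(n_exc, n_inh)),
                struct_class = rep(1L, n),
                config = list(duration = duration, burn_in = burn_in),
                record_nodes = rec,
                sample_times = dt_sample * seq_len(n_samples),
                dt_sample = dt_sample)),
    class = "sim_result")
}
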