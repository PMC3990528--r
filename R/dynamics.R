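#' Difference-of-exponentials synaptic conductance kernel
#'
#' Peak-normalised conductance time course elicited by a single presynaptic
#' spike at time 0: zero up to the onset latency, then
#' \code{exp(-(t - latency)/decay) - exp(-(t - latency)/rise)} scaled so its
#' maximum over time equals 1. This reports the kernel \emph{shape}; the
#' conductance actually applied by the simulator additionally carries the
#' efficacy and the \code{kernel_norm} prefactor of
#' \code{\link{synapse_params}}.
#'
#' @param t Time since the presynaptic spike, ms (vectorised).
#' @param edge_class One of \code{"ee"}, \code{"ie"}, \code{"ei"},
#'   \code{"ii"} (source-target; external inputs share the excitatory
#'   kernels).
#' @param sp A \code{\link{synapse_params}}.
#' @return Dimensionless conductance values in [0, 1].
#' @examples
#' tpk <- kernel_peak_time("ee")
#' synaptic_kernel(tpk, "ee")  # 1
#' @export
synaptic_kernel <- function(t, edge_class = c("ee", "ie", "ei", "ii"),
                            sp = synapse_params()) {
  edge_class <- match.arg(edge_class)
  tr <- sp$rise[[edge_class]]; td <- sp$decay[[edge_class]]
  if (tr >= td) stop("rise time must be smaller than decay time")
  s <- t - sp$latency
  out <- numeric(length(t))
  pos <- s > 0
  peak <- kernel_unnormalised_peak(tr, td)
  out[pos] <- (exp(-s[pos] / td) - exp(-s[pos] / tr)) / peak
  out
}

kernel_unnormalised_peak <- function(tr, td) {
  tstar <- tr * td / (td - tr) * log(td / tr)
  exp(-tstar / td) - exp(-tstar / tr)
}

## Kernel prefactors for the simulator, per (source sign, target type):
## (exc->E, exc->I, inh->E, inh->I). External inputs share the exc entries.
kernel_prefactor <- function(sp, np) {
  kc <- c("ee", "ei", "ie", "ii")
  tau_m <- c(np$tau_m_exc, np$tau_m_inh, np$tau_m_exc, np$tau_m_inh)
  tr <- sp$rise[kc]; td <- sp$decay[kc]
  out <- switch(sp$kernel_norm,
                charge = tau_m / (td - tr),
                peak = 1 / mapply(kernel_unnormalised_peak, tr, td))
  stats::setNames(as.numeric(out), kc)
}

## Conductance elicited by one spike at time 0 through the given edge class,
## under the simulator's kernel convention (includes efficacy and prefactor).
conductance_response <- function(t, edge_class, sp, np,
                                 efficacy = sp$efficacy[[edge_class]]) {
  pf <- kernel_prefactor(sp, np)[[edge_class]]
  s <- t - sp$latency
  tr <- sp$rise[[edge_class]]; td <- sp$decay[[edge_class]]
  out <- numeric(length(t))
  pos <- s > 0
  out[pos] <- efficacy * pf * (exp(-s[pos] / td) - exp(-s[pos] / tr))
  out
}

#' @rdname synaptic_kernel
#' @return \code{kernel_peak_time}: the time since the presynaptic spike at
#'   which the kernel attains its maximum,
#'   \code{latency + rise*decay/(decay - rise) * log(decay/rise)}.
#' @export
kernel_peak_time <- function(edge_class = c("ee", "ie", "ei", "ii"),
                             sp = synapse_params()) {
  edge_class <- match.arg(edge_class)
  tr <- sp$rise[[edge_class]]; td <- sp$decay[[edge_class]]
  sp$latency + tr * td / (td - tr) * log(td / tr)
}

#' External Poisson spike trains
#'
#' Independent homogeneous Poisson processes, one per node, at the
#' configured external rate. This is the reference generator for the
#' external drive statistics; \code{\link{simulate_network}} draws an
#' equivalent stream internally (seeded from its own configuration) for
#' speed.
#'
#' @param config A \code{\link{sim_config}} (uses \code{ext_rate},
#'   \code{duration}, \code{seed}).
#' @param n_nodes Number of independent trains.
#' @return A list of numeric vectors of spike times in (0, duration], ms.
#' @export
generate_external_spikes <- function(config, n_nodes) {
  stopifnot(inherits(config, "sim_config"), n_nodes >= 0)
  if (config$ext_rate == 0)
    return(rep(list(numeric(0)), n_nodes))
  with_seed(config$seed, {
    lapply(seq_len(n_nodes), function(i) {
      ## draw gaps in blocks until the duration is covered
      times <- numeric(0); t_last <- 0
      repeat {
        k <- max(16L, ceiling(config$ext_rate *
                                (config$duration - t_last) * 1.2))
        gaps <- rexp(k, rate = config$ext_rate)
        times <- c(times, t_last + cumsum(gaps))
        t_last <- times[length(times)]
        if (t_last > config$duration) break
      }
      times[times <= config$duration]
    })
  })
}

#' Simulate the conductance-synapse LIF network
#'
#' Integrates the network dynamics: leaky integrate-and-fire membranes with
#' class-specific time constants and refractory periods, peak-normalised
#' difference-of-exponentials conductance synapses with a common onset
#' latency, threshold crossing detected at step boundaries, and independent
#' external Poisson drive through the excitatory-reversal synapse class.
#' All state variables start at zero. Synaptic states are advanced by exact
#' exponential updates; the membrane by exponential Euler per step.
#'
#' @param net A \code{directed_network}.
#' @param np A \code{\link{neuron_params}}.
#' @param sp A \code{\link{synapse_params}}; the onset latency must be an
#'   integer multiple of the step \code{sc$dt}.
#' @param sc A \code{\link{sim_config}}.
#' @param v_init Optional initial membrane potentials (mV, one per node);
#'   default all zero (rest).
#' @return A \code{sim_result} with elements \code{spikes} (data frame
#'   \code{time_ms}, \code{node}), \code{lfp} (if recorded: list with
#'   \code{values}, \code{time_ms}, \code{dt_sample}; the summed absolute
#'   synaptic currents into excitatory neurons), optional trace matrices
#'   \code{v}, \code{i_ext}, \code{i_exc}, \code{i_inh}, \code{g_ext},
#'   \code{g_exc}, \code{g_inh} (samples x recorded nodes), and \code{meta}
#'   (configuration echo, seeds, recorded node ids, sample times).
#' @examples
#' net <- build_random_fixed_indegree(
#'   topology_config(n_exc = 40, n_inh = 10, k_from_exc = 8, k_from_inh = 2))
#' res <- simulate_network(net, sc = sim_config(duration = 200, seed = 1))
#' nrow(res$spikes)
#' @export
simulate_network <- function(net, np = neuron_params(), sp = synapse_params(),
                             sc = sim_config(duration = 1000),
                             v_init = NULL) {
  stopifnot(inherits(net, "directed_network"),
            inherits(np, "neuron_params"), inherits(sp, "synapse_params"),
            inherits(sc, "sim_config"))
  lat_steps <- sp$latency / sc$dt
  if (abs(lat_steps - round(lat_steps)) > 1e-9)
    stop("onset latency must be an integer multiple of dt")
  lat_steps <- as.integer(round(lat_steps))
  n <- net$n_exc + net$n_inh
  n_steps <- as.integer(round(sc$duration / sc$dt))

  tadj <- as(Matrix::t(net$adj), "CsparseMatrix")  # per-origin target lists
  rec <- sc$record
  rec_nodes <- sc$record_nodes
  if (is.null(rec_nodes)) rec_nodes <- seq_len(n)
  if (any(rec_nodes < 1 | rec_nodes > n)) stop("record_nodes out of range")

  raw <- .sim_core(n, net$n_exc, tadj@p, tadj@i,
                   unclass(np), unclass(sp), kernel_prefactor(sp, np),
                   sc$dt, n_steps, lat_steps,
                   sc$ext_rate, sc$seed, sc$sample_every,
                   "lfp" %in% rec, "v" %in% rec, "currents" %in% rec,
                   "conductances" %in% rec,
                   rec_nodes - 1L,
                   if (is.null(v_init)) numeric(0) else as.numeric(v_init))

  sample_dt <- sc$dt * sc$sample_every
  sample_t <- seq_len(raw$n_samples) * sample_dt
  trace <- function(m) {
    if (nrow(m) == 0) return(NULL)
    colnames(m) <- as.character(rec_nodes)
    m
  }
  res <- list(
    spikes = data.frame(time_ms = raw$spike_times, node = raw$spike_ids),
    lfp = if ("lfp" %in% rec)
      list(values = raw$lfp, time_ms = sample_t, dt_sample = sample_dt),
    v = trace(raw$v),
    i_ext = trace(raw$i_ext), i_exc = trace(raw$i_exc),
    i_inh = trace(raw$i_inh),
    g_ext = trace(raw$g_ext), g_exc = trace(raw$g_exc),
    g_inh = trace(raw$g_inh),
    meta = list(n_nodes = n, n_exc = net$n_exc, n_inh = net$n_inh,
                ei = net$ei, struct_class = net$struct_class,
                neuron = np, synapse = sp, config = sc,
                record_nodes = rec_nodes, sample_times = sample_t,
                dt_sample = sample_dt,
                topology = net$provenance$topology))
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  m <- x$meta
  cat("LIF network simulation:", m$n_nodes, "neurons,",
      m$config$duration, "ms at dt =", m$config$dt, "ms\n")
  rate_e <- sum(x$spikes$node <= m$n_exc) / m$n_exc / m$config$duration * 1000
  rate_i <- sum(x$spikes$node > m$n_exc) / m$n_inh / m$config$duration * 1000
  cat(sprintf("  %d spikes (E: %.2f /s, I: %.2f /s over the full run)\n",
              nrow(x$spikes), rate_e, rate_i))
  cat("  recorded:", paste(m$config$record, collapse = ", "), "\n")
  invisible(x)
}

#' Fine-step subthreshold reference integrator
#'
#' Integrates the subthreshold membrane equation for a single neuron
#' receiving a given train of input spikes through one synapse class, using
#' an independent adaptive ODE solver (\code{deSolve::lsoda}) on the
#' analytic conductance waveform. Serves as an oracle for bounding the
#' integration error of the main simulator.
#'
#' @param np A \code{\link{neuron_params}}.
#' @param input_times Presynaptic spike times, ms.
#' @param edge_class Synapse class of the inputs (see
#'   \code{\link{synaptic_kernel}}); \code{"ee"}/\code{"ei"} use the
#'   excitatory reversal, \code{"ie"}/\code{"ii"} the inhibitory one.
#' @param target One of \code{"E"}, \code{"I"} (selects the membrane time
#'   constant).
#' @param efficacy Peak conductance per input spike (relative to leak).
#' @param times Output time grid, ms.
#' @param sp A \code{\link{synapse_params}}.
#' @param v0 Initial membrane potential, mV.
#' @return Data frame with columns \code{time_ms}, \code{v}.
#' @export
subthreshold_oracle <- function(np = neuron_params(), input_times = numeric(0),
                                edge_class = "ee", target = c("E", "I"),
                                efficacy = NULL, times = seq(0, 100, 0.05),
                                sp = synapse_params(), v0 = 0) {
  if (!requireNamespace("deSolve", quietly = TRUE))
    stop("subthreshold_oracle needs the deSolve package")
  target <- match.arg(target)
  tau_m <- if (target == "E") np$tau_m_exc else np$tau_m_inh
  vrev <- if (edge_class %in% c("ee", "ei")) np$v_rev_exc else np$v_rev_inh
  if (is.null(efficacy)) efficacy <- sp$efficacy[[edge_class]]
  g_of_t <- function(t) {
    if (length(input_times) == 0) return(0)
    sum(conductance_response(t - input_times, edge_class, sp, np,
                             efficacy = efficacy))
  }
  deriv <- function(t, y, parms) {
    g <- g_of_t(t)
    list((-y[1] + g * (vrev - y[1])) / tau_m)
  }
  out <- deSolve::lsoda(c(v = v0), times, deriv, parms = NULL,
                        rtol = 1e-9, atol = 1e-11)
  data.frame(time_ms = out[, "time"], v = out[, "v"])
}
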