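#' Neuron membrane parameters
#'
#' Leaky integrate-and-fire membrane parameters for the two physiological
#' neuron types. Membrane potential is measured relative to rest (rest =
#' 0 mV), so the excitatory reversal potential is depolarising (+70 mV) and
#' the inhibitory reversal potential is shunting at rest (0 mV),
#' hyperpolarising above rest.
#'
#' @param tau_m_exc Membrane time constant of excitatory (E) neurons, ms.
#' @param tau_m_inh Membrane time constant of inhibitory (I) neurons, ms.
#' @param v_rev_exc Reversal potential of excitatory (and external) synaptic
#'   currents, mV relative to rest.
#' @param v_rev_inh Reversal potential of inhibitory synaptic currents, mV.
#' @param refrac_exc Absolute refractory period of E neurons, ms.
#' @param refrac_inh Absolute refractory period of I neurons, ms.
#' @param v_thresh Spike threshold, mV.
#' @param v_reset Post-spike reset potential, mV.
#' @return A list of class \code{neuron_params}.
#' @examples
#' neuron_params()
#' @export
neuron_params <- function(tau_m_exc = 20, tau_m_inh = 10,
                          v_rev_exc = 70, v_rev_inh = 0,
                          refrac_exc = 2, refrac_inh = 1,
                          v_thresh = 18, v_reset = 11) {
  stopifnot(tau_m_exc > 0, tau_m_inh > 0,
            refrac_exc > 0, refrac_inh > 0,
            v_reset < v_thresh, v_thresh < v_rev_exc)
  structure(list(tau_m_exc = tau_m_exc, tau_m_inh = tau_m_inh,
                 v_rev_exc = v_rev_exc, v_rev_inh = v_rev_inh,
                 refrac_exc = refrac_exc, refrac_inh = refrac_inh,
                 v_thresh = v_thresh, v_reset = v_reset),
            class = "neuron_params")
}

#' Synapse parameters per edge class
#'
#' Difference-of-exponentials conductance synapses,
#' \code{g(t) = J * F * (exp(-(t-latency)/decay) - exp(-(t-latency)/rise))}
#' for \code{t > latency}. Rise and decay time constants are shared between
#' external and recurrent excitatory synapses onto a given target type;
#' efficacies J (dimensionless, relative to the leak conductance) differ per
#' edge class.
#'
#' The prefactor F is set by \code{kernel_norm}:
#' \describe{
#'   \item{\code{"charge"} (default)}{\code{F = tau_m / (decay - rise)} with
#'     the target's membrane time constant, so one spike contributes the
#'     conductance integral \code{J * tau_m} (the convention of the
#'     current-based predecessors of this model family). This is the
#'     normalisation under which the default efficacies yield the balanced
#'     operating regime; see the methods vignette.}
#'   \item{\code{"peak"}}{\code{F = 1/max_t(...)}, so J is the peak
#'     conductance of a single spike.}
#' }
#'
#' Edge-class naming: \code{ee} = E (or Ext) onto E, \code{ie} = I onto E,
#' \code{ei} = E (or Ext) onto I, \code{ii} = I onto I.
#'
#' @param latency Axonal/synaptic onset latency, ms (all edge classes).
#' @param rise Named numeric vector of rise time constants, ms, with names
#'   \code{ee, ie, ei, ii}.
#' @param decay Named numeric vector of decay time constants, ms (same names).
#' @param efficacy Named numeric vector of efficacies relative to leak, with
#'   names \code{ee, ei, ie, ii, ext_e, ext_i}.
#' @param kernel_norm Kernel prefactor convention, \code{"charge"} or
#'   \code{"peak"}.
#' @return A list of class \code{synapse_params}.
#' @examples
#' synapse_params()
#' @export
synapse_params <- function(latency = 2,
                           rise = c(ee = 0.4, ie = 0.25, ei = 0.2, ii = 0.25),
                           decay = c(ee = 2, ie = 5, ei = 1, ii = 5),
                           efficacy = c(ee = 0.0076, ei = 0.011,
                                        ie = 0.113, ii = 0.180,
                                        ext_e = 0.008, ext_i = 0.014),
                           kernel_norm = c("charge", "peak")) {
  kc <- c("ee", "ie", "ei", "ii")
  kernel_norm <- match.arg(kernel_norm)
  stopifnot(latency >= 0,
            all(kc %in% names(rise)), all(kc %in% names(decay)),
            all(c(kc, "ext_e", "ext_i") %in% names(efficacy)),
            all(rise[kc] > 0), all(efficacy >= 0))
  if (any(rise[kc] >= decay[kc]))
    stop("synaptic rise time must be strictly smaller than decay time")
  structure(list(latency = latency, rise = rise[kc], decay = decay[kc],
                 efficacy = efficacy[c(kc, "ext_e", "ext_i")],
                 kernel_norm = kernel_norm),
            class = "synapse_params")
}

#' Simulation configuration
#'
#' @param duration Simulated time, ms.
#' @param dt Integration step, ms. The onset latency must be an integer
#'   multiple of \code{dt}.
#' @param burn_in Initial interval, ms, flagged for exclusion from analyses
#'   (all state variables start at zero, so early activity is transient).
#' @param ext_rate External Poisson spike rate per neuron, spikes/ms. The
#'   default is the package's calibrated operating point at which the
#'   default full-scale random network fires at about 1 spike/s (E neurons);
#'   see the methods vignette.
#' @param seed Integer seed for the simulator's random stream (external
#'   spike trains).
#' @param record Character vector of recording switches, any of
#'   \code{"spikes"}, \code{"lfp"}, \code{"v"}, \code{"currents"},
#'   \code{"conductances"}. Traces are recorded at \code{sample_every} steps
#'   for the nodes in \code{record_nodes}.
#' @param record_nodes Integer node ids (1-based) whose traces to record;
#'   \code{NULL} records all nodes (only sensible at small scale).
#' @param sample_every Sampling stride for traces and the LFP, in steps.
#'   The default samples once per millisecond at \code{dt = 0.05}.
#' @return A list of class \code{sim_config}.
#' @examples
#' sim_config(duration = 1000, seed = 1)
#' @export
sim_config <- function(duration, dt = 0.05, burn_in = 100,
                       ext_rate = 2.8, seed = 1L,
                       record = c("spikes", "lfp"),
                       record_nodes = NULL,
                       sample_every = max(1L, round(1 / dt))) {
  stopifnot(dt > 0, duration > burn_in, burn_in >= 0, ext_rate >= 0,
            sample_every >= 1)
  record <- match.arg(record, c("spikes", "lfp", "v", "currents",
                                "conductances"), several.ok = TRUE)
  structure(list(duration = duration, dt = dt, burn_in = burn_in,
                 ext_rate = ext_rate, seed = as.integer(seed),
                 record = record,
                 record_nodes = if (is.null(record_nodes)) NULL
                                else as.integer(record_nodes),
                 sample_every = as.integer(sample_every)),
            class = "sim_config")
}
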