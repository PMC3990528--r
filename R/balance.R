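#' LFP trace container
#'
#' The model local field potential: a nonnegative time series proportional
#' to the summed absolute synaptic currents into excitatory neurons.
#'
#' @param values Nonnegative numeric series.
#' @param dt_sample Sampling interval, ms.
#' @param time_ms Optional sample times; defaults to
#'   \code{dt_sample * seq_along(values)}.
#' @return A list of class \code{lfp_trace}.
#' @export
lfp_trace <- function(values, dt_sample, time_ms = dt_sample * seq_along(values)) {
  stopifnot(all(values >= 0), dt_sample > 0, length(time_ms) == length(values))
  structure(list(values = as.numeric(values), time_ms = time_ms,
                 dt_sample = dt_sample), class = "lfp_trace")
}

#' Compute the model LFP from recorded currents
#'
#' Sums the absolute values of the three synaptic current types (external,
#' recurrent excitatory, recurrent inhibitory) over the recorded excitatory
#' neurons at every sample, times a proportionality constant. The simulator
#' can also record this quantity directly over all E neurons
#' (\code{record = "lfp"}); the two routes agree when all E neurons' currents
#' are recorded.
#'
#' @param result A \code{sim_result} with current traces
#'   (\code{record = "currents"}) for excitatory neurons.
#' @param constant Proportionality constant (default 1).
#' @return An \code{\link{lfp_trace}}.
#' @export
compute_lfp <- function(result, constant = 1) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(result$i_ext))
    stop("current traces were not recorded; rerun with record = \"currents\"")
  rec <- result$meta$record_nodes
  e_cols <- which(rec <= result$meta$n_exc)
  if (length(e_cols) == 0)
    stop("no excitatory neurons among the recorded nodes")
  vals <- rowSums(abs(result$i_ext[, e_cols, drop = FALSE])) +
          rowSums(abs(result$i_exc[, e_cols, drop = FALSE])) +
          rowSums(abs(result$i_inh[, e_cols, drop = FALSE]))
  lfp_trace(constant * vals, result$meta$dt_sample,
            result$meta$sample_times)
}

## The LFP the simulator records directly, as an lfp_trace.
recorded_lfp <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(result$lfp))
    stop("the LFP was not recorded; rerun with record = \"lfp\"")
  lfp_trace(result$lfp$values, result$lfp$dt_sample, result$lfp$time_ms)
}

## centred sliding window value series: f applied to windows of width w
## (samples), each sample assigned the window centred on it (clipped at the
## edges to the nearest full window).
centred_window_means <- function(x, w) {
  n <- length(x)
  if (w >= n) return(rep(mean(x), n))
  cs <- cumsum(c(0, x))
  wm <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w   # window starts 1..n-w+1
  start <- pmin(pmax(seq_len(n) - ((w - 1L) %/% 2L), 1L), n - w + 1L)
  wm[start]
}

#' Two-pass network up/down-state detection from the LFP
#'
#' Pass 1 smooths the LFP with a sliding uniform window (default 100 ms,
#' 1-sample stride); the baseline window is the window with the smallest
#' mean, and preliminary upstate samples are those whose window mean exceeds
#' the baseline mean by \code{k_sd} baseline-window standard deviations.
#' Pass 2 refines each preliminary upstate's boundaries with a short
#' geometric-mean window (default 5 ms; the LFP distribution is strongly
#' positively skewed) against the same criterion. The result tiles the trace
#' with alternating up and down intervals, each with its duration and
#' geometric-mean LFP.
#'
#' The criterion is mean/SD based and the geometric means are compared to
#' the same threshold, so the detector is invariant to multiplying the LFP
#' by a positive constant. A constant trace yields a single downstate.
#'
#' @param lfp An \code{\link{lfp_trace}} (or a \code{sim_result} with a
#'   recorded LFP).
#' @param coarse_window Pass-1 uniform window, ms.
#' @param fine_window Pass-2 geometric-mean window, ms.
#' @param k_sd Threshold in baseline standard deviations above the baseline
#'   mean.
#' @param merge_gap If non-\code{NULL}, upstates separated by less than this
#'   many ms are merged into one event (used for transition analyses).
#' @param skip_ms Initial interval to drop before detection (the simulator's
#'   burn-in), ms.
#' @return A \code{state_intervals} object: \code{intervals} data frame
#'   (\code{state}, \code{start_ms}, \code{end_ms}, \code{duration_ms},
#'   \code{geo_mean}, \code{censored}), and \code{summary} with per-state
#'   mean/max durations over uncensored intervals and the switch count.
#' @export
detect_up_down_states <- function(lfp, coarse_window = 100, fine_window = 5,
                                  k_sd = 3, merge_gap = NULL, skip_ms = 0) {
  if (inherits(lfp, "sim_result")) lfp <- recorded_lfp(lfp)
  stopifnot(inherits(lfp, "lfp_trace"), all(lfp$values >= 0))
  dts <- lfp$dt_sample
  keep <- lfp$time_ms > skip_ms
  x <- lfp$values[keep]
  t0 <- if (skip_ms > 0) skip_ms else 0
  n <- length(x)
  cw <- max(1L, as.integer(round(coarse_window / dts)))
  fw <- max(1L, as.integer(round(fine_window / dts)))
  if (n <= cw) stop("trace must be longer than the coarse window")

  ## pass 1: coarse means, baseline window, threshold
  cs <- cumsum(c(0, x))
  wm <- (cs[(cw + 1):(n + 1)] - cs[1:(n - cw + 1)]) / cw
  b <- which.min(wm)
  base <- x[b:(b + cw - 1)]
  theta <- mean(base) + k_sd * sd(base)
  coarse <- centred_window_means(x, cw)
  prelim <- coarse > theta

  eps <- 1e-12 * max(x, 1e-300)
  up <- rep(FALSE, n)
  if (any(prelim)) {
    ## pass 2: geometric-mean refinement of each preliminary upstate
    gm <- exp(centred_window_means(log(x + eps), fw))
    fine <- gm > theta
    r <- rle(prelim)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      a <- starts[k]; z <- ends[k]
      if (!any(fine[a:z])) next            # no fine-scale support: drop
      a2 <- if (fine[a]) {
        w <- a; while (w > 1 && fine[w - 1L]) w <- w - 1L; w
      } else a + min(which(fine[a:z])) - 1L
      z2 <- if (fine[z]) {
        w <- z; while (w < n && fine[w + 1L]) w <- w + 1L; w
      } else a + max(which(fine[a:z])) - 1L
      up[a2:z2] <- TRUE
    }
  }

  ## optional merging of briefly interrupted upstates
  if (!is.null(merge_gap) && any(up)) {
    r <- rle(up)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    gap <- !r$values & r$lengths * dts < merge_gap
    interior <- seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
    for (k in which(gap & interior)) up[starts[k]:ends[k]] <- TRUE
  }

  r <- rle(up)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  geo <- vapply(seq_along(r$values), function(k)
    exp(mean(log(x[starts[k]:ends[k]] + eps))), numeric(1))
  intervals <- data.frame(
    state = ifelse(r$values, "up", "down"),
    start_ms = t0 + (starts - 1L) * dts,
    end_ms = t0 + ends * dts,
    geo_mean = geo)
  intervals$duration_ms <- intervals$end_ms - intervals$start_ms
  intervals$censored <- seq_len(nrow(intervals)) %in%
    c(1L, nrow(intervals))
  ok <- !intervals$censored
  dur_stats <- function(st) {
    d <- intervals$duration_ms[ok & intervals$state == st]
    c(n = length(d), mean_ms = if (length(d)) mean(d) else NA_real_,
      max_ms = if (length(d)) max(d) else NA_real_)
  }
  out <- list(intervals = intervals[, c("state", "start_ms", "end_ms",
                                        "duration_ms", "geo_mean",
                                        "censored")],
              summary = list(up = dur_stats("up"), down = dur_stats("down"),
                             n_switches = nrow(intervals) - 1L,
                             n_upstates = sum(intervals$state == "up"),
                             threshold = theta,
                             baseline_mean = mean(base),
                             baseline_sd = sd(base)),
              params = list(coarse_window = coarse_window,
                            fine_window = fine_window, k_sd = k_sd,
                            merge_gap = merge_gap, skip_ms = skip_ms,
                            dt_sample = dts))
  class(out) <- "state_intervals"
  out
}

#' @export
print.state_intervals <- function(x, ...) {
  s <- x$summary
  cat("Up/down state intervals:", nrow(x$intervals), "intervals,",
      s$n_switches, "switches\n")
  cat(sprintf("  upstates:   n = %d, mean %.1f ms, max %.1f ms (uncensored)\n",
              s$up["n"], s$up["mean_ms"], s$up["max_ms"]))
  cat(sprintf("  downstates: n = %d, mean %.1f ms, max %.1f ms (uncensored)\n",
              s$down["n"], s$down["mean_ms"], s$down["max_ms"]))
  invisible(x)
}

#' Low-state membrane-potential threshold from a reference run
#'
#' The per-neuron low state is defined relative to membrane potentials
#' observed in a matched random-network (balanced) run: the threshold is the
#' mean minus two standard deviations of all recorded membrane samples after
#' the burn-in.
#'
#' @param result A \code{sim_result} of a random-network run with membrane
#'   traces (\code{record = "v"}).
#' @return The threshold, mV.
#' @export
low_state_threshold <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(result$v)) stop("membrane traces were not recorded")
  keep <- result$meta$sample_times > result$meta$config$burn_in
  v <- result$v[keep, , drop = FALSE]
  mean(v) - 2 * sd(v)
}

#' Per-neuron high / neutral / low state classification
#'
#' At every analysis bin a neuron is \emph{high} if it spiked at least once
#' within the trailing window (default 15 ms), otherwise \emph{low} if its
#' membrane potential is below \code{low_v_threshold}, otherwise
#' \emph{neutral}. High overrides low: a recently spiking neuron is never
#' classified low in the same bin.
#'
#' @param result A \code{sim_result} with membrane traces and spikes.
#' @param low_v_threshold Low-state membrane threshold, mV (see
#'   \code{\link{low_state_threshold}}).
#' @param high_window Trailing spike window for the high state, ms.
#' @return A \code{neuron_state_series}: integer matrix (samples x recorded
#'   nodes) with levels 1 = high, 2 = neutral, 3 = low, plus the thresholds
#'   used, as attributes \code{levels}, \code{low_v_threshold},
#'   \code{high_window}.
#' @export
classify_neuron_states <- function(result, low_v_threshold,
                                   high_window = 15) {
  stopifnot(inherits(result, "sim_result"), is.numeric(low_v_threshold))
  if (is.null(result$v))
    stop("membrane traces were not recorded; rerun with record = \"v\"")
  tt <- result$meta$sample_times
  rec <- result$meta$record_nodes
  sp <- split(result$spikes$time_ms, factor(result$spikes$node,
                                            levels = rec))
  lab <- matrix(2L, nrow = length(tt), ncol = length(rec),
                dimnames = list(NULL, as.character(rec)))
  lab[result$v < low_v_threshold] <- 3L
  for (r in seq_along(rec)) {
    st <- sp[[r]]
    if (length(st) == 0) next
    high <- findInterval(tt, st) > findInterval(tt - high_window, st)
    lab[high, r] <- 1L
  }
  structure(lab, levels = c("high", "neutral", "low"),
            low_v_threshold = low_v_threshold, high_window = high_window,
            class = c("neuron_state_series", "matrix", "array"))
}

#' Highly-active neuron thresholds
#'
#' Rate thresholds above which a neuron counts as highly active within an
#' interval: more than 4 spikes/s for E neurons and more than 30 spikes/s
#' for I neurons (strict inequalities), derived from average rates in the
#' balanced random network. The refractory periods bound attainable rates at
#' 500 spikes/s (E) and 1000 spikes/s (I).
#'
#' @param highly_active_exc,highly_active_inh Thresholds in spikes/s.
#' @return A list of class \code{activity_thresholds}.
#' @export
activity_thresholds <- function(highly_active_exc = 4,
                                highly_active_inh = 30) {
  stopifnot(highly_active_exc > 0, highly_active_inh > 0)
  structure(list(highly_active_exc = highly_active_exc,
                 highly_active_inh = highly_active_inh),
            class = "activity_thresholds")
}

#' Per-node firing rates within an interval
#'
#' @param result A \code{sim_result} (or a spikes data frame with columns
#'   \code{time_ms}, \code{node}; then \code{n_nodes} is required).
#' @param interval \code{c(start_ms, end_ms)}; default is burn-in to end of
#'   run.
#' @param n_nodes Number of nodes (taken from \code{result$meta} when a
#'   \code{sim_result} is given).
#' @return Numeric vector of rates in spikes/s, one per node.
#' @export
firing_rates <- function(result, interval = NULL, n_nodes = NULL) {
  if (inherits(result, "sim_result")) {
    if (is.null(interval))
      interval <- c(result$meta$config$burn_in, result$meta$config$duration)
    n_nodes <- result$meta$n_nodes
    spikes <- result$spikes
  } else spikes <- result
  stopifnot(!is.null(n_nodes), length(interval) == 2,
            interval[2] > interval[1])
  sel <- spikes$time_ms > interval[1] & spikes$time_ms <= interval[2]
  counts <- tabulate(spikes$node[sel], nbins = n_nodes)
  counts / (interval[2] - interval[1]) * 1000
}

#' Flag highly active neurons within an interval
#'
#' A node is flagged when its firing rate within the interval strictly
#' exceeds its physiological class threshold.
#'
#' @param result A \code{sim_result} or spikes data frame.
#' @param interval \code{c(start_ms, end_ms)}.
#' @param ei_label Per-node \code{"E"}/\code{"I"} labels (taken from
#'   \code{result$meta} when available).
#' @param thresholds An \code{\link{activity_thresholds}}.
#' @return Logical vector, one flag per node.
#' @export
classify_highly_active <- function(result, interval,
                                   ei_label = NULL,
                                   thresholds = activity_thresholds()) {
  if (inherits(result, "sim_result") && is.null(ei_label))
    ei_label <- result$meta$ei
  stopifnot(!is.null(ei_label))
  if (interval[2] <= interval[1]) stop("zero-length interval")
  rates <- firing_rates(result, interval, n_nodes = length(ei_label))
  thr <- ifelse(ei_label == "E", thresholds$highly_active_exc,
                thresholds$highly_active_inh)
  rates > thr
}

#' Functional in-degree
#'
#' Per node, the number of incoming edges whose origin is flagged as highly
#' active and belongs to the requested origin class. During a network
#' upstate this transient functional topology differs from the (constant)
#' structural in-degrees.
#'
#' @param net A \code{directed_network}.
#' @param active_flags Logical vector, one per node (see
#'   \code{\link{classify_highly_active}}).
#' @param origin_class Origin restriction: \code{"all"}, \code{"E"},
#'   \code{"I"}, or a structural label such as \code{"E2"}, \code{"I2"}.
#' @return Integer vector of counts, one per node.
#' @export
functional_in_degree <- function(net, active_flags, origin_class = "all") {
  stopifnot(inherits(net, "directed_network"),
            length(active_flags) == nrow(net$adj))
  six <- paste0(net$ei, net$struct_class)
  in_class <- switch(origin_class,
                     all = rep(TRUE, length(six)),
                     E = net$ei == "E",
                     I = net$ei == "I",
                     six == origin_class)
  mask <- which(active_flags & in_class)
  as.integer(Matrix::colSums(net$adj[mask, , drop = FALSE]))
}

#' Per-class rate, conductance and state-occupancy summary
#'
#' For every structural class present (E1..I3): node count, mean firing rate
#' within the interval, mean recorded excitatory and inhibitory conductances
#' (when \code{record = "conductances"}), and — when membrane traces and a
#' low-state threshold are available — the time-averaged fraction of the
#' class in the high, neutral and low neuron states.
#'
#' @param result A \code{sim_result}.
#' @param net The simulated \code{directed_network} (for structural labels;
#'   defaults to the labels echoed in \code{result$meta}).
#' @param interval \code{c(start_ms, end_ms)}; default burn-in to end.
#' @param low_v_threshold Optional low-state threshold, mV.
#' @param high_window Trailing high-state window, ms.
#' @return A data frame, one row per class.
#' @export
class_rate_and_conductance_summary <- function(result, net = NULL,
                                               interval = NULL,
                                               low_v_threshold = NULL,
                                               high_window = 15) {
  stopifnot(inherits(result, "sim_result"))
  ei <- if (is.null(net)) result$meta$ei else net$ei
  sc <- if (is.null(net)) result$meta$struct_class else net$struct_class
  six <- paste0(ei, sc)
  if (is.null(interval))
    interval <- c(result$meta$config$burn_in, result$meta$config$duration)
  rates <- firing_rates(result, interval, n_nodes = length(ei))
  rec <- result$meta$record_nodes
  in_int <- result$meta$sample_times > interval[1] &
    result$meta$sample_times <= interval[2]
  states <- if (!is.null(result$v) && !is.null(low_v_threshold))
    classify_neuron_states(result, low_v_threshold, high_window)
  rows <- lapply(sort(unique(six)), function(cl) {
    idx <- which(six == cl)
    row <- data.frame(class = cl, n = length(idx),
                      mean_rate = mean(rates[idx]),
                      mean_g_exc = NA_real_, mean_g_inh = NA_real_,
                      frac_high = NA_real_, frac_neutral = NA_real_,
                      frac_low = NA_real_)
    rcols <- which(rec %in% idx)
    if (!is.null(result$g_exc) && length(rcols)) {
      row$mean_g_exc <- mean(result$g_exc[in_int, rcols, drop = FALSE] +
                               result$g_ext[in_int, rcols, drop = FALSE])
      row$mean_g_inh <- mean(result$g_inh[in_int, rcols, drop = FALSE])
    }
    if (!is.null(states) && length(rcols)) {
      s <- states[in_int, rcols, drop = FALSE]
      row$frac_high <- mean(s == 1L)
      row$frac_neutral <- mean(s == 2L)
      row$frac_low <- mean(s == 3L)
    }
    row
  })
  do.call(rbind, rows)
}
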