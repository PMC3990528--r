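---
title: "Structured topology and bistable balance in a cortical network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured topology and bistable balance in a cortical network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(balancenet)
```

## The scientific question

Cortical circuits usually operate in a *balanced* regime: every neuron
receives strong excitation and strong inhibition whose net effect keeps the
membrane potential just below threshold, so that firing is sparse,
irregular, and driven by fluctuations. Most models that reproduce this
regime connect their neurons with a directed random graph. `balancenet`
implements a family of models that keep every neuron's *in-degree*
fixed — 800 excitatory and 200 inhibitory synapses per neuron at the
default scale, always 20% of the size of the originating population — while
changing only *where* those synapses come from. The question is whether
such purely topological changes can destroy balance, and they can: a
ring-lattice network in which a small fraction of neurons has its incoming
inhibition rewired to random, non-local origins switches stochastically
between a quiet "downstate" and a locally hyperactive "upstate" at roughly
one-second time scales, even though every neuron keeps identical intrinsic
dynamics and identical in-degree counts.

## Network constructors

All four topologies share the node layout: excitatory (E) nodes first,
inhibitory (I) nodes after them, adjacency oriented origin-row to
target-column, no self-edges.

* `build_random_fixed_indegree()` — the null-hypothesis network. Incoming
  edge origins are drawn uniformly without replacement per node, so
  in-degrees are exactly constant; out-degrees are random with the correct
  mean (an exact-out-degree "doubly regular" construction is deliberately
  out of scope).
* `build_ring_lattice()` — a deterministic forwards-backwards ring: E node
  *m* receives edges from its k/2 nearest E neighbours in both directions;
  the I ring is analogous; cross-class edges use symmetric windows arranged
  so that adjacent E nodes receive input from the same I nodes and project
  to adjacent I nodes. The E-E submatrix is symmetric, so the lattice is
  maximally reciprocated — this is what makes reciprocal counts a
  fingerprint of the construction later.
* `rewire_lattice()` — each node independently becomes Class 2 with
  probability `p2` (default 0.075: all incoming *inhibitory* edges get new
  origins drawn from I nodes that did not project to it in the lattice) or,
  if not Class 2, Class 3 with probability `p3` (all incoming edges
  rewired). Only edge *origins* change, so in-degrees are bit-identical
  before and after. Class 2 neurons therefore keep their dense local
  excitatory neighbourhood but lose all local inhibition — the structural
  motif behind the bistability.
* `build_embedded_modular()` — non-overlapping modules of E neurons with
  dense within-module and sparse between-module Bernoulli connectivity.
  This is the one constructor without exactly constant in-degrees, which
  its provenance records.

Two constructor details are genuinely open choices. The lattice window
arithmetic (which I nodes feed an E block, where an I node's E window is
centred) is fixed here as: E node *m* takes I origins
`floor(m/c) ± 1..k/2` on the I ring (`c = n_exc/n_inh`), and I node *n*
takes E origins `c·n ± 1..k/2`; this satisfies both adjacency-preservation
properties above. Second, the lattice-origin exclusion rule that the
construction states for Class 2 is also applied to Class 3 resampling by
default (`exclude_original_class3 = TRUE`), for symmetry; the flag
preserves the alternative reading. The Class-3 probability `p3` has no
recoverable published value; the package default is 0.05 — small, the same
order as `p2`, and consistent with the observation that results with the
selected value behave like `p3 = 0`.

## Neuron and synapse model

Leaky integrate-and-fire neurons with conductance synapses, voltages
relative to rest:

$$\tau_m \dot V_i = -V_i + \sum_{k \in \{ext, exc, inh\}} g_{i,k}(t)\,
  (V^{rev}_k - V_i),$$

with $\tau_m$ = 20 ms (E) / 10 ms (I), threshold 18 mV, reset 11 mV,
refractory 2 ms (E) / 1 ms (I), excitatory/external reversal +70 mV and
inhibitory reversal 0 mV — inhibition is *shunting* at rest and
hyperpolarising above it. Each presynaptic spike, after a 2-ms onset
latency, adds a difference-of-exponentials conductance

$$g(t) = J \, F \, \left(e^{-t/\tau_d} - e^{-t/\tau_r}\right),$$

with class-specific rise/decay constants (0.4/2 ms for excitatory and
external synapses onto E, 0.2/1 ms onto I, 0.25/5 ms for inhibitory
synapses). External drive is an independent homogeneous Poisson train per
neuron through the external synapse class.

**The kernel prefactor F and the E-to-E efficacy are the two places where
this package had to make a real modelling decision.** The published form of
the model fixes the time constants and efficacies but not the kernel
normalisation. We evaluated three conventions at full scale — peak
normalised ($F = 1/\max$), unit area ($F = 1/(\tau_d-\tau_r)$), and the
convention of the current-based predecessors of this model family,
$F = \tau_m/(\tau_d-\tau_r)$, under which one spike contributes conductance
integral $J\,\tau_m$ ("charge" normalisation). Only the charge convention
produces a *robust* balanced regime: with it, the default random network
settles from zero initial conditions into sparse irregular firing over a
broad plateau of external rates (roughly 1.6–2.8 spikes/ms), with E
neurons near 1 spike/s and I neurons near 4 spikes/s — the operating point
this model family reports. Under the other two conventions the quiescent
state jumps discontinuously into a saturated state with no balanced window
at any external rate. `synapse_params(kernel_norm = "peak")` preserves the
alternative for experimentation, and `synaptic_kernel()` always reports the
peak-normalised *shape* (maximum 1 at the analytic argmax).

Relatedly, the efficacy table is internally consistent with the
predecessor models' millivolt efficacies divided by the typical driving
force of the corresponding synapse for every class except recurrent E→E,
whose published value (0.028) appears to have been converted with the
inhibitory driving force. The package default is `ee = 0.0076`
(= 0.42 mV / 55 mV, the excitatory-driving conversion). This is not a free
tuning knob: with 0.028 the excitatory positive feedback makes the
saturated state absorbing under *every* kernel convention, extinguishing
the balanced regime entirely, while values below ≈0.0075 extinguish the E
population instead (an I-only state wins). The default external rate,
`ext_rate = 2.8` spikes/ms, is the calibrated operating point within the
balanced plateau at which both class rates match the published values; it
is recorded here once and not revisited.

## Numerical integration

Synaptic states are a rising and a decaying exponential per current type
per neuron, advanced by *exact* exponential updates between events; the
membrane uses exponential Euler per `dt` (default 0.05 ms), with spikes
detected at step boundaries without interpolation and the onset latency
implemented as a circular pending-delivery buffer (`latency/dt` slots).
State variables all start at zero; analyses discard a 100-ms burn-in.
Decayed-out synaptic states are flushed to zero below 1e-120 to avoid
subnormal-arithmetic stalls; the hot loop uses a degree-7 polynomial for
`exp(-x)` with |error| < 1.1e-7, negligible against the O(dt) integrator
error. External arrivals use one counter-based (splitmix64) stream per
neuron, so the drive realisation depends only on the seed and neuron id —
not on `dt`, which makes step-refinement comparisons meaningful — and
`simulate_network()` is bit-reproducible given (network, parameters, seed).

Two accuracy checks are built into the test suite: pure leak decay matches
the closed form to < 0.1% relative error, and the response to a single
synaptic spike matches an independent adaptive-step integration
(`subthreshold_oracle()`, `deSolve::lsoda` on the analytic conductance
waveform) to < 1% at the peak. A caveat on step-size studies: the network
itself is chaotic, so two runs at different `dt` decorrelate within
~100 ms and single-run spike counts differ by several percent for *any*
integrator; only ensemble means are comparable across `dt`.

## LFP and the two-pass up/down-state detector

The model LFP is the sum of absolute synaptic currents into excitatory
neurons (`compute_lfp()`, or recorded directly by the simulator at 1-ms
resolution — analyses run on this 1-ms series; windows are specified in
ms, so results are resolution-robust). Detection
(`detect_up_down_states()`) is two-pass: a sliding 100-ms uniform mean
(1-sample stride) defines the baseline window as the window with the
smallest mean; samples whose window mean exceeds the baseline mean by 3
baseline standard deviations are preliminary upstates; a second pass
refines each boundary with 5-ms sliding *geometric* means (the LFP
distribution is strongly right-skewed) against the same threshold.
Intervals tile the analysed span and alternate; the first and last
(censored) intervals are excluded from duration statistics. Geometric means
add `1e-12 × max` before the log to tolerate silent samples, and the whole
criterion is invariant to rescaling the LFP by a positive constant. A
`merge_gap` option (default off; 75 ms in transition analyses) merges
briefly interrupted upstates into single events.

Per-neuron states (`classify_neuron_states()`) follow the two-threshold
rule: *high* if the neuron spiked within the trailing 15 ms, else *low* if
its membrane potential is below a threshold derived from a seed-matched
random-network run (`low_state_threshold()`: mean − 2 SD of recorded
membrane samples; the published mV value is not recoverable, so the
derivation is the documented default), else *neutral*. "Highly active"
neurons within an interval exceed 4 spikes/s (E) or 30 spikes/s (I),
strictly; `functional_in_degree()` then counts incoming edges from highly
active origins of a chosen class.

## Motif metrics and class identification

`reciprocal_counts()` splits each node's reciprocally connected partners by
feedback sign (even number of inhibitory edges = positive: E–E and I–I
pairs; odd = negative: E–I pairs). `ffi_counts()` counts feed-forward
inhibition motifs (E→x, I→x, E→I) per convergence target via the diagonal
of a product of class-restricted submatrices, and `cycle_counts()` counts
directed 3-cycles x→E→I→x (negative feedback) and x→E→E→x (positive
feedback); each node on a cycle counts it once as reference. All motif
nodes are distinct by construction (no self-edges, class-disjoint roles,
zero diagonals). `brute_force_motif_counts()` is a deliberately naive
enumerator kept as the independent oracle; the suite checks exact agreement
on hundreds of seeded random graphs.

`identify_structural_classes()` recovers Class 1/2/3 labels from
connectivity alone: within each E/I population the integer histogram of
total reciprocal counts separates into strata (unrewired nodes keep the
fully reciprocated lattice neighbourhood; Class 2 loses its reciprocated
I partners; Class 3 loses almost everything), and strata map to classes by
descending count. Gap-finding uses the *widest* runs of empty integer bins
(at most two separators): a finite binomial stratum spread over ~50 integer
bins contains internal empty bins by chance, so "any empty bin" would
over-split; the true inter-class gaps are orders of magnitude wider than
any within-stratum gap at both full and test scale. When fewer than three
strata exist the result carries a warning flag, and with rewiring switched
off everything is Class 1.

## Experiments, seeds and scale

`run_experiment()` wires the stages together (build → simulate → LFP →
states → summaries → motifs) and writes plain-text artifacts plus a JSON
manifest; a master seed expands through `derive_seeds()` into independent
per-component streams, and identical configurations produce byte-identical
artifacts. `sweep_rewiring()` reproduces the rewiring-probability analyses:
the time-averaged fraction of each structural class in the high and low
states over a (p2, p3) grid, with the low-state threshold derived per
realisation from a matched random network.

Problem sizes: the full-scale defaults are 4000 E + 1000 I neurons with
in-degrees 800/200. The test suite exercises constructors and analyses at
1/5 linear scale (800 E + 200 I, in-degrees 160/40 — the same 20% rule)
and reserves full scale for the structural checks, a 5-s rate check, a
5-seed lattice/rewired contrast, and one 100-s bistability run; the
acceptance script uses full scale throughout.

## What the synthetic conditions do and do not show

The generator-driven runs demonstrate the model's internal phenomenology:
exact in-degree conservation, balance in the random and lattice networks,
Class-2-driven bistability in the rewired lattice, and exact class recovery
from connectivity. They do not establish anything about real cortical
tissue: the topology is a stylised ring, neurons within a physiological
class are identical, synapses are static, and the external drive is
homogeneous Poisson. Two known limitations deserve emphasis. First, at the
package's operating point the rewired lattice re-enters upstates about
130 ms after each termination (slightly supercritical Class-2 clusters),
so downstates are several times shorter than the published ~0.6 s while
upstate durations and both class rates match; no parameter within the
documented freedoms lengthened them, and the discrepancy is reported as
measured. Second, the embedded modular network reproduces loss of balance
but, as in the original account, not robust bistability; it is provided as
a comparison topology, not an object of the duration analyses.
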