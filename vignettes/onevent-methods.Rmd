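---
title: "Methods: event-based simulation of conductance-based point neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-based simulation of conductance-based point neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, algorithms,
parameter choices and limitations. The empirical behaviour it refers to
is exactly what the test suite and `scripts/acceptance.R` compute;
nothing beyond those runs is claimed.

## The conductance-based point models

All six catalogue models are single-compartment cells obeying

$$C_m \frac{dV}{dt} = -g_{Na} m^3 h (V - E_{Na}) - g_K n^4 (V - E_K)
  - g_L (V - E_L) - g_e(t)(V - E_e) - g_i(t)(V - E_i),$$

with first-order gating kinetics
$\dot x = \alpha_x(V)(1-x) - \beta_x(V)x$ for $x \in \{m, h, n\}$.

* The five HH parameterizations (`base`, `lw`, `lt`, `lwlt`, `burst`)
  share the classic squid-axon rate functions and constants
  ($g_{Na} = 0.12$, $g_K = 0.036$, $g_L = 3\times10^{-4}$ S/cm²,
  $E_{Na} = 50$, $E_K = -77$, $E_L = -54.3$ mV, $C_m = 1$ µF/cm²) and
  differ only in their synapses (weights in µS, decay constants in ms;
  see `inst/extdata/point_models.csv`). No temperature scaling is
  applied.
* The `wb` model uses the fast-spiking interneuron kinetics: activation
  $m$ is instantaneous ($m = m_\infty(V)$), $h$ and $n$ rates are
  scaled by $\phi = 5$, with $g_{Na} = 0.035$, $g_K = 0.009$,
  $g_L = 10^{-4}$ S/cm², $E_{Na} = 55$, $E_K = -90$, $E_L = -65$ mV.
  Because $m$ is instantaneous it is *not* a state variable: WB state
  frames carry only $(V_m, h, n)$ and the integrator recomputes
  $m_\infty$ from $V_m$.

Synapses are single-exponential conductances: each event adds its
weight to $g_e$ or $g_i$, which otherwise decays as
$e^{-\Delta t/\tau}$. An output spike is the moment $V_m$ crosses 0 mV
from below, linearly interpolated between the two bracketing samples.

### Calibration of the unspecified constants

Three constants of the study conditions are not fixed by the model
equations and had to be chosen once:

* **Synaptic reversals.** $E_e = 0$ mV (the conventional default for
  excitatory conductance synapses) and $E_i = -75$ mV. Both are
  configurable (`pointModel()`, config keys `e_exc`/`e_inh`).
* **Compartment geometry.** Specific conductances only acquire absolute
  meaning through the membrane area, and the catalogue's synaptic
  weights (~0.2 nS) only produce meaningful EPSPs for a small cell.
  Area is therefore the calibration knob of the catalogue. It was set
  once so that, under the default stimulus (below), sub-threshold EPSPs
  summate into the documented 14–25 Hz firing regime: 200 µm²
  ($2\times10^{-6}$ cm²) for the HH models and 30 µm² for the smaller
  WB interneuron. Under these defaults 60-second runs give `base`
  ≈ 22.4 Hz, `lw` ≈ 13.7 Hz and `wb` ≈ 25.0 Hz (recomputed by
  `scripts/acceptance.R`).
* **Stimulus rate.** Each model is driven by two independent Poisson
  streams (one excitatory, one inhibitory) with an expected inter-event
  interval of 10 ms per stream, i.e. 100 events/s of each sign. This
  rate was chosen jointly with the geometry: it is dense enough for
  temporal summation (the HH membrane time constant is ~3 ms), which is
  what makes the response genuinely history-dependent rather than
  determined by the last event alone.

A known limitation of this shared calibration: the long-time-constant
models (`lt`, `lwlt`, `burst`) accumulate standing inhibition (τ up to
40 ms) and fire well below their documented rates (about 5–14 Hz
instead of 18–30 Hz). No shared setting of area, rate and $E_i$ that we
explored reproduces all six rates simultaneously; the fast-synapse
models (`base`, `lw`, `wb`) match to within a few percent and are the
ones used for rate comparisons. All knobs are exposed, so users can
recalibrate per model.

## Numerical integration

Fixed step `dt = 0.025` ms (configurable). Per step:

1. Gates advance by the exponential (Rush–Larsen) update
   $x \leftarrow x + (x_\infty - x)(1 - e^{-dt/\tau_x})$ with rates
   evaluated at the current voltage; removable singularities of the
   rate functions (e.g. $\alpha_m$ at $-40$ mV for HH) are evaluated by
   their limits.
2. The membrane equation, linear in $V$ for fixed gates and
   conductances, advances by the trapezoid-consistent (Crank–Nicolson)
   update using the freshly updated gates.
3. Synaptic conductances decay by the exact factor $e^{-dt/\tau}$.

Events are applied at the first grid time at or after their timestamp
(event times remain continuous in files; snapping happens only inside
the integrator). Halving `dt` moves the spike times of a stimulated
500 ms `base` run by less than 0.1 ms per spike (asserted in the test
suite), and the resting state stays within 0.5 mV over 1 s.

Spike detection requires a strictly sub-zero sample before the
crossing, so one contiguous suprathreshold excursion yields exactly one
spike.

## The on-event framework

The scheduler (`runOnEventSim()`) advances stimulus to stimulus. On
each stimulus it calls the on-event function with a window of up to `n`
recent events whose last entry is the triggering stimulus (during a
cold start, all available events). A finite NST schedules a pending
spike at `t_stimulus + NST`; the spike is committed only if it precedes
the next stimulus, otherwise the prediction is discarded and
recomputed. Design rules adopted where the contract leaves room:

* A prediction exactly simultaneous with a stimulus is discarded (the
  stimulus wins) — robust to floating-point ties.
* At most one output event can occupy a given time point.
* With `include_output_spikes = TRUE` committed spikes enter the
  history, and any window containing one is truncated to start at the
  most recent spike: the stereotyped action potential screens off
  earlier input, so older events carry no usable information for the
  oracle's initialization.

The **conductance oracle** (`conductanceOracle()`) implements the
on-event contract with the model itself: initialize a fresh instance
from a state frame *at the time of the first window event*, zero both
synaptic conductances (frames deliberately exclude synaptic state:
only replayed events contribute conductance), replay the window's
stimuli at their relative times, integrate for the window span plus an
extension (default 20 ms), and return the time from the triggering
event to the first spike strictly after it, else infinity. Spikes that
occur during replay — before the triggering event — are discarded.
Frame policy: `RANDOM_FRAME` draws per call from a dedicated seeded
stream (the global RNG is never touched); `MEDIAN_FRAME` uses the
library medoid; windows that start at an output spike always use a
spiking frame, which pins the model to an action-potential onset at
that instant.

The framework's central correctness property — asserted over many
random streams in the test suite — is *oracle equivalence*: with the
full event history, the true initial state as the frame, and an
extension covering the horizon, the on-event simulation reproduces the
continuous simulation's spike train to within one integration step
(in practice exactly, since both paths snap events to the same grid).

One edge case is worth knowing: when a stimulus arrives within a
fraction of a step after a committed output spike, the spiking-frame
initialization (whose $V_m$ is just below 0) can complete its action
potential *after* the triggering event, occasionally yielding one
spurious sub-refractory interval even with spike feedback enabled. At
the default conditions this affects at most ~1 interval per several
hundred.

## State-variable frame libraries

* **Random frames** are drawn at uniformly random sample times of a
  long ground-truth run (default 100 s), so their distribution is the
  run's state-occupancy distribution.
* **Spiking frames** are taken at the grid sample of each detected
  upward 0 mV crossing (the last sub-zero sample): observed state
  vectors within one step of threshold.
* The **median frame** is the library member minimizing Euclidean
  distance to the per-variable medians after min–max normalization of
  each variable over the library (variables constant across the
  library are excluded). Min–max was chosen over z-scoring because
  gating variables are already bounded in [0, 1] and the $V_m$ range is
  finite; the result is a *medoid* — always an observed frame, never an
  interpolated one — and is invariant to duplicating every member.

## Metrics and conventions

* **Spiking ratio** $r$: fraction of finite NSTs among $k$ responses.
* **Spike prediction coherence** $r^2 + (1-r)^2$: probability two
  randomly drawn responses agree on spike presence; bounded in
  [0.5, 1], symmetric under $r \mapsto 1-r$.
* **NST standard deviation**: sample (denominator $k-1$) SD over the
  finite NSTs only; undefined (NA) below two finite responses.
* **Determinism categories**: deterministic non-spiking ($r < 0.01$);
  deterministic spiking ($r \ge 0.99$ and SD $< 0.1$ ms);
  non-deterministic spiking ($r \ge 0.99$ and SD $\ge 0.1$ ms);
  non-deterministic otherwise. The SD boundary value 0.1 ms classifies
  as non-deterministic spiking (strict `<` for deterministic).
* **van Rossum distance**: each train is filtered with the causal
  kernel $e^{-t/\tau}$ and
  $D = \sqrt{(1/\tau)\int (f_a - f_b)^2\,dt}$, evaluated in closed form
  over spike pairs (no time grid). Normalization conventions differ
  across toolkits; this one gives $\sqrt{1/2}$ for one spike against an
  empty train and $\sqrt{1 - e^{-\Delta/\tau}}$ for two single-spike
  trains offset by $\Delta$. Default $\tau = 10$ ms, configurable —
  comparisons are only meaningful at a stated $\tau$. Both raw and
  per-ground-truth-spike distances are reported.
* **Spike-triggered variance**: windows of the recorded trace aligned
  at each spike (windows overlapping the boundary are discarded);
  per-offset variance across windows versus the whole-trace baseline.
  `spikeVarianceSummary()` reports variances of min–max-normalized
  $V_m$ so models with different spike amplitudes are comparable; the
  percentage-of-baseline column is scale-invariant.
* **Transition analysis**: at each window-size increment
  $n \to n+1$, category changes are attributed to the newly included
  $(n+1)$-th most recent stimulus, recording its label and its interval
  to the $n$-th most recent event, against the unconditional interval
  and label distributions.

## The synthetic stimulus generator

`poissonStream()` draws i.i.d. exponential inter-event intervals;
`makePattern()` merges an excitatory and an inhibitory stream, keeps
exactly the last `n_events` events and re-anchors the first at time 0.
Simultaneous events keep the stable order exc < inh < spike. The
generator emulates stationary, independent, balanced excitation and
inhibition — the regime the models were designed around. It does *not*
emulate rate modulation, inter-stream correlation, bursty or oscillatory
drive, or synapse-specific locations; conclusions drawn from passing
tests therefore concern the stationary-Poisson regime only, and the
input statistics are part of every experiment's configuration.

## Experiment drivers and problem sizes

All drivers derive every stochastic component from one master seed and
are bit-reproducible. Default sizes are scaled for a desk-class
machine; every size is a parameter:

* `determinismSweep()`: 50 patterns × 100 random frames over
  `n ∈ {3, 5, 10, 15, 25, 50}` (the full battery would be 1000 × 1000
  over `n = 3..50`; it is reachable through the same arguments).
  Patterns contain no output spikes, so the spiking-frame constraint
  never triggers there.
* `replicationExperiment()`: 10 s of shared stimulus, frame libraries
  from a separate 100 s run, `MEDIAN_FRAME` oracle.
* `reconstructionExperiment()`: 500 pairs × 100 ms, each pair started
  from two distinct-index random spiking frames with an identical
  fresh stimulus stream; reports mean absolute $V_m$ difference per
  time offset.
* `spikeVarianceSummary()`: 100 s per model by default (60 s in the
  acceptance script), ±20 ms windows.

## Known limitations

* Single-compartment models only; no morphology, dendrites, axial
  currents, ion accumulation or temperature dependence.
* The `lt`/`lwlt`/`burst` firing rates under the shared default
  calibration sit below their documented values (see above).
* The oracle is serial; on-event calls are independent by construction,
  so parallel dispatch would be semantics-preserving, but none is
  implemented.
* Only Poisson input statistics are generated (see the generator
  section).
* The spiking-frame edge case described under the on-event framework.
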