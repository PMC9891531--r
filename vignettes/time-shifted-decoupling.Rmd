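---
title: "Decoupling interacting neuronal populations by time-shifted stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoupling interacting neuronal populations by time-shifted stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decouplr)
```

## The problem

Several brain disorders are associated with abnormally strong long-range
synaptic connections between brain regions, which sustain pathologically
synchronized oscillations. Because synapses obey spike-timing-dependent
plasticity (STDP), a stimulation protocol that systematically imposes
*unfavourable* spike-timing relations between two regions can, in principle,
make the network *unlearn* those connections: decoupling the regions then
desynchronizes them, and the effect can outlast the stimulation.

`decouplr` implements this programme end to end:

1. a closed-form **per-period theory** of the net STDP change for a
   reciprocally connected pair of periodically firing neurons with
   transmission delays (`net_change()`, `classify_pair()`, `phase_map()`,
   `stdp_ratio_map()`);
2. a **two-module LIF network simulator** with plastic, delayed
   inter-population synapses (`build_network()`, `simulate_network()`);
3. the **time-shifted pulse-train protocols** (`stim_protocol()`,
   `pulse_times()`), burst and continuous;
4. a **metric suite** for synchrony and coupling (`metrics_report()` and
   friends);
5. **figure-level experiments and sweeps** (`run_experiment()`,
   `run_sweep()`).

## The pair-based STDP rule and its period average

A plastic synapse changes at each pre/post spike pairing by

$$\Delta g \;=\; A_\pm\,\mathrm{sgn}(\Delta t + \xi)\,
  e^{-|\Delta t + \xi|/\tau_\pm},$$

where $\Delta t = t_\mathrm{post} - t_\mathrm{pre}$ is the somatic lag,
$A_+ = 0.008$, $A_- = 0.005$, $\tau_+ = 10$ ms, $\tau_- = 20$ ms by default,
and $\xi = \tau_d - \tau_a$ is the *effective delay*: the timing offset
perceived at the synapse when the presynaptic volley travels down the axon
($\tau_a$) and the postsynaptic spike back-propagates up the dendrite
($\tau_d$). For long-range projections $\tau_a > \tau_d$, so $\xi < 0$;
entry points parameterized by the magnitude use `xi_from_abs()`.

When both neurons fire periodically with period $T$ and the post lags the
pre by $\Delta t$ at the soma, the synapse experiences exactly one
potentiation and one depression pairing per period. Reducing the
synapse-local lag $\delta = (\Delta t + \xi) \bmod T$ into $[0, T)$,

$$\Delta g(T) \;=\; A_+ e^{-\delta/\tau_+} \;-\; A_- e^{-(T-\delta)/\tau_-}.$$

The modular reduction matters: for $\Delta t + \xi < 0$ (common with
delays), the potentiation partner of a presynaptic arrival is the *next*
postsynaptic back-propagation, at lag $T + \Delta t + \xi$. Without the
reduction the formula misclassifies exactly the delayed regimes the method
targets.

Evaluating the two directions of a reciprocal pair (forward lag $\Delta t$,
reverse lag $T - \Delta t$) and reading the sign pair yields the emergent
connectivity: **decoupled** (both negative), **unidirectional** (mixed), or
**bidirectional** (both positive):

```{r}
classify_pair(5, 30, stdp_params(), xi = xi_from_abs(10))
```

Two properties anchor the test suite:

* at $\xi = 0$ the map is mirror-symmetric about $\Delta t = T/2$ and the
  decoupled band sits exactly there (fire in anti-phase to depress both
  directions);
* an event-level implementation of the pairing rule on forced periodic
  trains reproduces the sign of the closed form everywhere on the
  operating grid ($T \ge 20$ ms, $|\xi| \le 10$ ms) except on the
  coincidence boundary $\delta \in \{0, T\}$, where the closed form puts the
  potentiation exponential at 1 while the event rule's $\mathrm{sgn}(0) = 0$
  drops the update. The boundary is measure-zero; tests exclude a 1 ms
  neighbourhood of it.

A helper, `is_depression_dominated()`, reports the window-integral condition
$A_+\tau_+ < A_-\tau_-$ (0.08 < 0.10 at the defaults) under which
uncorrelated firing erodes weights — the condition for decoupling to be
self-sustaining after stimulation ends.

## The network model

Each module is a sparse Erdős–Rényi network of $N = 200$ LIF neurons (80%
excitatory, connection probability 0.15), with static intra-module synapses:
excitatory magnitudes $\mathcal N(0.2, 0.05)$, inhibitory
$\mathcal N(0.8, 0.05)$ (the 4:1 balance), clipped to the global bounds
$[g_\mathrm{min}, g_\mathrm{max}] = [0.05, 1]$. The two modules are coupled
only by excitatory-to-excitatory synapses (probability 0.15, both
directions) with total transmission delay $\tau_d + \tau_a = 11$ ms; only
these synapses are plastic. The default inter-module mean of 0.8
("initially strong", the pathological preset) reflects the parameter table
of the reference model; the weaker alternative (mean 0.2) documented
elsewhere in the same source is exposed as `inter_preset = "weak"`.

Membrane dynamics are dimensionless LIF: $\tau_m \dot v = -v + I$ with
threshold 1, reset 0, a 2 ms absolute refractory period, and every synaptic
or external arrival filtered through an exponential trace with
$\tau_s = 5$ ms. The printed trace kernel in the source grows with time;
it is implemented as the decaying exponential, the only physically sensible
reading. Integration is forward Euler at $dt = 0.1$ ms (delays become
integer ring buffers; halving $dt$ changes a deterministic run's final
coupling by well under 1%). Stimulation pulses are instantaneous kicks of
size $K$ added to $v$; $K$ is not stated in the source and defaults to 1.3
(30% above threshold) so that a pulse reliably fires a resting neuron.

Three numerical conventions worth knowing:

* **In-degree normalization.** Synaptic currents are multiplied by
  `current_scale`, defaulting to the reciprocal expected in-degree
  $1/(p N)$ (and to 1 for the two-neuron motif). Without it, 24 convergent
  inter-module inputs each delivering an $O(1)$ kick saturate the network at
  unphysical rates; with it, dynamics are invariant under rescaling the
  module size, which is what makes the fast reduced-scale test presets
  faithful.
* **Delay semantics.** A spike emitted at step $s$ first affects the
  postsynaptic trace at exactly $s + \tau/dt$ steps (instantaneous
  transmission is promoted to one step).
* **Pairing bookkeeping.** Online STDP pairs each spike with the partner's
  most recent *strictly earlier* spike, at both pre- and postsynaptic
  events, with additive updates and hard clipping. Exactly coincident
  somatic spikes produce no update, so each pair is counted once.

## Background drive and calibration

Each excitatory neuron receives 8000 independent 1 Hz Poisson excitatory
trains, each inhibitory neuron 6500; the superposition is drawn as one
aggregate Poisson process per neuron and each arrival adds `w_ext` to the
neuron's external trace. The per-arrival amplitude is the one deliberately
free parameter of the model (the source states only that the input was
tuned). We calibrate it once — `calibrate_drive()` ships the bisection —
against the *regime* the source describes, not against any result:

* an **isolated** module must fire irregularly at a low rate (we get
  ~9 Hz excitatory at `w_ext = 0.023`, median CV of ISIs ≈ 0.7, population
  Fano factor ≈ 0.005, inhibitory cells nearly silent — matching the
  reference baseline in which the inhibitory rate is 0);
* the **strongly coupled** network must synchronize at a high rate: at the
  same `w_ext` we get ~32 Hz, population Fano factor ≈ 0.11, and the two
  modules oscillate in anti-phase (median phase lag 0.97π);
* resetting the inter-module weights to $g_\mathrm{min}$ must return the
  network to asynchronous ~8 Hz firing — decoupling is sufficient for
  desynchronization.

The two-neuron motif has no in-degree normalization, so its drive is
calibrated separately (`drive_motif`, `w_ext = 0.015`): the motif neurons
fire stochastically at a low rate and a partner arrival alone is
subthreshold.

## What the simulations reproduce — and one honest discrepancy

At reduced scale (50-neuron modules, 2 s / 1–2 s / 2 s epochs) and full
scale alike, the package reproduces the method's qualitative structure:

* the time-shifted protocol **depresses** the pooled inter-module coupling
  on the same seed for which the coincident ($\Delta t = 0$) control
  **potentiates** it;
* the **continuous** pattern decouples at least as fast as the **burst**
  pattern (no OFF-epoch for recovery);
* the two-neuron **motif** is decoupled in both directions by the
  time-shifted burst protocol;
* after a successful stimulation run the network **desynchronizes**
  (population Fano factor drops ~20-fold) and stays desynchronized.

One headline quantity is *not* reproduced: driving **both** directions of
the full network below the coupling stability threshold (≈ 0.3) with the
5 s, $\Delta t = 5$ ms burst protocol. The reason is mechanistic and worth
recording. In our calibrated network the only available synchronization
mechanism is the delay-loop *ignition* mode: each module's volley ignites
the other module 11 ms later, giving an anti-phase rhythm with period
$\approx 2(\tau_\mathrm{inter} + \text{ignition lag}) \approx 28$ ms rather
than the slower (≈ 45 ms) rhythm of the reference simulations. Under
ignition-driven synchrony every arrival-ignited spike pairs with its
igniting volley at synaptic lag $2\tau_d + \varepsilon \approx 1$ ms —
maximal potentiation — so whichever direction's arrivals ignite spikes is
structurally protected from depression. With $\Delta t = 5 <
\tau_\mathrm{inter}$, the leading module's arrivals land in the lagging
module's refractory window (no echo, full depression: that direction falls
to $g_\mathrm{min}$) while the lagging module's arrivals land on recovered
neurons (echo, pinned at the ceiling). Scanning $\Delta t$ confirms the
mirror image: the decoupled direction flips at $\Delta t = T - 5$, and no
time shift decouples both at $T = 30$ ms in this regime. The package
therefore reproduces robust *unidirectional* stimulation-induced
decoupling, its direction set by the time shift, together with the
desynchronization that follows; the bidirectional variant would require a
synchronized regime that is not ignition-driven, which we could not obtain
from this parameter table under any calibration we searched.

## Analysis defaults

Bin widths are not stated in the source; the defaults are typical for
cortical network analyses and always reported alongside results:
population activity in 1 ms bins (5 ms moving average before peak and phase
detection), population Fano factor on 5 ms bins, spike-count correlations on
50 ms bins; all "before/after" metrics use 10 s windows at full scale (2 s
reduced). Pairwise correlations use all pairs up to 20 000 and a seeded
subsample beyond. Phase lags are extracted per cycle by peak matching on the
smoothed activity (no analytic-signal filtering), mapped to $[0, 2\pi)$
with the measured period. Degenerate inputs are explicit: fewer than three
spikes gives an NA CV; zero-variance neurons are excluded from
correlations; zero-mean activity makes the Fano factor an error; a flat
spectrum gives an NA peak.

## What the generator does not emulate

The synthetic networks are Erdős–Rényi with Gaussian weights: no spatial
geometry, no distance-dependent connectivity or delays, no degree
correlations, no conductance-based synapses, no adaptation or short-term
plasticity, and static intra-module synapses by construction. Passing tests
therefore validate the plasticity arithmetic, the protocol bookkeeping and
the collective phenomena of this model class — not quantitative predictions
for any particular biological circuit.

## Problem sizes

The default test and acceptance runs use 50-neuron modules for property
checks and the full 2×200-neuron network over 25 s of simulated time for
the headline protocol; the compiled clock-driven core integrates the latter
in a few seconds, and all problem sizes are exposed through
`experiment_scale()` and `sim_config()`.
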