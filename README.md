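# decouplr

Tools for designing and evaluating **time-shifted two-site stimulation**
protocols that decouple reciprocally connected neuronal populations through
**spike-timing-dependent plasticity (STDP)**.

Pathologically strong long-range synapses between two brain regions can
sustain abnormally synchronized oscillations. Because synapses follow STDP —
potentiation when the presynaptic spike precedes the postsynaptic one,
depression otherwise, with amplitudes `A±` and time constants `τ±` —
stimulating the two regions with a *time shift* Δt between their pulse
trains imposes spike-timing relations that can make the network unlearn
those synapses. `decouplr` provides, for this model class:

* **Closed-form theory.** For two neurons firing periodically with period
  `T` and lag Δt, with dendritic/axonal delays entering as the effective
  delay `ξ = τ_d − τ_a`, the net per-period change of a synapse is

  `Δg(T) = A₊ exp(−δ/τ₊) − A₋ exp(−(T−δ)/τ₋)`, with `δ = (Δt + ξ) mod T`.

  The sign pair over the two directions classifies the emergent motif as
  decoupled / unidirectional / bidirectional (`net_change()`,
  `classify_pair()`, `phase_map()`, `stdp_ratio_map()`).
* **A plastic two-module LIF network simulator** (compiled clock-driven
  core): sparse excitatory-inhibitory modules with static local synapses,
  delayed plastic excitatory long-range synapses updated online by the
  pair-based rule with hard bounds, aggregate-Poisson background drive, and
  instantaneous stimulation kicks (`build_network()`, `simulate_network()`).
* **Protocol generators** for time-shifted burst and continuous pulse
  trains (`stim_protocol()`, `pulse_times()`, `target_mask()`).
* **Metrics**: inter-population mean coupling, population activity and Fano
  factor, spike-count correlations, CV of inter-spike intervals, spectral
  peaks, per-cycle phase lags, thresholded binary topology
  (`metrics_report()` and friends).
* **Figure-level experiments and parameter sweeps** with archived,
  re-creatable run manifests (`run_experiment()`, `run_sweep()`), plus a
  thin command-line front end (`exec/decouplr`).

## Worked example

Where should a decoupling protocol operate? With the default cortical STDP
profile and a 10 ms effective delay, the theory says a 5 ms shift at
33.3 Hz depresses both directions of a reciprocal pair:

```r
library(decouplr)
classify_pair(5, 30, stdp_params(), xi = xi_from_abs(10))
#> # A tibble: 1 × 5
#>   delta_t T_period    dg_21     dg_12 label
#>     <dbl>    <dbl>    <dbl>     <dbl> <fct>
#> 1       5       30 -0.00324 -0.000577 decoupled
```

Both per-period changes are negative (the 1→2 synapse loses 0.0032 in
weight per 30 ms cycle, the reverse 0.0006), so sustained stimulation at
this point erodes the pair's coupling. Over the whole (Δt, T) plane about
30% of feasible cells are decoupling at this delay:

```r
glance(phase_map(seq(1, 29), seq(10, 60), stdp_params(), xi = xi_from_abs(10)))
#> # A tibble: 1 × 6
#>   n_cells n_applicable frac_decoupled frac_unidirectional frac_bidirectional
#> 1    1479         1269          0.303               0.377              0.320
```

In the network, the time shift is what matters — on the same seed, the
shifted burst protocol weakens the stimulated direction while the
coincident (Δt = 0) control potentiates both:

```r
run_experiment("shifted_vs_unshifted", scale = "reduced", seed = 1)$metrics
#> # A tibble: 4 × 4
#>   run       window   g21   g12
#>   <chr>     <chr>  <dbl> <dbl>
#> 1 shifted   pre    0.808 0.813
#> 2 shifted   post   0.758 0.867
#> 3 unshifted pre    0.808 0.813
#> 4 unshifted post   0.838 0.843
```

`g21`/`g12` are the mean plastic synaptic strengths per direction
(dimensionless, bounded in [0.05, 1]) averaged over the pre- and
post-stimulation analysis windows: the shifted protocol drives `g21` down
by 0.05 in a 1 s reduced-scale run, while the unshifted control pushes both
directions up by ~0.03.

See the vignette (`vignettes/time-shifted-decoupling.Rmd`) for the model,
its assumptions, the drive calibration, and a mechanistic account of which
reference behaviours the simulator reproduces bidirectionally versus
unidirectionally.

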