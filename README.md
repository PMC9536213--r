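# tcsim

Construction and simulation of somatosensory thalamocortical spiking circuits
at configurable, desk-testable scale.

Large biophysical models of the somatosensory cortex wire tens of thousands of
cells from explicit lists of touching neurites — data that are enormous,
machine-bound and hard to rescale. The alternative this package implements is
*statistical reconstruction*: estimate, for every pathway, the probability of
connection as a function of horizontal (XZ-plane) somatic distance from a few
stochastic connectome instances, fit a compact parametric rule, and rebuild the
circuit at any scale from those rules plus a 29-class registry of synaptic
physiology. On top of the reconstructed column, tcsim adds a six-population
thalamic circuit (three reticular sectors, VPL, VPM, POm) with
footprint-, divergence- and convergence-based wiring, reduced point-neuron
models with low-threshold calcium rebound bursting, deterministic
Tsodyks–Markram short-term plasticity, calcium-dependent synaptic state
switching, spike-replay (hybrid) simulation, and line-source local field
potentials.

The moving parts, in the field's standard notation:

* **Connectivity rules.** Per pathway, the binned connection probability
  `p(d)` (bins 25 ± 25 … 375 ± 25 um, averaged over 7 instances) is fitted by
  a single exponential `A·exp(−d/λ)`, a saturating exponential
  `min(p_sat, A·exp(−d/λ))`, or a Gaussian `A·exp(−(d−μ)²/2σ²)`; the
  best-fitting family is selected per pathway.
* **Synaptic dynamics.** Dual-exponential conductances (τ_rise 0.2 ms) with
  deterministic Tsodyks–Markram plasticity: utilization `U`, depression
  recovery `D` (ms), facilitation recovery `F` (ms) per class; release on each
  spike is `u·R` with the standard facilitation-before-release update.
* **Neurons.** Adaptive-exponential integrate-and-fire cortical cells;
  thalamic relay/reticular cells with a T-type calcium current
  `g_T·m∞²(V)·h·(E_Ca−V)` giving rebound bursts (rest −60 / −80 mV).
* **LFP.** Line-source approximation in a homogeneous medium
  (σ = 0.3 mS/mm), balanced two-segment dipoles for point neurons.

All inputs are generated in code (or shipped as small plain-text tables): the
me-type catalogue, ground-truth pathway curves and thalamocortical convergence
table are clearly-labeled synthetic fixtures, so the full pipeline is
reproducible offline at any scale.

## Worked example

Build a 10% cortical column — placement, synthetic connectome instances, rule
fitting, connectome instantiation — simulate 11 s with short-term plasticity,
and measure the slow synchronous rhythm:

```r
library(tcsim)

ctx <- build_cortical_column(scale = 0.1, seed = 7)
ctx
#> <tc_circuit> 3135 cells, 43 populations, 1180485 synapses, background attached

sim <- run_simulation(ctx, simulation_config(duration = 11000,
                                             transient = 1000, seed = 7))
glance(sim)
#> # A tibble: 1 × 4
#>   n_cells duration n_spikes mean_rate
#>     <int>    <dbl>    <int>     <dbl>
#> 1    3135    11000   172737      5.04

bursts <- detect_bursts(sim$spikes, nrow(ctx$cells), window = c(1000, 11000))
burst_frequency(bursts)
#> [1] 1.086957
```

The column fires at a few hertz overall and, with depressing recurrent
excitation (the dominant class has `U = 0.50`, `D = 671 ms`), organizes into
network-wide bursts at about 1 Hz — `autoplot(sim)` shows the raster. Dropping
extracellular calcium to the in-vivo-like state desynchronizes it:

```r
vivo <- run_simulation(ctx, simulation_config(duration = 11000,
                                              transient = 1000, seed = 7,
                                              calcium = calcium_state(1.2)))
oscillation_peak(vivo$spikes, nrow(ctx$cells), band = c(1, 15),
                 window = c(1000, 11000))$synchrony   # ~0.10, vs ~1.00 in vitro
```

The isolated thalamic network oscillates in the theta band through the
relay–reticular rebound loop:

```r
th <- build_thalamic_circuit(scale = 0.1, seed = 1)
sth <- run_simulation(th, simulation_config(duration = 11000,
                                            transient = 1000, seed = 1))
oscillation_peak(sth$spikes, nrow(th$cells), band = c(1, 15),
                 window = c(1000, 11000))
#> <tc_osc> peak 6.30 Hz (power 1.9e+03), synchrony 0.942
```

Fitted objects and simulations follow broom conventions (`tidy()`,
`glance()`), results plot with `autoplot()` / `plot_*()`, and every builder
takes and returns tibbles. See the methods vignette
(`vignettes/thalamocortical-methods.Rmd`) for the models, calibration choices
and limitations.

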