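---
title: "Models and methods behind tcsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tcsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tcsim builds and simulates somatosensory thalamocortical spiking circuits at
configurable scale. This vignette explains the models it implements, the
parameters that matter, the choices made where the design was genuinely open,
and what the synthetic-data machinery does and does not emulate.

## The construction pipeline

A circuit is assembled in five stages, each an exported function:

1. **Placement.** Cortical cells are placed uniformly at random within their
   layer's slice of a cylinder (height 2,082 um, radius 210 um; layer
   thicknesses L1 165, L2/3 502, L4 190, L5 525, L6 700 um). Depth `y`
   increases downward from the pia. Disc positions are sampled area-uniformly
   by inverse CDF on the radius (`r = R sqrt(u)`). Thalamic populations occupy
   six stacked boxes with a 420 x 420 um footprint: three reticular (RTN)
   sectors of 78, 78 and 156 um, then VPL, VPM and POm at 156, 156 and 312 um.
   POm is placed at 50% density, reflecting the fraction of its cells that
   project to motor rather than somatosensory cortex. The vertical gap between
   the cortical column and the thalamic stack is configurable and only
   cosmetic: every wiring rule uses horizontal (XZ) distance and box-aligned
   depth offsets, never the absolute inter-structure distance.

2. **Distance-dependent probability rules.** Connection probabilities are
   estimated from stochastic connectome instances in 50-um distance bins
   centered at 25, 75, ..., 375 um, averaged across instances (seven by
   default), and fitted per pathway with three candidate families: a single
   exponential `A exp(-d / lambda)`, a saturating exponential
   `min(p_sat, A exp(-d / lambda))`, and a Gaussian
   `A exp(-(d - mu)^2 / (2 sigma^2))` whose center may sit away from zero.
   Fitted curves are clipped to `[0, 1]` on evaluation.

3. **Synapse classes.** The packaged registry holds the 29 connection classes
   with their dynamics type (facilitating E1/I1, depressing E2/I2,
   pseudo-linear E3/I3), projection type, kinetic and plasticity parameters
   (mean and standard deviation), and a textual pre:post cell-type rule. A
   small grammar parses the rules; matching an ordered me-type pair returns the
   most specific matching class (specificity counts constrained tokens: layer,
   m-type, e-type), with remaining ties resolved to the highest class index.

4. **Wiring.** The cortical connectome draws a Bernoulli edge per ordered pair
   from the fitted rule, with `1 + Poisson(mean_nsyn - 1)` synapses per
   connection (the mean matches the pathway's observed mean while guaranteeing
   at least one synapse). Thalamic wiring uses three strategies: exponential
   footprint wiring with hard truncation at the footprint radius between
   first-order nuclei and their RTN sector; the same rule within each RTN
   sector; and a fixed-divergence rule without spatial constraint for all
   higher-order (POm) edges. Corticothalamic feedback from L5_TTPC2 and
   L6_TPC_L4 uses exact convergence (30 sources within 50 um). Thalamocortical
   projections use per-m-type convergence values, scaled for inhibitory
   targets by the innervation-ratio factor (~0.595), with 9 synapses per
   connection of the excitatory-depressing thalamocortical class.

5. **Simulation.** A clock-driven engine (Rcpp) integrates all cells at a
   fixed step (0.1 ms default), delivers spikes through per-edge delays, and
   applies deterministic Tsodyks-Markram short-term plasticity per synapse.

## Short-term plasticity and conductances

Each synapse carries utilization `u` (initially 0) and resources `R`
(initially 1). On a presynaptic spike at interval `delta` since the last one,
facilitation is applied before release,

    u <- U + u (1 - U) exp(-delta / F)
    R <- 1 + (R - 1) exp(-delta / D)        # lazy recovery
    release = u R;  R <- R (1 - u)

so the first spike of a train releases exactly `U`. The limits `F -> 0`
(utilization pinned at `U`) and `D -> 0` (resources pinned at 1) are exact,
which is also how static synapses are encoded (`U = 1, D = F = 0`). The
periodic-train fixed point has the closed form

    u* = U / (1 - (1 - U) exp(-isi/F))
    R* = (1 - exp(-isi/D)) / (1 - (1 - u*) exp(-isi/D))

used as the oracle in the test suite (agreement to 1e-9 for all 29 classes).

Conductances are dual exponentials with a 0.2 ms rise time for all synapses
and per-class decay, normalized so the kernel peak equals the sampled peak
conductance (the registry labels `g_syn` as a peak value). Per-synapse
parameters are drawn from normal distributions with the class mean and
standard deviation, truncated below at 1% of the mean (and `U` to `(0, 1]`)
so kinetics stay positive.

**Kernel grouping.** The network engine lumps conductance states per
postsynaptic cell and kinetic class (reversal, rise, class-mean decay) instead
of integrating one dual-exponential per synapse. Per-synapse variability in
conductance and plasticity parameters is fully retained; only the decay
variability within a class is collapsed to the class mean in network runs.
The standalone PSP protocol runner uses the exact per-synapse kinetics.

## Point-neuron models

The morpho-electrical detail of the original cell models is out of scope; the
network-level dynamics are the target. Cortical cells are adaptive-exponential
integrate-and-fire models: an adapting excitatory set and a fast-spiking
inhibitory set (one each, shared across layers). Thalamic cells are
integrate-and-fire models augmented with a low-threshold T-type calcium
current `g_T m_inf(V)^2 h (E_Ca - V)` with instantaneous activation and
first-order inactivation whose time constant interpolates between a fast
depolarized value and a slow hyperpolarized value. The relay set rests near
-60 mV and the reticular set near -80 mV (calibration targets, +/-2 mV); a
-200 pA, 500 ms pulse produces a rebound burst in the relay cell that
disappears when `g_T = 0`, and reticular cells burst when excited from their
hyperpolarized rest. All kinetic constants are implementer-calibrated to
these behaviors; none are literature values.

Integration is exponential-Euler for the gating/adaptation variables and
forward Euler for the membrane equation at `dt = 0.1` ms. Spike times
therefore carry O(dt) discretization error that accumulates along a train;
the refinement tests assert first-spike agreement and population-rate
agreement (<5%) when `dt` is halved, not per-spike identity.

## Calcium-dependent state switching

Lowering extracellular calcium from 2.0 to 1.2 mM reduces release
probability. Connections are classified by dependence: steep for excitatory
connections onto excitatory cells and onto distal-targeting interneurons
(DBC, BTC, MC, BP), shallow for excitatory connections onto proximal-targeting
interneurons (LBC, NBC, SBC, ChC), intermediate otherwise. The corresponding
`U` multipliers default to 0.25 / 0.75 / 0.50: the published description gives
only the 0.25-0.75 range, so the endpoints are assigned to the steep and
shallow classes and the midpoint to the intermediate class, all
config-overridable. In-vitro state (`cao = 2.0`) leaves `U` untouched.

## The synthetic-data generator

No external connectome is shipped or downloaded. The generator defines
ground-truth probability curves per pathway and draws independent Bernoulli
edges over fixed placements, so the estimation pipeline can be validated
against known structure (the fit-recovery tests re-identify all three families
at 2,000 cells and 7 instances). The default cortical pathway table works at
the layer-by-polarity level (9 groups, 81 directed pathways): peak probability
0.15 within a layer, decaying with laminar separation; inhibitory pathways are
exponential with an 85-um length constant, within-layer excitatory pathways
saturate at short range, and the rest are Gaussian with a 110-um width. Mean
synapses per connection are 3-4.5. These values are plausible for cortical
microcircuitry but are *not* measured values, and the packaged me-type
catalogue (44 types summing to 31,346 cells, 26,567 excitatory / 4,779
inhibitory) is likewise a synthetic stand-in with realistic layer proportions.
Consequently, passing tests validate the machinery - estimation, fitting,
construction, dynamics - on data with known structure; they do not certify
agreement with any measured connectome.

## Model selection among nested families

The saturating exponential contains the pure exponential (whenever
`p_sat >= A`), so on noisy bins its least-squares error is never larger and
raw SSE comparison would systematically select it. `select_best_fit()`
therefore scores candidates by small-sample-corrected AIC,
`n log(sse/n) + 2k + 2k(k+1)/(n-k-1)`; materially different fits still
resolve by SSE, exact ties resolve by fewer parameters and then by the fixed
family order. A second, structural guard handles the nested pair directly: a
fitted ceiling that binds on fewer than two bins is not identifiable from a
pure exponential, so such a saturating fit is not a candidate in its own
right. Fits are evaluated at the mean pair distance of each bin rather
than the bin center: pair density grows with distance inside a bin, and
center evaluation visibly biases the short-distance bins (enough to mimic
saturation on exponential data).

## Thalamic wiring conventions

Two published quantities needed interpretation:

* **Radii.** Printed footprint *diameters* (RTN->VPL/VPM 64.33 um, VPL->RTN
  97.67 um, VPM->RTN 103.57 um) are halved for the truncation radius; the
  intra-RTN 264.63 um value is already a radius. The exponential decay
  constant is set equal to the footprint radius (the proportionality constant
  is unstated; 1.0, config-overridable).
* **Depth alignment.** The depth constraint (offset at most 10% of the
  footprint radius) is applied to box-aligned depths: each cell's depth is
  measured from its population's depth midpoint. Applied in a shared absolute
  frame, the constraint would forbid nearly all inter-nucleus connections,
  because the stacked boxes are separated by far more than the allowed few
  micrometers, contradicting the column-like topological organization these
  projections implement. Within a population the two conventions coincide.
* **Sector preference.** Each RTN sector pairs with one nucleus (default
  RTNo<->VPL, RTNm<->VPM, RTNi<->POm, config data); all POm edges use the
  divergence strategy (default out-degree 20, from the explored set
  {5, 10, 20, 40}).

Receptors: RTN->RTN GABA_A; RTN->relay an equal-weight GABA_A + GABA_B
combination (implemented as two kernels, each carrying half the conductance);
relay->RTN and all thalamocortical/corticothalamic synapses AMPA. GABA_B is
approximated by a slow linear dual-exponential kernel (10 ms rise, 35 ms
decay, reversal -95 mV): a linearization of its nonlinear kinetics, tuned
jointly with the intrathalamic weights so the isolated thalamic network
sustains its characteristic theta-band (about 6 Hz) rebound-burst loop.
Synaptic delays are 1 ms within a structure and 2 ms between cortex and
thalamus (delays are not published). Intrathalamic weights (relay->RTN 12 nS,
RTN->relay 6 nS split across the two kernels, RTN->RTN 0.8 nS) and the
background quantal conductances are free calibration parameters, as the
corresponding published values were themselves targets of optimization.

## Background drive and scaled-down runs

Every driven cell receives 10 independent excitatory and 10 inhibitory
Poisson sources with per-source rates and quantal conductances as calibration
parameters (defaults: cortex 15 / 4 Hz at 4 nS; thalamic relay nuclei 8 Hz
excitatory at 4 nS, with RTN driven by relay input rather than background).
`grid_search_background()` reproduces the tuning procedure.

Desk-scale work uses a 10% circuit (3,135 cortical cells, 727 thalamic
cells). The reduced in-degree of a scaled column is compensated by scaling
synaptic conductances with `1 / scale`. Under these conditions the isolated
thalamic network shows a population-rate spectral peak at 6-7 Hz across
seeds; the isolated cortical column with short-term plasticity produces
synchronous population bursts at 0.7-1.1 Hz, led by depression recovery
(D = 671 ms on the dominant excitatory class) and spike-frequency
adaptation; and switching to the low-calcium state sharply reduces the
synchrony index and overall rate. The analysis windows (11-21 s after a 1 s
transient) are the package defaults for these problem sizes.

## Local field potentials

Extracellular potentials use the line-source approximation in a homogeneous,
frequency-independent medium (`sigma = 0.3 mS/mm`): each segment contributes
`I / (4 pi sigma L) [asinh((L - s0)/r) - asinh(-s0/r)]`, with the
perpendicular distance clamped at 1 um. Superposition is an exact matrix
product (linearity to machine precision), and short segments converge to the
point-source `I / (4 pi sigma r)` within 0.1%. Point neurons carry no spatial
current distribution, so for LFP work each recorded cell is assigned a
synthetic two-segment vertical cable - a somatic sink carrying the negative
of its recorded synaptic current and a dendritic return above it - enforcing
exact current balance. This is the minimal dipole consistent with synaptic
currents dominating the extracellular signal and is a deliberate departure
from full-morphology transmembrane currents; absolute microvolt amplitudes
are therefore not comparable to recordings, while distance attenuation,
linearity and spectral shape are. Spectral analysis uses Welch's averaged
windowed periodogram (Hann window, 50% overlap).

## Analysis metrics

Population rates are spikes/cell/second over a window excluding the 1 s
transient. The ISI coefficient of variation is computed per cell with at
least three spikes. The synchrony index compares the variance of the 5-ms
binned population rate against a spike-time-shuffled baseline (counts
preserved, times redrawn uniformly), normalized to `[0, 1]`; no standard
statistic is prescribed in the source description, so this shuffle-corrected
rate-variance index is the package's choice, validated by construction
(lockstep firing near 1, independent Poisson near 0, invariance under cell
relabeling). Population bursts are threshold crossings of the binned rate at
mean + 2 SD, merged within 100 ms; the inter-burst frequency is the inverse
mean onset interval.

## Known limitations

* Point neurons cannot reproduce morphology-dependent quantities: absolute
  PSP amplitudes (only relative amplitude sequences are meaningful),
  backpropagation, and absolute LFP amplitudes.
* The synthetic catalogue, pathway curves and thalamocortical convergence
  table are labeled synthetic fixtures; analyses of real tissue require
  replacing them with measured inputs in the same tabular formats.
* Network-engine kinetics share class-mean decay constants (above).
* Full-scale (31,346-cell) simulation is structurally supported (`scale = 1`)
  but not routinely exercised; all shipped calibrations target the 10% scale.
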