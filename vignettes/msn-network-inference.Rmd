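---
title: "Striatal MSN network dynamics and parameter inference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Striatal MSN network dynamics and parameter inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The scientific problem

The striatum's principal cells, medium spiny neurons (MSNs), inhibit one
another through an extensive network of axon collaterals. In slice calcium
imaging this network expresses *cell assemblies*: groups of co-active cells
that switch sequentially over timescales of minutes, with characteristic
disruptions in Parkinsonian (6OHDA) and dyskinetic (L-DOPA) tissue. Two
network-level quantities are thought to govern these dynamics: the strength
of lateral inhibition between MSNs, written `G_I`, and the tonic excitatory
drive each MSN receives, written `G_E` (a lump for bath NMDA, intrinsic
excitability and feedforward input).

`msnet` implements the full chain needed to estimate `(G_I, G_E)` from
binary activity rasters: a conductance-based MSN network simulator with
short-term synaptic plasticity, a calcium-like raster summarizer, and a
simulation-based-inference (neural posterior estimation) layer. Everything
runs at desk scale on one CPU.

## The cell model

Each MSN is a single compartment (capacitance 1 µF/cm²) with leak plus the
canonical striatal channel complement: fast sodium `I_Na`, delayed-rectifier
potassium `I_K`, inward rectifier `I_Kir`, fast and slow A-type potassium
`I_Af`/`I_As`, persistent potassium `I_Krp`, and persistent plus
slowly-equilibrating sodium `I_NaP`/`I_NaS`. Gating uses Boltzmann
steady-state curves with fixed or sigmoidal voltage-dependent time
constants; the slow A-current inactivation (τ ≈ 1.2 s) produces the long,
drive-dependent delay to first spike that distinguishes MSNs.

Excitatory drive is expressed in abstract *drive units*; `drive_scale`
converts drive into injected current. All network drives lie in
`[0.001305, 0.001305 + G_E]` with `G_E ≤ 2e-5`, a window of less than 2%
in current. The model is calibrated — once, by numerical search over peak
conductances and the two scale factors — against the behavioural anchors
that pin the operating regime:

* rheobase just below the base drive (0.001284 vs. 0.001305 drive units),
  so every network cell is suprathreshold but only barely;
* tonic firing at 10 Hz at the maximum drive `0.001305 + 2e-5` (10 s
  window including the first-spike delay);
* first-spike latency decreasing with drive (≈3.5 s near base, ≈2.2 s at
  maximum);
* single-spike IPSP peaks of ≈0.1 / 0.45 / 0.7 / 1.5 mV at
  `G_I = 0.002 / 0.008 / 0.011 / 0.02` under the characterization protocol
  below.

The quartet of IPSP anchors grows supralinearly with `G_I` (a factor 15 in
amplitude for a factor 10 in strength). A plain ohmic membrane cannot do
this; the calibration therefore relies on the subthreshold *amplifying*
nonlinearities of the MSN — the negative-slope region of the inward
rectifier and a sharp persistent-sodium activation foot placed just above
the holding potential (implemented in the `I_NaS` slot with fast
activation). With these, all four anchors are met within 1%. We treat the
channel kinetics as phenomenological: the anchors pin behaviour, and the
parameters were frozen after calibration and never revisited.

## Synapses

MSN→MSN GABA synapses use the deterministic Tsodyks–Markram short-term
plasticity model with the connectome-derived constants `U = 0.41`,
`D = 222 ms` (depression recovery), `F = 1859 ms` (facilitation decay), a
20 ms exponential conductance decay, −85 mV GABA reversal and uniform 1–3 ms
axonal delays. At a presynaptic spike the utilization facilitates first,
`S⁺ = S + U(1−S)`; the conductance increment is `weight · R⁻ · S⁺` with the
pre-spike resources `R⁻`; resources then deplete, `R⁺ = R⁻(1−S⁺)`. Between
spikes both variables relax exponentially in closed form, and the TM state
is advanced lazily at presynaptic spike times only (all synapses of one
source share a state because the model is deterministic). Whether the spike
update uses pre- or post-spike quantities is a convention; we use the
standard one above, and `steady_state_efficacy()` provides the analytic
periodic-train fixed point used as a test oracle.

The IPSP characterization protocol (`ipsp_peak()`) holds the cell at
−80 mV by a closed-form holding current, sets the chloride reversal to
−40 mV so IPSPs are depolarizing, and delivers one spike through a synapse
of weight `0.625 · G_I` — the mean of the network weight range
`[0.3125, 0.9375]·G_I`, since the reference curves are labelled by `G_I`
rather than by individual weights.

## The network and its desk-scale profile

The reference network has 400 cells, each ordered pair connected
independently with probability 0.4 (mean in-degree ≈ 160), weights uniform
in `[0.3125 G_I, 0.9375 G_I]`, delays uniform in 1–3 ms rounded to the
integration grid, and per-cell drives uniform in
`[0.001305, 0.001305+G_E]`, fixed for the run. Four independent RNG
streams (topology, weights, delays, drives) derive from the build seed.
There is no extrinsic noise: given the built network, integration is
bit-reproducible.

Runs of 10 min at `dt = 0.025 ms` with 400 cells are cluster-scale, so the
package defines a desk profile (`desk_profile()`): 100 cells, 120 s.
Scaling down changes two things. First, summed inhibition per cell falls
with in-degree; weights are therefore multiplied by
`κ = (399·0.4)/((N−1)p)`. Second, with fewer, stronger inputs the
*fluctuation* of the inhibitory input grows like `1/√in-degree`, and input
fluctuations destabilize the winners-take-all (WTA) fixed point: keeping
`p = 0.4` (in-degree ≈ 40) at 100 cells moved the WTA transition from
`G_I ≈ 0.006` down to `≈ 0.0035`. The desk profile therefore raises
the connection probability to 0.8 (in-degree ≈ 79, κ ≈ 2), which restores
the transition to between 0.005 and 0.006 — the same location the
full-scale 400-cell network exhibits. This was fixed by matching the
package's own full-scale reference sweep before the desk profile was
frozen.

### Integration scheme

Fixed-step exponential Euler at `dt = 0.025 ms` (any `dt ≤ 0.1` is
accepted): gating variables use tabulated steady states and per-step decay
factors on a 0.05 mV voltage grid (rebuilt per `(params, dt)`), and the
membrane equation uses the exact exponential update with conductances
frozen over the step. Spikes are upward crossings of 0 mV with a 2 ms
detection lockout. Each protocol starts from a rest state obtained by 2 s
of drive-free settling. Halving `dt` changes a 10 s spike count at maximum
drive by at most one spike. Non-finite state aborts integration with the
cell index and time.

## Calcium-like rasters and summary features

Spike trains are binned into non-overlapping 250 ms windows tiling
`[0, duration)` (half-open, so a spike at exactly 250 ms belongs to bin 2)
and binarized by whether a bin contains at least one spike — the temporal
resolution of the slice calcium recordings the model is compared with.
Cells that never spike are dropped (their indices are kept).

Three cell-averaged features feed the inference:

1. **mean activity** — fraction of active bins per cell;
2. **mean activation interval** — mean gap, in bins, between consecutive
   active bins (adjacent active bins count as a zero interval);
3. **interval CV** — SD/mean of those gaps.

Cells with fewer than two intervals contribute a CV of 0 (and, with no
interval at all, a mean interval of 0); the convention is arbitrary but
fixed and documented. All three are invariant under temporal shifts of
individual cells (exactly so for shifts that do not wrap activity across
the recording boundary), which is why they can reveal assembly structure
without any cross-correlation input.

The **total fluctuation** — the CV of the population-mean activity series
after discarding a 30 s (120-bin) transient — is a quality filter only: it
vanishes when the network locks into a WTA fixed point, but it depends
strongly on the number of recorded cells, so it cannot serve as an
inference feature. Simulations with total fluctuation strictly below 0.09
are rejected before training (`wta_filter()`; the boundary value is kept).

## Neural posterior estimation

The conditional density estimator is a mixture-density network written in
plain R: features are z-scored with training-set moments, parameters
min-max scaled to the prior box `[0.002, 0.02] × [0, 2e-5]`; two tanh
hidden layers of 64 units feed a head with 8 Gaussian components
(mixture logits, means, diagonal log-SDs). Training minimizes the negative
log-likelihood with full-batch Adam (learning rate 1e-2, at most 500
epochs, early stopping on a 10% validation split with patience 100); with
~150 records a training takes about a second. Diagonal covariances,
network width, component count and schedule are implementation choices
fixed after a small hyperparameter sweep on surrogate data; the published
procedure fixes none of them.

Because results depend on the training initialization, `train_restarts()`
repeats the training 30 times, each leaving out its own random 20
simulations; each restart is scored by the mean weighted error
`(G_I*−G_I)² + 900²(G_E*−G_E)²` between held-out truths and posterior
peaks (the factor 900 rescales `G_E`'s range onto `G_I`'s), and
`select_winner()` returns the argmin, ties broken by restart index.

`posterior_map()` evaluates the winner's conditional mixture on a 200×200
grid of cell centers over the prior box, truncates and renormalizes there
(grid mass 1 ± 0.01), and reports the joint grid argmax as the MAP —
marginal peaks are also reported, since reference figures mark both — plus
marginals by grid summation and a 10⁶-sample set (component-wise sampling,
out-of-box draws redrawn). Features more than 4 SDs outside the training
cloud raise a support warning on the summary. `best_fit_lookup()` returns
the simulation record minimizing the same weighted error to a target,
ties broken by lowest `sim_id`.

## Synthetic data: what it emulates and what it does not

Real slice rasters are not publicly deposited, so the package ships two
generators, both first-class code:

* **Markov rasters** (`synth_raster()`): independent two-state Markov
  chains per cell started from stationarity, with closed-form stationary
  activity `r/(1−q+r)` — the format of a slice recording with fully known
  statistics. They have no assembly structure and no cross-cell
  correlation; passing feature tests on them validates bookkeeping, not
  biology.
* **A surrogate feature landscape** (`surrogate_features()`): an explicit
  analytic map from `(G_I, G_E)` to the three features honouring the
  simulated landscape's structure — activity strictly decreasing in
  inhibition (logistic) and increasing in drive; interval increasing in
  inhibition with a weaker drive interaction; interval CV a bump that
  collapses below `g_c = 0.006` when drive is high — with Gaussian
  observation noise of SD 5% of each feature's actual range over the box.
  It is a test double for the biophysical simulator (~10⁴× faster), used
  to measure parameter recovery; its exact coefficients were chosen so
  that an exact-likelihood oracle on the map recovers both parameters
  within the recovery tolerance, i.e. so that the recovery property is
  attainable at all at this noise level. Passing recovery on the surrogate
  shows the estimator works on a landscape *like* the simulated one; it
  does not by itself validate the biophysical features.

`slice_like_subsample()` emulates the varying number of recorded cells
across preparations; the three features are unchanged in expectation while
the total fluctuation is not.

## Assembly analysis

The descriptive module mirrors the published visualization chain in
simplified, pinned form: Jaccard distances between cell activity vectors,
non-metric multidimensional scaling into 3-D (duplicate rows collapsed and
sharing coordinates), Louvain clustering on a 15-nearest-neighbour graph of
the embedding, clusters under 5 cells merged into their nearest neighbour.
A bin's dominant cluster is the one with the highest fraction of its cells
active provided that fraction reaches 0.5 (ties and empty bins yield
none); transition graphs count successive distinct dominant clusters with
gaps skipped. The original method uses UMAP with settings that live in the
cited authors' code; this module is deliberately descriptive, reproducible
bit-for-bit from its seed, and carries no acceptance weight.

## Problem sizes and runtime

The test suite and the acceptance script use the desk profile throughout:
100-cell, 120 s networks (about 12 s each on one CPU), 150-record
surrogate trainings (seconds), and the 7-point × 2-seed WTA sweep
(~3 min). The full-scale profile (400 cells, 600 s, 200 simulations) is
available through `validate_config(list(profile = "full"))` but is a
cluster-scale undertaking, not part of routine runs.

## Known limitations

* Simulated mean activity (0.4–1.0 across most of the box at desk scale)
  is denser than typical slice rasters; correspondingly, total fluctuation
  rarely exceeds the 0.09 threshold, so the WTA filter removes most
  desk-scale biophysical simulations. Estimator training in the shipped
  analyses therefore uses the surrogate landscape; the biophysical sweep
  driver reports its filter outcome honestly.
* One cell type: no D1/D2 distinction, no dopamine modulation, no
  cortical/thalamic spiking afferents, no fast-spiking interneuron
  feedforward inhibition, no stochastic channel or release noise.
* The channel kinetics are behaviourally calibrated, not fitted to voltage-
  clamp data; conclusions should rest on the calibrated anchors and the
  network regimes, not on individual current traces.
* Connection probability is fixed (0.4 at full scale; 0.8 in the desk
  profile for transition fidelity); varying it is out of scope.
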