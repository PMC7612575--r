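---
title: "Graph-based axon tracking and conduction-velocity estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based axon tracking and conduction-velocity estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axontrace)
```

## The problem

High-density microelectrode arrays (HD-MEAs) place thousands of extracellular
electrodes at a pitch of ~17.5 µm under a neuronal culture. After spike
sorting, averaging the raw signal around every spike of one unit gives that
unit's *template* (or electrical footprint): a channels × samples voltage
matrix in which the action potential of a single neuron is visible not only
at the soma but — at tens of microvolts — along its axonal arbor. The axonal
signal propagates, so the *peak latency* of each channel increases with arc
length along the axon. `axontrace` reconstructs the axonal branches of one
unit from its template alone and estimates each branch's conduction velocity,
fully automatically.

The pipeline has four stages.

### 1. Channel selection

Per channel we compute four scalar features: peak-to-peak amplitude (µV),
peak time (time of the most negative sample, ms), excess kurtosis over the
template window, and the standard deviation of peak times within a 30 µm
neighborhood. Four filters — each can be disabled or retuned — keep channels
that plausibly carry axonal signal:

* **amplitude** ≥ `detect_threshold` × the footprint maximum (default 1%),
  or an absolute µV cutoff;
* **kurtosis** ≥ 0.3: a channel with a spike riding on a flat baseline is
  strongly supergaussian, while pure noise is near-Gaussian (excess
  kurtosis ≈ 0);
* **peak-time dispersion** ≤ 1 ms over the 30 µm neighborhood: signal peaks
  are locally coherent, noise peaks are uniform over the window;
* **initial delay**: channels peaking earlier than 0.1 ms after the
  largest-amplitude channel (the *initial channel*, assumed near the axon
  initial segment) carry somatic/dendritic signal and are dropped.

The selection is the intersection of the four masks; isolated channels (no
other selected channel within 100 µm) are removed in a single pass, and the
initial channel is force-included because every path search targets it.

### 2. Propagation graph

Selected channels become nodes of a directed graph. Each node is scored by

h_init = α·a_n + (1 − α)·p_n,  α = 0.2,

where a_n and p_n are min–max-normalized amplitudes and peak latencies.
Channels peaking late — the distal ends of branches — get high h_init.
Each node receives at most 3 outgoing edges towards channels that peak
strictly earlier and lie within 100 µm, preferring large amplitudes with a
shortest-distance tie-break; nodes with no such candidate other than the
initial channel connect straight to it when within 200 µm. Edge costs
combine **h_edge** — edge amplitudes (mean of the two endpoints) min–max
normalized and reversed, so that high-amplitude (axonal) edges are cheap,
with edges into the initial channel pinned at 2 — and **d_n**, the
normalized edge length raised to the power e = 2, which penalizes long
jumps super-linearly.

### 3. Branch reconstruction

Starting nodes are h_init local maxima within 100 µm. From each, the path
to the initial channel minimizing Σ(h_edge + d_n) is found; because no
admissible distance-to-goal estimate exists for this cost, the optimal-path
search runs with a zero heuristic, i.e. as Dijkstra's algorithm, which
attains the exact minimum. A new path is trimmed against the neighbor sets
(100 µm) of paths found earlier; the earliest-peaking surviving channel is
attached to the closest node of the nearest existing path, which becomes a
*branching point*. Stubs with fewer than 3 channels beyond their branching
point are pruned; chainable paths are merged; a raw branch is accepted when
longer than 100 µm with at least 5 channels; accepted channels plus a 50 µm
margin are excluded from further searches.

### 4. Velocity estimation

For each branch, cumulative along-path distance (µm) is regressed on peak
latency (ms) with the Theil–Sen estimator (median of all pairwise slopes),
so the slope is directly a velocity in mm/s (µm/ms ≡ mm/s). Channels whose
absolute residual exceeds both 8 × the raw median absolute deviation of the
residuals and 30 µm are removed once and the line refit. Latency gaps above
1 ms trigger a tentative split at the largest gap, kept only if it raises
the mean R²; sub-branches recurse and must retain the minimum point count.
Branches with R² < 0.9, or a non-positive slope, are discarded. The
reported standard error and p-value are those of the two-sided slope test
of an ordinary least-squares fit on the cleaned points — the robust line
has no standard parametric error, and these OLS diagnostics are the
conventional companion statistics.

## The synthetic footprint generator

Unit tests and the acceptance analysis need footprints with known ground
truth. `simulate_footprint()` builds planar arbors (radial multi-branch,
single straight branch, or a wide Y with a trunk and two daughters) rooted
at a soma on a regular grid, with per-branch conduction velocities drawn
from 200–500 mm/s — the physiological range for unmyelinated cortical
axons — branch lengths of 380–480 µm, and a 0.3 ms onset delay standing in
for initiation at the axon initial segment. Rendering is phenomenological:
each electrode sees a somatic deflection plus one axonal deflection from
its nearest arbor point, with peak latency `onset + arc/velocity`, peak
amplitude `scale/(lateral² + offset²)^(decay/2)` (10 µm plane offset,
decay 2; 600 µV somatic and 60 µV axonal peak), a negative Gaussian
waveform (σ = 0.1 ms) and optional seeded white noise. The sampling
frequency defaults to 32 kHz (a 0.03125 ms step). Problem sizes used
throughout the tests — a 64 × 64 grid at 17.5 µm pitch, three branches,
ten seeds — were chosen to represent a full footprint at realistic scale
while keeping a complete run in seconds.

This generator produces exactly the two observables the algorithm consumes
(per-channel amplitude and latency with axonal structure). It does **not**
simulate membrane biophysics: no amplitude decay along the axon, no
waveform shape changes at branch points, no correlated noise, no electrode
area averaging. Passing tests therefore demonstrate correctness of the
tracking machinery under the algorithm's own signal model, not performance
on every pathology of real recordings.

## Parameter configurations

The defaults listed in `axon_tracking_params()` are the clean-template
configuration. Two documented variants:

* **Noisy templates.** With additive white noise the excess-kurtosis
  estimator has sampling standard deviation ≈ √(24/n); at the ~120-sample
  windows used here that is ≈ 0.44, so the clean-data threshold 0.3 sits
  *inside* the noise distribution and lets pure-noise channels through. For
  noise at ~10% of the axonal peak we recommend `kurt_threshold = 1`
  (≈ 2.3 σ of the noise kurtosis, while genuinely spiking channels lie well
  above 1) and `peak_std_threshold = 0.5` ms (true latency spread within
  30 µm is ≤ 0.15 ms at ≥ 200 mm/s; uniform noise peaks give ≈ 1.1 ms).
* **Coarse arrays / bifurcation localization.** Radius-type parameters
  scale with the pitch (e.g. `exclusion_radius = 2 × pitch`); conversely,
  shrinking `max_edge_distance` to ~2 × pitch forces paths through
  consecutive electrodes, which localizes branching points to electrode
  resolution (used in the Y-arbor test).

## Numerical choices and degenerate inputs

* Kurtosis uses the population (biased) moment estimator over the full
  window; zero-variance traces get −∞ and always fail the filter. Whether
  to clip the baseline before the moment computation is left open by the
  method description; the full window is used here.
* Peak-time ties resolve to the earliest sample; processing-order ties in
  h_init resolve by descending amplitude then channel index; starting-node
  ties suppress the later node. All ties being deterministic makes the
  whole pipeline reproducible bit-for-bit.
* Min–max normalizations with zero range (all amplitudes equal, single
  edge) contribute 0, so degenerate graphs still search.
* The MAD in the outlier rule is the raw median absolute deviation
  (no 1.4826 consistency factor), matching the plain "N times the MAD"
  prescription with N = 8.
* The relative detection threshold uses ≥, keeping boundary channels.
* Pruning measures the portion of a path on the far side of its branching
  point from the initial channel.

## Ground-truth evaluation

Estimated branches are matched to ground-truth polylines many-to-one: a
ground-truth branch matches the estimated branch minimizing the median of
point-to-path distances, accepted below 40 µm, after resampling ground
truth at 1 µm arc steps ("segments" are otherwise undefined, and the
median is directional, ground truth → estimate, as specified). Overlapping
ground-truth branches matched to one estimate (> 20% of points within
15 µm) drop the shorter member. Tracking error is the mean ± sd of
point-to-*segment* distances from branch channels to the matched
polylines; the ground-truth velocity of an estimate spanning several
branches is their length-weighted mean.

## Known limitations

* Velocity estimates on short noisy branches (5–8 channels) can deviate
  substantially while keeping a high R²; the R² gate does not protect
  against coherent latency jitter on few points. Longer branches are
  intrinsically more reliable.
* Branching points are localized no finer than the path node spacing, and
  the neighbor-set trimming attaches daughters up to one neighbor radius
  past the true bifurcation.
* The method is 2-D: arbors growing out of the electrode plane violate the
  latency/arc-length model.
* Estimated path length along grid electrodes slightly exceeds true arc
  length (discretization zigzag), biasing velocities upward by a small
  percentage at fine pitches.
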