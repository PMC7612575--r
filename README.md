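# axontrace

Automated reconstruction of **axonal branches** and estimation of
**action-potential conduction velocities** from extracellular templates
("electrical footprints") recorded on high-density microelectrode arrays
(HD-MEAs).

After spike sorting an HD-MEA recording, the spike-triggered average of one
unit across all electrodes shows the neuron's action potential propagating
along its axonal arbor: tens-of-µV deflections whose peak latency grows with
arc length. `axontrace` turns one such template (channels × samples matrix,
µV) plus the electrode x–y layout (µm) into a set of axonal branches, each
an ordered electrode path with a fitted conduction velocity. This is useful
to anyone studying axonal physiology at scale — conduction-velocity changes
in development, demyelination models, pharmacology — directly from
extracellular recordings.

## Method

1. **Channel selection** — four filters (peak-to-peak amplitude; excess
   kurtosis, since spike-bearing traces are supergaussian; peak-time
   dispersion over 30 µm neighborhoods; initial delay relative to the
   largest-amplitude *initial channel*) are intersected, and isolated
   channels removed.
2. **Propagation graph** — selected channels are scored by
   *h_init* = α·a_n + (1 − α)·p_n (normalized amplitude and latency,
   α = 0.2) and connected by directed edges towards earlier-peaking
   channels within 100 µm; edge cost is *h_edge* (reversed normalized edge
   amplitude; axonal, high-amplitude edges are cheap; edges into the
   initial channel cost 2) plus *d_n* (normalized length, squared).
3. **Branch reconstruction** — from every *h_init* local maximum, the path
   to the initial channel minimizing Σ(*h_edge* + *d_n*) is extracted
   (zero-heuristic optimal search = Dijkstra), trimmed against earlier
   paths' 100 µm neighbor sets (recording branching points), pruned,
   merged, and accepted when ≥ 100 µm long with ≥ 5 channels.
4. **Velocity estimation** — cumulative path distance (µm) vs. peak latency
   (ms) is fit with the Theil–Sen estimator; the slope is the velocity in
   mm/s (µm/ms ≡ mm/s). Outliers (> 8 × MAD **and** > 30 µm residual) are
   removed once, > 1 ms latency jumps trigger a tentative split, and
   branches with R² < 0.9 are discarded.

A seeded synthetic-footprint generator (planar arbors with known per-branch
velocities, phenomenological amplitude/latency rendering) and a
ground-truth evaluation module (many-to-one branch matching, tracking and
velocity errors) make the whole pipeline testable offline.

## Worked example

```r
library(axontrace)

sim <- simulate_footprint(arbor_params(), seed = 1)   # 64x64 grid, 17.5 um
print(sim$arbor)
tr <- track_axons(sim$template, sim$locations)
print(tr)
evaluate_tracking(tr, sim$arbor, sim$locations)
```

```
axon_arbor: 3 branches (preset radial, seed 1)
  branch 0: length  400.0 um, velocity 469.5 mm/s, onset 0.30 ms
  branch 1: length  380.0 um, velocity 343.2 mm/s, onset 0.30 ms
  branch 2: length  460.0 um, velocity 236.5 mm/s, onset 0.30 ms
axon_tracking: 361 selected channels, 3 branches
  branch 0:  11 channels, length  447.3 um, velocity   235.8 mm/s (r2 1.000)
  branch 1:   9 channels, length  381.7 um, velocity   338.2 mm/s (r2 0.999)
  branch 2:   8 channels, length  377.3 um, velocity   484.8 mm/s (r2 0.998)
  model branch matched_gt velocity_gt velocity_est  abs_error   rel_error
1 model      0          2    236.5076     235.7895  0.7181026 0.003036277
2 model      1          1    343.1690     338.1799  4.9891146 0.014538360
3 model      2          0    469.5169     484.8198 15.3028845 0.032592830
  tracking_error_mean tracking_error_sd
1            3.137389          2.606909
2            2.425430          1.028602
3            2.051106          1.258191
```

All three branches are recovered; velocities agree with ground truth within
0.3–3.3% and the mean tracking error is 2–3 µm — a fraction of the 17.5 µm
electrode pitch. `track_axons()` also works on templates loaded from disk
(`load_template()`: CSV/TSV voltage matrix + `channel,x,y` layout), and
results serialize with `write_tracking_json()`. Ground truth round-trips
through SWC + JSON sidecar (`write_ground_truth()` / `read_ground_truth()`).

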