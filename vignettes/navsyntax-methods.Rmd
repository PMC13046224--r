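---
title: "Space-syntax and navigation-state analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-syntax and navigation-state analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navsyntax)
```

## What the package computes

`navsyntax` analyses fixed-rate 2-D position logs from navigation tasks in a
virtual environment (coordinates in virtual meters, vm) together with a
geometric description of that environment. It has four layers:

1. **Environment space syntax.** The street network is abstracted as *axial
   lines* (fewest, longest straight sight lines); their intersection graph is
   scored with connectivity (degree), mean topological depth, and
   integration. The open space is additionally discretised on a square
   lattice and scored by *visibility graph analysis* (VGA): two cells are
   connected when the open segment between their centers avoids every
   obstacle interior.
2. **Navigation states.** Instantaneous speed at each interior sample is the
   average of the two adjacent-interval velocity estimates. Each
   participant's pooled speed series is partitioned by 1-D k-means into
   `k = 3` clusters, read in ascending centroid order as WAYFINDING (search,
   hesitation, reorientation), TRANSITION (directional adjustment), and
   MOVING (goal-directed locomotion). Clustering per participant gives
   individualized relative thresholds instead of one absolute speed cutoff.
3. **Navigation efficiency and experienced metrics.** Efficiency is
   `(moving time + transition time) / navigation time`. The six experienced
   metrics (EAI, EAC, EMAD; EVI, EVC, EVMD) average the occupied axial
   line's / grid cell's integration, connectivity, and mean depth over all
   trajectory samples.
4. **Statistics.** Group contrasts and correlations are gated per variable
   (and per group) by the Shapiro–Wilk test at α = 0.05: parametric
   (t test / Pearson) when everything passes, rank-based (Mann–Whitney U /
   Spearman) otherwise. Efficiency along the normalized shortest route is
   compared between groups bin-by-bin with a permutation test, and
   wayfinding-labelled samples are summarised as a density map with
   top-1% hotspot regions.

## The integration measure

For a connected graph of `n` elements with mean depth `MD` from a given
element, relative asymmetry is `RA = 2(MD - 1)/(n - 2)`, rescaled by the
diamond value

`D_n = 2 { n [log2((n+2)/3) - 1] + 1 } / [(n-1)(n-2)]`,

and integration is `1/RRA = D_n / RA`. This is the classic
Hillier–Hanson global (radius-n) variant, the default of the depthmapX
family of tools; local radius-restricted variants are deliberately out of
scope. When `MD = 1` (an element at depth 1 from every other) RA is 0 and
integration is undefined; the package returns a flagged `NA`, never a large
stand-in number, and trajectory averages over such elements raise an error
rather than silently propagate.

```{r integration}
# P4 chain: endpoints 1/3, interior 1.0
p4 <- matrix(FALSE, 4, 4); p4[cbind(1:3, 2:4)] <- TRUE; p4 <- p4 | t(p4)
integration(md = 2, n = 4)      # endpoint of a 4-chain
integration(md = 4/3, n = 4)    # interior
```

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `grid_resolution` | vm | 1 | VGA lattice cell edge; 1 vm matches common practice for room/street-scale analysis |
| `k` | – | 3 | navigation states; elbow of the SSE curve and stable silhouette across cohorts |
| `k_range` | – | 2–6 | candidate range for `cluster_diagnostics()` |
| `dt` | s | 0.1 | sampling interval of the logs (10 Hz) |
| `bin_vm` | vm | 1 | route-profile bin width in arclength of the concatenated shortest route |
| `n_perm` | – | 10000 | permutation draws when exhaustive enumeration (≤ 20000 relabellings) is infeasible |
| `deviation_threshold` | vm | one street width | a sample farther than this from the route flags the trial as a route error |
| `alpha_normal` | – | 0.05 | Shapiro–Wilk gate level |

## Numerical and procedural choices

- **Axial adjacency tolerance** is 1e-6 vm; segments touching at endpoints
  count as adjacent, so street chains are connected at junctions.
- **Line of sight** is blocked only when the open segment passes through an
  obstacle's strict interior; grazing along a wall or touching a corner
  stays visible. This makes the relation symmetric and deterministic.
  Axis-aligned rectangular obstacles use an exact slab-clip test; arbitrary
  simple polygons use boundary-crossing subdivision with midpoint
  interiority tests.
- **Grid convention**: origin lower-left; cell `(row, col)` is 0-based with
  center `((col+0.5)res, (row+0.5)res)`; a cell is open iff its center is in
  open space; a point exactly on a cell edge belongs to the lower-index
  cell; a point inside an obstacle (clipping noise) is reassigned to the
  nearest open cell.
- **k-means initialization.** Lloyd iterations are run from a small set of
  deterministic starts — sample quantiles at `(2j-1)/(2k)`, the same
  quantiles of the distinct values, and even spacing over the range — and
  the lowest-SSE solution is kept. A single quantile start is not enough:
  when one regime holds most of the samples, all its seeds fall inside that
  regime and Lloyd converges to splitting it instead of recovering the three
  regimes. Multiple deterministic starts fix this while keeping the fit
  RNG-free and reproducible. Fewer distinct speeds than `k`, or duplicate
  converged centroids, raise a degenerate-input error.
- **Endpoint samples** have no defined speed, so they are excluded from
  clustering and inherit the state of the nearest interior sample for
  duration accounting. Navigation time is the sum of the three state times
  (one `dt` per sample), so the partition
  `wayfinding + transition + moving = navigation` is exact by construction
  and efficiency equals `1 - wayfinding/navigation` identically.
- **Per-participant pooling**: speeds are pooled across a participant's
  trials before clustering, so thresholds are individualized but stable
  within participant.
- **Nearest-line assignment**: every sample maps to the axial line with
  minimum segment distance (ties to the lower line id), so off-street
  samples in parks still contribute; the analogous total rule holds for
  grid cells.
- **Sample weighting**: experienced metrics average over samples, not
  arclength — dwelling in a region up-weights it, which is what makes the
  metrics "experienced" rather than purely geometric.
- **Statistics**: all tests are two-sided; the two-sample parametric branch
  is the Welch t test. No multiple-testing correction is applied across
  route bins by default (a Benjamini–Hochberg option exists but is off),
  so per-bin p-values are reported unadjusted. The permutation statistic is
  the difference of group means; labels are permuted jointly across bins;
  enumeration is exhaustive when the relabelling count is at most 20000
  (exact p = proportion with `|T*| ≥ |T|`), otherwise the add-one estimator
  `(1 + #{|T*| ≥ |T|})/(1 + n_perm)` is used. Bins with fewer than two
  observed participants in a group are skipped.
- **Density hotspots**: the top mask always contains
  `ceiling(0.01 × positive cells)` cells, ties broken by cell index, so the
  mask size is deterministic under flat densities.
- **MoCA adjustment**: +1 point for ≤ 12 education years, capped at 30.

## The synthetic cohort generator

No participant data ships with the package; the generator provides known
ground truth for every stage. It emulates:

- a Manhattan-grid urban block (default 200 × 150 vm, 4 + 3 streets of
  width 5 vm) with one axial line per street and targets in a fixed
  sequential order at street intersections (6 targets, 5 consecutive
  trials);
- a semi-Markov walk along each trial's shortest street route: per-sample
  speeds drawn from the active regime's Normal distribution truncated at 0,
  wayfinding dwells injected at decision points (trial starts and route
  vertices) with group-specific probability, and a fixed slow-down
  transition at every vertex;
- group profiles — young: moving 2.0 vm/s, hesitation probability 0.2,
  mean dwell 7 s; older: moving 1.5 vm/s, hesitation probability 0.6,
  mean dwell 12 s; both: wayfinding 0.15 vm/s, transition 0.9 vm/s,
  regime SDs 0.04/0.08/0.05 vm/s. Speed SDs are small because VR
  locomotion is controller-paced; dwell lengths are set so each state
  occupies a non-trivial share of time, as in real wayfinding cohorts.
  With a vanishing wayfinding share, k-means' variance criterion genuinely
  prefers splitting the dominant moving regime — a property of the method
  the generator must respect, not work around;
- cognitive scores `intercept + slope × efficiency + noise`, clipped to
  instrument ranges, with positive couplings for MoCA, MMSE, ROCF and MRT
  and a negative coupling for TMTA (a completion time), so every
  association's sign is known by construction.

Per-participant RNG streams derive from `(seed, participant index)`, so
regeneration is bit-identical and order-independent.

What the generator does **not** emulate: route errors and backtracking
(trajectories follow the shortest route), gaze/head orientation, fatigue or
learning across trials, VR hardware artifacts, and psychometrically
realistic score distributions. Passing tests therefore demonstrate that the
pipeline recovers structure *of the kind assumed by the analysis* — three
latent speed regimes, localized hesitation, linear score couplings — not
that it is robust to every failure mode of real data.

## Problem sizes in the test suite

The suite validates the space-syntax oracle on 200 random connected graphs
(n ≤ 12) against an independent brute-force BFS implementation at 1e-12;
VGA correctness on 5 × 5 and L-shaped rooms plus 50 random layouts; state
recovery (≥ 95%) and group/correlation recovery on cohorts of 20 + 20
participants over 50 replicates; and permutation-test calibration with 1000
null replicates (rejection rate in [0.03, 0.07] at α = 0.05). Compact
3 × 2-street environments with a 1.5 vm grid are used where a full-size
visibility graph is not the property under test.

## Known limitations

- Axial lines are supplied or generated, never derived automatically from
  geometry; isovist areas and angular segment analysis are out of scope.
- Global metrics error on disconnected graphs unless per-component analysis
  is requested explicitly; component-wise integration uses the component's
  size for normalization, so values are not comparable across components of
  different size.
- The route-error flag is a maximum-deviation criterion, a stand-in for
  richer error taxonomies (wrong-target visits, loops).
- The Shapiro–Wilk gate is applied per variable at a fixed α; with many
  variables the implied model selection is itself uncorrected, mirroring
  common practice rather than best practice.
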