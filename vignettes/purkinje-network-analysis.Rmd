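---
title: "Morphometry and complex-network analysis of distal Purkinje networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry and complex-network analysis of distal Purkinje networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(purkinet)
```

## The measurement problem

The distal Purkinje network couples the ventricular conduction system to
working myocardium through strands, plexuses and two distinct cell shapes
(tubular and star-like). At confocal resolution the measurable objects are
(i) closed triangle meshes of individually segmented cells and (ii) a
spatially embedded centreline graph per image stack: labelled 3D landmarks
placed at furcations and along pathways, joined by straight segments.
`purkinet` takes those two objects — real or synthetic — and produces the
quantitative description of the network: per-cell shape descriptors, branch
and furcation-angle statistics, and graph-theoretic complexity measures
with null-model context.

This vignette records the model assumptions, the tunable parameters and
their defaults, what the synthetic generator does and does not emulate, the
numerical choices, and the design decisions taken where more than one
reasonable convention exists. It states no empirical result that the test
suite and the acceptance script do not themselves compute.

## Cell morphometry

Surface area is the sum of triangle areas; enclosed volume applies the
divergence theorem, summing signed origin-tetrahedron volumes
$(v_1 \cdot (v_2 \times v_3))/6$ over faces. Both require a watertight,
consistently oriented mesh; construction of a `trimesh` enforces this and
flips the orientation globally if the signed volume comes out negative.
Open meshes are rejected with the boundary-edge count rather than repaired:
hole-filling would silently change the volume the divergence theorem
reports.

Cell dimensions use the principal axes of the area-weighted vertex
second-moment matrix (each vertex weighted by a third of its incident face
area, so tessellation density does not bias the axes). Length is the vertex
extent along the first axis; the two transverse extents are the sagittal
and coronal diameters. Conventions chosen where measurement practice is
ambiguous:

* **Tubular cells** report one diameter, the mean of the two transverse
  extents — mirroring how repeated calliper measurements on a roughly
  circular cross-section are averaged.
* **Star-like cells** report the longest principal extent as the length, a
  chord-like proxy for the longest trajectory between borders; a
  `method = "chord"` variant reports the true maximum vertex-to-vertex
  distance instead. The surface-geodesic reading of "longest trajectory"
  is not implemented; for flattened star shapes the chord underestimates a
  geodesic by at most the hub thickness, well inside the biological
  variance.
* **Degenerate spectra.** A capsule's two transverse moments are exactly
  equal, so eigenvectors in that plane are arbitrary and plain
  eigendecomposition is not rotation-equivariant. Ties (relative gap
  below $10^{-7}$) are resolved by pointing the axis at the vertex
  farthest from the axes already fixed (lowest index on ties). Because a
  rigid motion moves that same vertex, dimensions are
  rotation-invariant to about $10^{-12}$ relative — the test suite asserts
  $10^{-6}$. Fully isotropic meshes additionally emit a warning.

The voxel-count volume oracle in the tests rasterises an analytic
star-shaped blob at the 0.31 μm imaging grid and counts interior voxel
centres; mesh volume agrees within 2 %, tying the divergence-theorem
estimator to the voxel-sum convention used for myocyte volumes.

## Centreline networks

`build_graph()` joins landmarks with straight segments and assigns roles by
degree: terminal (1), pass-through (2), furcation (≥ 3). Branches are
maximal chains between non-degree-2 nodes; a connected component consisting
only of degree-2 nodes is reported as one closed branch and flagged. Branch
length is the summed member-segment length, so the sum over branches equals
the sum over edges exactly.

Furcation angles are measured between the *immediate* incident segments
(node → adjacent landmark), not whole-branch average directions: landmarks
sit exactly at the geometric features the tracer drew, so the local segment
is the drawn geometry. Angles strictly below 90° are acute (α); 90° and
above are obtuse (β), since the acute population is observed on an open
interval up to 90°. Degree-4 and higher nodes emit all pairwise angles,
each classified the same way. Angle summaries are circular (resultant-vector
mean, $\mathrm{sd} = \sqrt{-2\ln \bar R}$); linear mean ± SD are reported
alongside because angle populations confined to [0°, 180°] are commonly
summarised linearly.

## Complexity metrics

All metrics run in binary mode (every edge counts 1) or weighted mode,
where the connection weight is the inverse Euclidean edge length and
shortest paths minimise summed length — the standard weight-to-length
conversion for "inverse distance" efficiency. Global efficiency is the
mean inverse shortest-path length over ordered pairs (zero for unreachable
pairs); local efficiency of a node is the global efficiency of the subgraph
induced by its neighbours, with paths confined to that subgraph — the
stricter induced-subgraph definition rather than the looser verbal
"inverse shortest path of all neighbours". Betweenness uses Brandes
accumulation with fractional counting over tied shortest paths and is
normalised by $(n-1)(n-2)/2$; it runs on the same lengths as the efficiency
measures, with binary mode behind the same flag (which convention the
original analysis used is not recorded). Assortativity is the Pearson
correlation of endpoint degrees over the symmetrised edge list, computed on
binary degree, not strength; when all endpoint degrees are equal it is
reported as undefined rather than 0. Characteristic path length averages
finite distances only and reports the count of excluded unreachable pairs.
The compiled core (Floyd–Warshall, per-source BFS for binary mode, Brandes)
is cross-checked in the tests against brute-force path enumeration and
against igraph to $10^{-9}$.

## Null models and the small-world criterion

Random surrogates use degree-preserving double-edge swaps (10 attempts per
edge), rejecting self-loops and duplicate edges; edge lengths are carried
over as a permuted multiset, conserving the weight distribution while
destroying length–topology correlation (preserving that correlation would
require spatially constrained nulls, which are out of scope). Lattice
surrogates accept a swap only when it does not increase the adjacency band
cost $\sum |pos_i - pos_j|$ under a node ordering, and the swap passes
repeat until the cost stops improving. Two implementation findings are
recorded as design decisions:

* **Node ordering: depth-first, not breadth-first.** BFS from a hub
  interleaves the two sides of every chain, so ring-like graphs start with
  a large band cost and the greedy descent stalls in a half-scrambled
  state whose local efficiency is far *below* the original — an unusable
  lattice. DFS lays each chain out consecutively; the ordering is exposed
  as a parameter.
* **Run to convergence, not a fixed budget.** A single pass of 10 swaps
  per edge leaves the descent far from its minimum (observed on
  rewired-lattice test graphs as a surrogate less clustered than the
  input). Passes repeat until the band cost stops decreasing, capped at
  100 passes; the cap has never been reached in testing.

The small-world criterion is the two-sided efficiency comparison
`GE_latt < GE < GE_rand` and `LE_rand < LE < LE_latt` against ensembles of
100 random and 100 lattice surrogates (ensemble means). Graphs too small
to rewire (fewer than 4 nodes, or admitting no valid swap at all, like a
triangle) return `"indeterminate"` rather than `FALSE` — several real
stacks are near-trivial trees and a hard `FALSE` would overstate the
evidence. Whether the surrogate ensembles should use binary or weighted
efficiencies is not recorded in the source analysis; both are supported and
the result object labels which was used (binary is the default, since the
canonical small-world benchmarks are binary).

## The synthetic generator: a stated world

`simulate_network()` grows a spatially embedded tree (optional loop
closure) whose *measured* statistics match the configured population
values:

* **Branch lengths** are exponential with redraw above
  `branch_length_max` (300 μm). The configured mean (84.6 μm) is the mean
  of the truncated law; the parent rate is solved internally by
  root-finding. Configuring the parent mean instead would bias the
  generated mean about 9 μm low — a measured branch-length mean necessarily
  describes the truncated population.
* **Furcation angles.** At each furcation the daughter–daughter angle is
  drawn from the acute law (55.2° ± 20.6°) and the two parent–daughter
  angles from the obtuse law (140.19° ± 25.8°). Three pairwise angles
  among unit vectors must satisfy $\alpha + \beta_1 + \beta_2 \le 360°$
  and $\alpha \ge |\beta_1 - \beta_2|$; the configured means sit only
  0.58 SD below the closure bound, so roughly a quarter of raw draws are
  infeasible. Infeasible triples are reconciled by least-squares
  projection onto the violated constraint. Placement is fully 3D: the
  daughters need not be coplanar with the parent (a planar construction
  would force $\beta$ means to $(360° - \alpha)/2 \approx 152°$, far from
  the stated population). Projection pulls both populations down by a few
  degrees, so — exactly parallel to the branch-length rate — the internal
  draw means are calibrated by a deterministic fixed-seed fixed-point so
  that the measured populations match the configured means.
* **Field of view.** Growth starts at the centre of the 318 × 318 × 60 μm
  box with a mostly in-plane initial direction. The azimuth of a daughter
  pair about the parent axis is a free parameter, so it is re-drawn (up to
  20 times) to steer daughters back into the box *without altering any
  drawn angle*; branches that still exit simply terminate, as fibres
  leaving the field of view do. Furcations only occur inside the box.
* **Connectivity and budget.** If every tip terminates before the branch
  budget is spent, growth resumes by furcating at an existing terminal
  (re-using its incoming direction), so the graph stays connected and no
  degree-2 chain nodes merge two drawn branches. A furcation is only
  placed when the remaining budget covers both daughters and all pending
  tips; the rare one-branch remainder is attached as an extra daughter at
  an existing furcation node. Consequently the extracted branch set
  reproduces the drawn lengths one-to-one.
* **Unstated parameters**, chosen once: furcation probability 0.7
  (supercritical growth with a realistic mix of terminals and furcations),
  loop-closure probability 0 (pure trees; plexus redundancy via the
  `loop_prob` parameter), pass-through subdivision off by default (the
  drawn centrelines are straight landmark-to-landmark segments;
  `max_segments > 1` adds jittered degree-2 waypoints), and ±8° direction
  jitter at those waypoints.

`simulate_cell_mesh()` builds capsules (cylinder with hemispherical caps)
for tubular cells and, for star-like cells, a star-shaped radial surface
over a UV sphere: a flattened hub with `n_arms` (default 3) tapering arms,
slight seeded per-arm length jitter (arms of real cells are unequal, and
exact n-fold symmetry would make the principal axes degenerate), and the
arm pair realising the configured span kept exact. Star-shaped radial
surfaces are watertight and self-intersection-free by construction.

What a green test does **not** establish: the generator emulates summary
statistics (length law, angle populations, field-of-view truncation,
tree/plexus topology), not confocal physics — no point-spread function,
labelling noise, segmentation error, curvature of real pathways between
landmarks, or spatial correlation between branch length and position. Real
stacks also contain several disconnected subnetworks per field of view;
the generator grows one connected network per call.

## Numerical choices

* Distances: dense Floyd–Warshall (weighted) and per-source BFS (binary)
  in C++; Brandes betweenness with $O(n^2)$ Dijkstra extraction — graph
  sizes here are hundreds of nodes, where simplicity beats a heap.
* Tie counting in betweenness uses exact floating-point equality of path
  lengths, matching the reference implementations it is checked against;
  ties at random weights have measure zero.
* The landmark merge tolerance defaults to 0.31 μm — one voxel; two
  landmarks closer than that are indistinguishable at acquisition
  resolution and rejected loudly.
* Exactly-90° angles classify as β; the acute population is open at 90°.
* Circular means are reduced to [0°, 360°) with the 360° boundary snapped
  to 0; a mean resultant length below $10^{-12}$ flags the mean undefined.
* ANOVA uses the textbook between/within decomposition; its F and p are
  cross-checked against `stats::oneway.test` in the tests.
* Seeds: every stochastic function takes an explicit seed and restores the
  caller's RNG state. The pipeline derives per-stack, per-stage substreams
  from the master seed by fixed integer arithmetic, so adding a stack
  never perturbs another stack's results.

## Known limitations

* Lattice surrogates depend on the node ordering; the DFS default is a
  heuristic, and a poor custom ordering degrades the lattice (monotone
  band cost is still guaranteed).
* Weighted efficiencies carry units (μm⁻¹) and are not bounded by 1;
  comparisons across networks of different spatial scale should use binary
  mode or a common normalisation.
* The angle-population calibration targets the *mean* of each measured
  population; the realised SDs are mildly narrowed by the feasibility
  projection (a property of any generator honouring the closure
  constraint).
* `files` mode ingests fiducial CSV + edge lists and PLY/OBJ/ascii-STL
  meshes only; confocal stacks and their preprocessing are out of scope.
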