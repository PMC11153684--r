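---
title: "From chest CT to metastasis colonization heatmaps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From chest CT to metastasis colonization heatmaps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungmetmap)
```

## The problem

Small lung metastases (below roughly 2 mm) are routinely missed on CT and
PET-CT, yet their location drives treatment choices. `lungmetmap` turns a 3D
chest CT volume into a probability map of where circulating tumor cells shed
by a known primary tumor are most likely to colonize the lungs. The map is
not a detector: it is a biophysical forward simulation, conditioned on the
patient's own vascular geometry, of where seeding is feasible within a
chosen time horizon.

The pipeline has three layers:

1. **Initial condition construction** (computer vision): primary tumor
   location and size, a binary healthy-tissue lung mask, and a flow graph of
   cylinder-approximated blood vessels extracted from the image.
2. **Biophysical transport model**: tumor growth to vessel contact, cell
   shedding, bloodstream transport with exponential decay and an extinction
   threshold, and saturating colonization of the tissue around the arrival
   site.
3. **Heatmap generation**: the model evaluated on a uniform spatial grid and
   L1-normalized into a probability field.

Because clinical cohorts with longitudinal metastasis annotations are not
generally shareable, the package ships a phantom generator producing
CT-like volumes with exact ground truth; every stage is tested against it.

## Vessel segments and the flow graph

A vessel segment is the cylinder `b = (c, h, r, o_xy, o_xz)`: center of mass
`c`, height `h`, average radius `r`, and two orientation angles. Its start
and end points derive from the direction vector

```
u = ( cos(o_xy), cos(pi/4 - o_xy), cos(o_xz) ),    sl = c - h/2 u,   el = c + h/2 u.
```

This convention is adopted verbatim as the package's segment
parameterization, with two consequences worth stating plainly. First, `u` is
not a unit vector, so the Euclidean span `||el - sl||` equals `h * ||u||`
rather than `h`; all internal geometry (graph gaps, path lengths, flow edge
lengths) uses the derived endpoints consistently, so no unit mismatch
arises. Second, the family of representable directions does not cover the
sphere — a pure-z direction has no exact parameterization. The phantom
generator therefore samples orientations in angle space (every synthetic
vessel is representable by construction), and the detector's fitting step
inverts the endpoint formula exactly in x and y, clamping `o_xz` in the rare
unrepresentable case.

The graph `G = (B, E)` is built by an iterative search radius: segments are
sorted by height, and in each round a segment whose start lies within radius
`R` of another segment's endpoint is linked to the closest such segment it
is not yet linked to; if a round adds nothing, `R` grows by `delta_R`
(defaults `R0 = 2` mm, `delta_R = 1` mm, both user-settable). Construction
halts as soon as the graph is connected, the cardiovascular system being
connected by assumption. The "not yet linked" qualifier is a deliberate
reading: linking strictly to the single closest endpoint every round can
orphan mutually-closest pairs forever and the halting condition would be
unreachable. Distances within 1e-9 mm are treated as ties (resolved toward
the lower, i.e. taller-segment, id); exact endpoint coincidences at branch
junctions would otherwise be broken by floating-point noise.

The graph is then reduced to its **maximum-radius spanning tree**. The
"radius" of an edge is taken as `min(r_i, r_j)` — the hemodynamically
limiting bore of the connection — and Kruskal's algorithm with a
deterministic tie-break (smaller node index pair) maximizes the total. On
the spanning tree every source-target pair has a unique path, which is what
the heatmap stage evaluates.

## Vessel detection

The detector is a deliberately simple stand-in with the interface of a full
cylinder-detection method: threshold bright voxels inside the lung mask,
split into 26-connected components, extract a centerline per component by
geodesic binning (BFS depth from a farthest endpoint, quantized into bins,
clustered within bins, clusters linked across bins), cut the centerline
graph at degree-3+ clusters, and fit a cylinder per arc. The fitted radius
is `1.5 x` the mean perpendicular distance of member voxels to the principal
axis: for a solid cylinder the raw mean is `2R/3`, so the factor restores an
unbiased estimate of `R`. The centerline length is the projected extent of
the member voxels (extended by adjacent junction centroids, which otherwise
swallow the ends of every arc at a bifurcation).

Limitations stated openly: stubby branches whose length is within a couple
of radii of a junction merge into their parent's arc, so deep trees are
recovered with fewer, longer segments than generated. Topology recovery from
voxel data is well-posed only for well-separated branches; on the phantom's
ground-truth segment set the graph construction provably recovers every
parent-child edge (child starts coincide with parent ends at distance zero,
and the tie-break prefers the taller parent).

## Lung segmentation

Axial slices are processed independently and re-stacked:

1. **Adaptive Canny** edges with hysteresis thresholds tied to the slice's
   intensity median, `low = (1 - k) median`, `high = (1 + k) median`
   (`k = 0.33` default). A constant slice yields no edges.
2. **Two-ellipse Hough search.** For every candidate semi-axis pair, an
   elliptical ring kernel is correlated with the (1-px dilated) edge map via
   FFT convolution, scoring all centers at once; a candidate's score is the
   fraction of its perimeter supported by edges. Among candidates within a
   small slack of the best score, the largest-area ellipse wins — tiny rings
   over clutter trivially reach full support, while the lung boundary is the
   largest consistent model. The two picks (center-separated by at least
   `a1 + 2` px) are then refined against the raw edges by a local parameter
   search, which removes the +/-1 px bias the dilation tolerance would
   otherwise leave. Ellipses are axis-aligned; per-slice lung cross-sections
   are close enough to axis-aligned that rotation adds cost without benefit
   on this data.
3. **Contour closure**: edge components touching each ellipse's rasterized
   ring are accreted; the union is morphologically closed with growing disc
   radii (starting at none — an already-closed contour fills directly) until
   filling succeeds. The filled interior is the healthy-tissue region.
4. **Reconstruction**: slices stack along z (the conventional CT acquisition
   axis); failed slices are interpolated from their nearest successful
   neighbor and logged; the binary field is Laplacian-smoothed (each voxel
   moved toward its 6-neighbor mean, weight 0.5, 10 iterations) and
   re-binarized at 0.5.

The per-slice search is tracked from the middle slice outward, reusing the
previous slice's parameters within a +/-4 px window with a full-range
fallback, which keeps a 64-slice volume around ten seconds. Detected tumor
voxels are carved out of the mask: settlement targets must be healthy
tissue.

## The biophysical model

For a query location `tau` the settled cell count is composed as:

1. **Growth to contact.** Gompertz growth
   `N(t) = K exp( log(N0/K) e^{-a t} )`, with `N0` from the tumor radius at
   density `cells_per_mm3`; the contact time is found by bisection (to
   1e-6 h) on the equivalent radius against the distance to the nearest
   vessel surface. An unreachable vessel (carrying-capacity radius too
   small) is an explicit "never" sentinel that zeroes everything downstream.
2. **Shedding.** Once in contact, cells shed at rate `d`:
   `N_in = d * max(0, T - t_contact)` for stop time `T` (batch release at
   the source; whether shedding continues during transit is a genuinely
   open modeling choice, and batch is the simpler deterministic one).
3. **Transport.** A steady Poiseuille network stands in for graph
   Navier-Stokes (which is expensive and unstable at this scale): edge
   conductance `r^4 / L`, unit pressure at the inlet (largest-radius
   segment), zero at leaves, mass conserved at interior nodes. Pressures are
   in arbitrary units, so the one physical anchor is the inlet mean velocity,
   pinned to `root_velocity` (default 100 mm/s, a pulmonary-artery scale).
   Transit time along the unique tree path gives
   `N_out = N_in e^{-lambda t}`; if `N_out < xi` the population is extinct.
   The threshold implicitly defines the maximal survivable path length
   `nu_t = log(N_in/xi)/lambda` in transit-time units — `nu` is derived, not
   set independently.
4. **Colonization.** With `f` the healthy-tissue fraction of a
   `colonize_radius` ball around `tau` (zero if `tau` itself is not lung),
   the settled count is
   `round( cap * f * (1 - e^{-p N_out / cap}) )` — monotone in arrivals,
   saturating at `cap * f`, zero without tissue.

All semantics are expected-value: the probabilistic extravasation step is
realized as an expected settled count so the heatmap is deterministic and
exactly testable.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `d` | 1e6 | cells/h | shedding rate at the primary tumor |
| `lambda_decay` | 2 | 1/h | circulating-cell death rate |
| `xi` | 100 | cells | extinction threshold |
| `T` | 720 | h | stop time (30 days) |
| `growth_a` | 0.005 | 1/h | Gompertz rate |
| `growth_K` | 1e12 | cells | carrying capacity (~1 kg) |
| `cells_per_mm3` | 1e6 | cells/mm^3 | volume-to-count conversion |
| `p_extravasate` | 1e-3 | — | extravasation probability scale |
| `colonization_capacity` | 1e7 | cells | local settlement saturation |
| `colonize_radius` | 5 | mm | tissue-fraction ball |
| `root_velocity` | 100 | mm/s | inlet velocity anchor |

None of these is constrained by clinical data shipped with the package; they
were chosen once for physiological plausibility (extravasation is a
low-efficiency event, hence a small `p` keeping colonization in its
near-linear regime; circulating tumor cell half-lives of the order of
hours justify `lambda` around 2/h) and are exposed in the `biophysics:`
config block. Every run's manifest records the full parameter set.

## Heatmap generation

The volume is sampled with a grid of strides `alpha = (a_x, a_y, a_z)`
voxels (default 4 each). Grid points outside the lung mask are assigned 0
without model evaluation; the rest get the settled count at stop time `T`
along their unique tree path, and the vector of counts is L1-normalized into
probabilities. Per-point evaluations share a cache (flow field, contact
time, BFS parents, cumulative transit times accumulated in path order) that
is arithmetic-identical to evaluating each point independently — a property
the tests assert bitwise. If every count is zero the map is returned
unnormalized with a warning rather than inventing a distribution.

## Scoring

Validation against a binary truth image `I1` uses the soft classifier
`d_s(I1, I2) = 1 - mean((I1 - I2)^2)` and the hard classifier
`d_h(I1, I2, zeta) = d_s(I1, I2|zeta)`, where the prediction is binarized by
a strict `> zeta`. `d_h` is piecewise-constant in `zeta` with breakpoints
exactly at the prediction's distinct values. The default `zeta` is the
uniform baseline `1/|grid|`; cohort summaries report mean and sample (n-1)
standard deviation. For phantom scoring the point-like truth is dilated by
one voxel to absorb rasterization error (configurable).

## The phantom and what passing tests do and do not show

The generator emulates: two ellipsoidal lungs, a binary branching cylinder
tree grown inside one lung (child radii by the Murray-style closure
`n r_child^e = r_parent^e`, default exponent 3; heights shrinking by 0.75;
branch angles perturbed within a configured range with containment
steering), a spherical primary tumor beside the vessel root, four-level
piecewise-constant intensities (background 0.1, lung 0.3, vessel 0.7, tumor
0.9) with additive Gaussian noise, and metastasis ground truth planted near
distal leaf endpoints weighted by vessel radius. Cylinders are rasterized
flat-capped — a vessel continues into its neighbor rather than ending in a
hemispherical cap, and caps would bias fitted lengths by about `2r`.
Metastasis masks are truth only, not painted into the intensities: the
scenario is a scan taken before the metastases are visible.

Two couplings are declared openly. Radius-weighted distal placement makes
the planted truth correlated with what the transport model predicts — that
is the point (it lets end-to-end localization be tested at all), but it
means a passing localization test shows internal consistency, not clinical
validity. And the phantom's geometry is far simpler than real anatomy: no
airways, no mediastinum, piecewise-constant intensities, axis-aligned
ellipsoid lungs. Passing tests demonstrate the algorithms do what their
contracts say on geometry they can represent; they say nothing about
performance on patient data.

A known limitation the test suite surfaces honestly: with physiological
flow velocities, transit decay across a lung-sized tree is of order 1e-3,
so the extinction threshold never differentiates reachable sites, and the
heatmap over interior lung tissue is dominated by the local tissue fraction
(lower near the pleural boundary). Planted metastases sit subpleurally —
realistically — where the colonization ball clips the boundary, so their
mean heatmap percentile lands near 70 rather than above 80. Sharpening this
would require either a vessel-distance-dependent colonization term or
flow-split dilution at bifurcations, both outside the present model's
contracts and listed as future work.

## Numerical choices

* Grid/tie determinism: candidate scans and tie-breaks are ordered (lowest
  id, smallest parameter change first), so every stage is bit-reproducible
  under a fixed seed; the pipeline manifest hashes its artifacts to make
  this checkable.
* Endpoint-coincidence ties in graph building use a 1e-9 mm tolerance; the
  cross-distance matrix is computed by direct differencing because the
  expanded quadratic form loses ~8 digits to cancellation exactly where it
  matters (coincident endpoints).
* Bisection for contact time runs to 1e-6 h after doubling a bracket; the
  Poiseuille system is solved densely (trees here have tens of nodes).
* Degenerate inputs have defined behavior: constant slices give empty edge
  maps; empty vessel masks give an empty detection (message, not error); a
  single-segment graph is trivially connected; all-zero heatmaps are
  returned unnormalized with a warning; zero-velocity edges give infinite
  transit and extinction.
* Problem sizes in the shipped tests — 64^3 phantoms, tens of segments,
  grids of a few thousand points, cohorts of 5-20 phantoms — were chosen as
  the smallest sizes at which every contract is exercised meaningfully.

## Known limitations and future work

Beyond the flat-heatmap issue above: no artery/vein separation; no
airway or lobe segmentation; rotation-free per-slice ellipses; batch (not
continuous) shedding; no mutation, immune interaction, or pulsatile flow.
Each stand-in (growth, flow, colonization, tumor detection, vessel
detection) sits behind a small interface so a faithful model can be swapped
in without touching the rest of the pipeline.
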