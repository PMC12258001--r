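---
title: "Methods: delivery-time modeling and CSG post-processing for collimated proton arcs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delivery-time modeling and CSG post-processing for collimated proton arcs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`csgarc` models and shortens the delivery of dynamically collimated
step-and-shoot proton arc (DC-PAT) plans. This vignette is the package's
account of the underlying models, the choices made where the design was
genuinely open, and what the shipped tests do and do not demonstrate.

## Plan model

A plan is an ordered sequence of control points on a single arc. Each
control point carries exactly one energy layer, a set of spots (monitor
units, beam's-eye-view positions at isocenter) and a set of trimmer
configurations in delivery order; each spot references the configuration
that collimates it. Trimmer positions are signed medial-edge distances from
the beam central axis per bar (mm, beam's-eye view): positive retracts the
bar away from the axis, 65 mm is the fully retracted "off" state, and
−20 mm is a permissive over-travel floor (configurable; the hardware bound
is not published). Gantry angles are IEC degrees in [−180, 180], strictly
monotone in delivery order; an arc designed with `n` inclusive positions
over 360° has resolution `360/(n−1)` — the reference design of 129
positions gives 2.8125°, reported at one decimal as 2.8°. Spots below
0.025 MU are not deliverable; `remove_low_mu_spots()` drops them and any
control point they leave empty, and plan validation enforces the floor.

Plans serialize to a canonical JSON document (fixed key order, full float
precision) so that write–read–write is byte-stable; machine parameters read
from YAML or JSON.

## Beam delivery time

All delivery events are treated as strictly sequential, which is how the
present DCS integration operates (no trimmer motion during scanning, energy
switching only after the gantry settles): per control point, an energy
switch, then alternating trimmer moves and spot bursts; between control
points, a rest-to-rest gantry move. Consequences of this model worth
noting:

* the first control point is charged no energy switch, and trimmers start
  from the off state;
* equal consecutive energies cost nothing (a no-op switch takes no time);
* removing a control point merges its two gantry moves into one longer
  move, which is never slower than the two stop-and-go moves (the
  rest-to-rest profile is concave in distance).

Parameters (`machine_model()`): gantry `v_max` 6 deg/s and `a_max`
0.6 deg/s²; spot slope 6.6 ms/MU and slew 2.2 ms; energy switch 6 s up /
0.8 s down; trimmer travel time `c0 + c1·d + c2·d²` seconds for `d` mm of
travel. The default coefficients (0.3, 0.008, 2e-5) are a documented
configuration choice sized so a full 65 mm throw pauses ≈ 0.9 s; the fitted
coefficients of the reference delivery system are not published, so any
quantitative trimmer-time claim in this package is relative, not absolute.
Travel distance defaults to the `max_bar` metric (bars move simultaneously,
the slowest gates the pause); `sum_bars` is available for sensitivity
studies. The manual-intervention model for fixed-beam comparisons charges
30 s per beam transition plus 120 s per couch change.

## SWELS

Sliding-Window Energy Layer Sorting re-sorts the one-energy-per-control-
point sequence toward descending order (fast, 0.8 s downward switches)
inside a window of `⌊window_deg/resolution_deg⌋` consecutive control
points. The window grows from one index to capacity, re-sorting its
contents descending at each step, then slides one index at a time. When the
energy entering at the window's last index exceeds the one at its first
index, the window jumps so the last index becomes the new first index (the
stop condition) and regrows. One left-to-right pass is made; ties keep
their order and never trigger the jump.

Two properties are guaranteed and property-tested over 1000 random
sequences: the energy multiset is preserved, and no layer is displaced by
`capacity` or more positions. The displacement guarantee requires care: a
naive slide-and-resort drags small energies rightward indefinitely (a
window minimum is re-sorted to the window's end at every slide), so each
layer carries a displacement deadline and the within-window sort pins a
layer in place once any further right-move would break the bound. Pinning
has a cost: re-running the sorter on its own output can move a previously
pinned layer further (its deadline is reset), so the pass is *not* an exact
fixed point on arbitrary input. We consider the displacement bound the
load-bearing property — it is what keeps a layer's beam angle close to the
one it was optimized for — and accept approximate idempotence: re-applying
the sorter never increases up-jumps and never breaks the bound, and on
sequences that fit within one window (where no pinning can occur) it is an
exact fixed point. Both facets are tested.

Layers move whole: spots and configurations follow their energy to the new
gantry angle. Because a remapped layer's spot lattice was optimized for a
different angle, the pipeline regenerates lattices and reoptimizes weights
after sorting (below).

## Grouping

The Group stage reduces the number of unique trimmer configurations.
A spot is *effectively uncollimated* when every bar edge is at least
`mult·sigma` (default 3 × 3.2 mm, inclusive) from the spot centre on its
side; all such spots pool under one off configuration per control point.
Collimated spots are clustered agglomeratively: each starts as a singleton
with its own configuration, and the pair of groups whose merged envelope
(per-bar maximum — the least-collimating member position, so no spot is
ever clipped tighter than its plan intended) increases the total aperture
relaxation least is merged until the mean group size reaches the target.
The clustering rule is this package's gap-fill — only the target-size knob
is prescribed by the method being implemented — and a spatial-chunking
`greedy` fallback is selectable for tests.

Configuration visit order is an open travelling-salesman path from the
trimmer state the control point is entered with, threaded across control
points (the off state before the first). Instances of ≤ 6 configurations
are sequenced exhaustively; larger ones by an elitist ant colony system:
visibility `1/(ε + move time)`, pheromone weight α = 1, visibility weight
β = 2, evaporation ρ = 0.1, deposit `Q/cost` by the best-so-far ant,
defaults 20 ants × 200 iterations, seed mandatory. On ≤ 6-configuration
instances the colony reproduces the exhaustive optimum across 50 seeded
cases in the test suite.

Grouping must never cost time: when traversing the original per-spot
configurations from the arriving state is already cheaper than the grouped
sequence (which can happen on adversarial inputs — envelope relaxation can
move a shared configuration away from its neighbours), the control point is
left untouched. This is the efficiency plateau in miniature: beyond some
group size, merging stops paying. Spot identities, positions and weights
are never altered by grouping; only apertures relax, which is why the
pipeline re-evaluates dose afterwards.

## Dose engine

The engine is an analytic collimated pencil-beam model on a 3 mm isotropic
grid — a stand-in for a commissioned dose engine, adequate for exercising
collimation and sequencing trade-offs but making no absolute dosimetric
claims. Components:

* range from energy by the Bragg–Kleeman law `R = 0.0022·E^1.77` (cm, MeV),
  strictly increasing, so ordering by energy and by range coincide;
* depth dose: an entrance plateau (0.3 relative amplitude) with an
  error-function distal fall-off plus a unit-amplitude Gaussian Bragg peak
  of width `max(1.5 mm, 0.012·R)` (straggling grows with range);
* lateral profile: a 2D Gaussian of depth-dependent sigma
  `sqrt(3.2² + (0.025·z)²)` mm (3.2 mm is the median dedicated-nozzle spot
  size; 0.025 a documented scattering constant), truncated by the four
  trimmer edges. Voxel values are per-axis voxel-integrated
  (error-function) factors, so a bar edge on the spot axis halves the
  lateral integral exactly, the off configuration reproduces the open beam,
  and closing any bar can only remove fluence;
* water-equivalent depth by ray marching the density grid at grid
  resolution; beams are parallel (no divergence), the gantry rotates in the
  axial plane about the phantom's superior–inferior axis;
* collimator edges are ideal (no transmission, no thickness penumbra),
  modeled at the isocenter plane;
* dose calibration: 1 Gy/MU nominal Bragg-peak dose for an unclipped spot,
  chosen once so optimized spot weights land in the clinical 1–100 MU
  range where the 0.025 MU deliverability floor occasionally binds, as it
  does in practice.

Sparse influence columns drop entries below `1e-4` of the *uncollimated*
beamlet's peak voxel value. The floor is absolute per spot rather than
relative to the clipped column so that sparsification preserves collimation
monotonicity (a relative floor would retain voxels in a tight beam that the
open beam dropped).

DVH indices follow the standard definitions: `D_q` is the smallest dose
received by at least `q`% of a structure; `HI = (D2 − D98)/Dp`;
`CI = (TV_PIV/TV)·(TV_PIV/V100)`; `GI = V50/V100` with both volumes over
the whole scored grid (whether the published indices use the external
contour instead is not stated; reports note the choice). When no voxel
reaches the prescription, CI and GI are reported as `NA` rather than
extrapolated. Plans are normalized so the PTV `D95%` equals the
prescription (50 Gy by default).

## Spot-weight reoptimization and the pipeline

The reoptimizer minimizes a convex weighted sum of per-structure quadratic
terms — uniform target dose, one-sided overdose on the 10 mm rind, and a
mean-dose penalty per organ at risk — over nonnegative monitor units, by
projected gradient descent with Barzilai–Borwein step lengths and a
monotone backtracking safeguard (the objective never increases).
Convergence is declared when the relative objective decrease stays below
`1e-6` for three consecutive iterations (BB step lengths oscillate, so a
single small decrease is not evidence of convergence), or at 400
iterations. On ≤ 20-spot instances the solution matches a box-constrained
quasi-Newton oracle to 1e-4 in objective. After every solve the 0.025 MU
floor is re-applied and emptied control points dropped.

The pipeline runs Cut → reoptimize → Sort → regenerate lattices +
reoptimize → Group → renormalize, i.e. trimmer positions are not
reoptimized after grouping — the grouping itself discovers the relaxed
apertures — and each active stage ends with a `D95%` renormalization.
Stages that cannot change the plan under their parameters (zero cut
threshold, window below the resolution, group size one with no
uncollimated spots) are skipped, so neutral parameters compose to the
identity; the Cut threshold is a single fixed pass at 30% rather than an
iterative quality-guided removal.

## Robustness analysis

Delivery uncertainties only (patient setup is deliberately excluded — it is
managed by image guidance, not the delivery system): proton range scaling
(3.5% two-sided 95th percentile, so Gaussian σ = 3.5/1.96 % in the default
`sampled` mode; a fixed ±3.5% alternating pair in `systematic` mode — the
published wording supports either reading, so both are provided), per-spot
Gaussian position noise (σ = 0.5 mm), per-control-point uniform gantry
offsets (±1°), one systematic DCS mount shift per scenario (σ = 0.05 mm in
IEC X, 0.1 mm in IEC Y) and per-bar trimmer noise (σ = 0.3 mm, per
configuration). Each of the `n_samples` (default 100) scenarios is fully
determined by the model seed and the scenario index, independent of
evaluation order. The identity scenario reproduces the nominal dose
bit-for-bit, which anchors the whole analysis in the tests. Outputs are
per-structure tables of mean(sample − nominal) and SD for D2/D50/D98/Dmean
plus DVH band curves.

## Synthetic study conditions

The generator replaces patient CT data and the genetic baseline optimizer:
a spherical water phantom with an ellipsoidal PTV, a CTV (PTV eroded 3 mm),
a 10 mm rind and an adjacent spherical OAR; a single clockwise 360° arc
with inclusive endpoints; 3 mm spot lattices covering the target's
beam's-eye-view projection with a 6 mm expansion; out-of-target spots
trimmed at 0 mm offset by the bar(s) on their outward side, in-target spots
uncollimated; weights from the quadratic optimizer; the MU floor and `D95%`
normalization applied. Energy per angle comes from a round-robin heuristic
over the target's radiological depth extent (five slabs, seed-jittered) —
deliberately *not* a reproduction of the genetic selection, but it produces
the realistically non-monotone energy sequences the Sort stage needs.
Default scene: 170 mm phantom radius, 20/15/25 mm PTV semi-axes, 129
positions.

What the generator does not emulate — and hence what passing tests do not
show about clinical data: heterogeneous anatomy (water only), realistic
organ geometry, optimizer-specific weight distributions, nozzle-specific
spot-size energy dependence, and absolute trimmer-time calibration.

The test suites run a scaled-down scene chosen once: 33 mm phantom,
7/6/8 mm PTV semi-axes, 13-position arcs, SWELS window of twice the
resolution, mean group size 6, 20 seeds for the end-to-end property. The
window choice deserves a note: the published sweet-spot window (25° on a
2.8° arc) spans ~6% of the arc's positions, so *any* non-trivial window on
a 30°-resolution arc is already more aggressive than the published regime;
twice the resolution is the least aggressive capacity at which sorting
acts. The end-to-end property asserts that total delivery time strictly
decreases and that PTV D98 does not fall more than 2% below baseline after
renormalization. The bound is one-sided by design: on desk-scale plans the
pipeline's reoptimization sometimes *improves* D98 by more than 2% when
the baseline left residual cold spots, and flagging recovered coverage as
a failure would invert the property's meaning.

## Known limitations

* Dynamic (moving-gantry) arcs, concurrent trimmer motion and
  beam-current modeling are out of scope; the BDT model is conservative by
  construction.
* The dose engine is qualitative: no nuclear halo, no heterogeneity
  corrections beyond water-equivalent density, ideal collimator edges.
* SWELS is a single pass and only approximately idempotent (see above).
* The ant colony sequencer is heuristic for > 6 configurations; optimality
  is only guaranteed where exhaustive search takes over.
* Robust *optimization* is not provided — only robustness *evaluation* of
  fixed plans.
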