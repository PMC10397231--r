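---
title: "From a single fundus image to 3D vascular hemodynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a single fundus image to 3D vascular hemodynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fundus3d` turns one colour fundus photograph into (i) a vessel
segmentation, (ii) a centerline graph with per-point radii, (iii) a
triangulated 3D vessel surface, (iv) a reduced-order pulsatile flow
solution over the vascular tree, and (v) hemodynamic features for binary
disease classification. This vignette explains the models behind each
stage, the parameters that matter, the numerical decisions taken where the
design was genuinely open, and what the synthetic test bed does and does
not establish.

## The core modelling assumption

A single image supplies no depth. The package's 3D model therefore rests on
one explicit convention: the extracted centerline network lies flat in the
image plane (z = 0) and every vessel cross-section is a circle orthogonal
to the local centerline tangent. All three-dimensionality of the surface
model comes from those circular cross-sections. This is adequate for the
optic-disc region over the short physical depths involved, and it is the
assumption to revisit first if the package is applied to strongly curved
retinal geometry.

A second global convention: pixel coordinates are (row, col), 0-based, with
integer coordinates at pixel centers. Physical scale enters only through
`px_size` (cm per pixel). No imaging-hardware default is defensible, so
`px_size` is a required configuration item; the examples use 1e-3 cm
(10 µm), the right order of magnitude for fundus photography of the disc
region.

## Channel fusion and the proportion search

Vessel contrast concentrates in the green channel, with a weaker copy in
red; blue is noise-dominated and ignored. The working image is
`g·G + (1-g)·R`, kept floating point (no requantization) so no precision is
lost before segmentation. The proportion search is hill-climbing on the
lattice `g ± i·0.01`: the radius `i` expands while the best neighbour at
the current radius improves the incumbent and stops after one non-improving
radius. Two open choices were closed as follows: weights stepping outside
[0, 1] are *clipped* (not renormalized), and score ties keep the incumbent
nearest the start, so a flat score surface returns the starting proportion.

## Segmentation

Two segmenters share one probability-map interface.

**DenseBlock-Unet.** An encoder–decoder with 2-convolution dense blocks:
each block layer is conv 3×3 → batch normalization → ReLU, the second
convolution receives the concatenation of the block input and the first
layer's output, and the block emits the concatenation of both layer
outputs. Downsampling is 2×2 max pooling, upsampling is a 2×2 stride-2
transposed convolution followed by an encoder-to-decoder skip
concatenation, and a 1×1 convolution plus sigmoid ends the network. Depth,
base width, learning rate, patch size, batch size and epochs are all
configurable (defaults: depth 4, base 16, Adam at 1e-3, 32-px patches);
block widths double per level — a standard choice, since published block
diagrams rarely pin down widths. The implementation (forward and backward)
is written in plain R and verified against finite differences in the test
suite; training is patch-based with half the patches re-centred on vessel
pixels so thin structures are not swamped by background, and it is
deterministic given the seed. Inference pads to a multiple of 2^depth and
runs on batch-norm running statistics.

**Hessian vesselness.** A non-learned fallback: per scale σ ∈ {1.5, 2.5, 4}
px, the γ-normalized (σ²-scaled) image Hessian's eigenvalues score dark
ridges Frangi-style; the maximum over scales, normalized to [0, 1], is the
vessel score. This decouples the geometric pipeline from training entirely
and is the pipeline default. Binarization is hysteresis (strong 0.4, weak
0.05 of the score range): strong seeds grow through weak 8-neighbours,
which recovers the full vessel width from a ridge-shaped response.

Metrics are the pixel-classification counts (ACC, SE, SP) at a threshold,
and a threshold-free AUC computed as the midrank statistic (ties counted
half), which the tests validate against a brute-force concordant-pair
count. In the leave-one-out harness each image is scored by a model that
never saw it; the fold structure is recorded so the contract is testable.

## Skeleton graph

Thinning is classic two-subiteration Zhang-Suen (corrode while the
8-neighbour count is in [2, 6], the cyclic neighbour sequence has exactly
one 0→1 transition, and the pass-specific directional products vanish),
iterated to a fixed point. The result is idempotent, contained in the mask,
and preserves the 8-connected component count — all property-tested on
random blob masks.

Node classification follows the 3×3 neighbour count: 1 neighbour →
endpoint, 2 → path interior, ≥3 → intersection. Two consequences of that
rule deserve note. First, junction pixels cluster (several adjacent pixels
count ≥3); clusters are merged into a single node at their centroid.
Second, sharp 1-px corners and staircase bends also produce counts of 3 —
the rule genuinely classifies them as intersections. The pipeline tolerates
the resulting degree-2 "junction" nodes (they merely split segments, which
the hemodynamic solver composes in series anyway), and the unit fixtures
use chamfered corners where a hand count is meant to be unambiguous.

Tracing walks from node pixels along unvisited interior pixels, preferring
termination at an adjacent node but never the origin node on the very first
step (junction clusters touch their branches' first pixels), and choosing
the straightest continuation when two branches run diagonally adjacent. A
node-free cycle gets one synthetic "break" node and is traced as a single
closed segment. Short dead-end twigs below a length threshold (default
6 px), which thinning grows at junctions under mask noise, are pruned.

Centerline downsampling keeps every interval-th point plus the last. The
default interval is adaptive — the ceiling of the locally measured radius —
so that the spacing between cross-section contours exceeds what their radii
can bridge; a fixed interval is available in the configuration.

## Radius profiling

Edges come from a standard Canny (Gaussian blur σ = 1, Sobel gradients,
non-maximum suppression, hysteresis at 0.1/0.2 of the gradient range),
run by default on the binary mask rather than the grayscale: boundary
localization then cannot be corrupted by illumination texture. Two
numerical details matter for sub-half-pixel accuracy:

* An ideal step edge responds identically on both flanking pixels; which
  one survives non-maximum suppression would otherwise be decided by
  floating-point summation noise and differ between orientations. The
  suppression is therefore strict against the +offset neighbour and
  non-strict against the other (after quantizing magnitudes to 9 digits),
  so exactly one deterministic pixel survives — and across a tube the two
  walls resolve to *opposite* sides, cancelling the half-pixel bias in the
  two-sided radius average.
* The radius at a point is the mean of the first corridor hits (±1 px of
  the ray) marching both ways along the local normal; when a wall yields
  two hits within ~1 px (a residual plateau or staircase), their midpoint
  is used. One-sided hits are kept but flagged; points with no hit within
  `max_search` (default 15 px) are dropped, and segments reduced below two
  valid points are removed.

Tangents are least-squares line fits over ±window points (default 3, or the
sampling interval if larger); normals are tangents rotated 90°. On straight
and curved synthetic tubes with radii 2–10 px the recovery RMSE is about
0.3 px, within the 0.5 px the package commits to, and a 90° image rotation
reproduces radii exactly.

## Surface construction

Each profiled segment gets a ring of `n_pts` vertices (default 24) per
sampled point, oriented by parallel transport of the first ring's frame —
not a Frenet frame, which flips and twists at inflection points of planar
curves. Rings that would interpenetrate (possible only where the bend
radius approaches the tube radius) are dropped — a local re-downsampling —
with segment endpoints always retained. Lofting joins ring i vertex j to
ring i+1 vertices {j, j+1}, giving 2·n_pts·(k−1) wall triangles.

At junctions, the adjacent end-contour radii are compared; while max/min
exceeds the repair threshold (default 1.5) the most protruding radius (the
largest log-deviation from the junction median) is pulled minimally toward
the median until the ratio holds. Tube ends at a junction are then bridged
by triangle fans to the shared junction-node vertex, free ends are capped,
and a junction-local Laplacian smoothing (v ← v + λ(centroid − v), λ = 0.5,
3 iterations, vertices within 3 edge hops of a junction fan) irons the
bridged region. The result has no boundary edges anywhere, positive
enclosed volume, and — for a single capped tube — Euler characteristic 2;
smoothing never changes vertex or triangle counts. The 1.5 repair threshold
is a package choice: "too large a radius difference" has no canonical
value, and the threshold is exposed in the configuration (∞ disables
adjustment).

## Mesh quality

The four indicators are anchored so an equilateral triangle scores
(1, 1, 60°, 0): element quality `4√3·A/Σl²`; aspect ratio as circumradius
over twice the inradius (verbal definitions of this indicator in simulation
suites are notoriously garbled — the anchor values pin the formula);
maximum interior angle; and skewness as the normalized equiangular
deviation `max((θmax−60)/120, (60−θmin)/60)` (the equiangular rather than
equal-volume variant, chosen for being exact on triangles). All four are
rigid-motion and scale invariant, property-tested over random triangles.
Aggregation reports mean ± sd over wall triangles; caps and junction fans
are excluded by default since their shape is dictated by bridging, not
meshing quality.

## Reduced-order hemodynamics

Full 3D CFD is out of scope by design; the solver is a quasi-static
Poiseuille network. Each vessel segment becomes a resistor
`R = 8μL/(πr⁴)` (L = polyline length, r = median measured radius, both in
cm; μ = 0.035 dyn·s/cm², whole blood). At each of T time steps (default 32
over a 1 s period) the nodal pressures solve the linear Kirchhoff system
with the inlet flow prescribed by a half-sine pulse (midpoint-sampled, a
single interior maximum mimicking systole) and outlet gauge pressures fixed
at 0. The inlet defaults to the degree-1 node with the thickest adjacent
vessel — the root in any tree-shaped network. The solver conserves mass at
every junction to solver precision (≤ 1e-9 relative, verified against an
independently formulated dense solve in the tests), and the assumptions
worth naming are: laminar fully-developed Newtonian flow, rigid walls, no
inertia or compliance (each step is an independent steady state).

Features are emitted in a fixed documented order: per-face flow and
pressure series, per-face mean/max/min of each, then `Qmax_Time` (time of
the across-face mean-flow maximum; ties broken to the earliest step),
`Qmax_Time_from_cm` (the same statistic after converting flow to L/min),
and `Step_k_mean` for every step. The series + summary block counts
`2FT + 6F`; a total of 140 features corresponds to F = 2
faces and T = 32 steps, but the decomposition is configuration, not an
assertion — any (F, T) works, and the derived features add T + 2 more.

## Feature selection and classification

The t-test filter keeps features with equal-variance two-sample p < 0.05
(constant features are excluded with a warning); its type-I behaviour is
calibrated in the tests (null selection rate 0.05 ± 0.02 across 100 seeded
cohorts). The F-test scan iterates p-value thresholds 0.001–0.10 in steps
of 0.001 (the grid is a package choice, exposed as an argument), scoring
each distinct subset by LOOCV accuracy of the chosen classifier; ties
prefer the smaller subset, then the smaller threshold. For two classes
F = t², so both filters rank features identically — they are kept as two
procedures because they select differently (fixed α versus
accuracy-optimized threshold). Best-first search is a forward wrapper with
a priority queue over subsets, patience-limited, deterministic under the
fixed feature order; the tests verify it against exhaustive subset
enumeration on a four-feature problem whose only perfect separator is a
specific pair.

Two evaluation protocols are provided and logged: *flat* (select on all
subjects, then LOOCV — optimistically biased, but the standard small-cohort
protocol and the default) and *nested* (selection re-run inside every fold;
the honest generalization estimate). The headline accuracies the package
prints for its synthetic cohorts use the flat protocol; treat them as
training-protocol numbers, not generalization claims. Classifiers run with
library defaults, standardized inputs where the method needs it, and
per-fold reseeding for the stochastic ones.

## The synthetic test bed

The generator grows seeded planar binary trees of smooth piecewise-linear
segments (daughter radius = parent × decay, default 0.8; root radius 5 px;
two branching levels in a 128×128 image), rasterizes their capsule tube set
exactly into the ground-truth mask, and renders a reddish textured
background (Gaussian texture, sd 8) with vessels darkened by 70 intensity
units in green and 40% of that in red, softened by a 0.7 px blur. The
cohort experiment uses 20 subjects, half with all radii scaled ×0.7 — a
diffuse narrowing with a 1/0.7⁴ ≈ 4× resistance signature that the pressure
features carry clearly.

What the fixtures *do* establish: geometric recovery (skeleton topology,
radii to sub-pixel RMSE), mesh integrity, solver exactness, selection
calibration, and that the full pipeline separates a strong vascular
phenotype. What they do *not* establish: performance on real fundus
photographs — no optic disc, fovea, lesions, illumination gradients,
vessel tortuosity/caliber variation, or annotation noise are simulated, and
real-image segmentation accuracy would require training on real annotated
data. Desk-scale problem sizes are used throughout the tests (64–128 px
images, a depth-2/base-4 network trained for ~250 steps, 20-subject
cohorts); these are the package's chosen test conditions, and all sizes
scale up through the configuration.

## Known limitations

* Planar centerline + circular sections: no out-of-plane geometry, no
  elliptical lumina, no sub-pixel edge localization.
* The 3×3 neighbour-count rule mislabels sharp staircase corners as
  junctions (tolerated downstream, see above); crossing vessels are merged
  rather than resolved into overpassing branches, and arteries/veins are
  not distinguished.
* The 0D solver has no inertia, compliance, or non-Newtonian rheology;
  boundary values (outlet pressure 0, half-sine inlet) are idealized.
* The flat selection protocol is optimistically biased by construction;
  use the nested option for generalization estimates.
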