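---
title: "Methods: regularized montage stitching and 3D alignment at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regularized montage stitching and 3D alignment at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stitchforge)
```

## The stitching model

A serial-section EM acquisition images each physical section as a grid of
overlapping camera tiles. Stitching estimates, per tile, a 2D transform
from the tile's local pixel frame into a common section frame such that
point correspondences found in the overlap regions coincide. For a chosen
transform family (translation, affine, or second-order polynomial), each
correspondence between tiles $i$ and $j$ contributes one linear constraint
per axis, $T_i(p) - T_j(q) = 0$, written in the family's basis — $(x, y,
1)$ for affine, $(1, x, y, x^2, xy, y^2)$ for the polynomial. Stacking all
constraints gives a sparse matrix $A$ and the regularized least-squares
system

$$K\,t = L, \qquad K = A^\top W A + \Lambda, \qquad
  L = \Lambda t_0 + A^\top W b,$$

solved per axis by sparse Cholesky factorization. $W$ weights individual
correspondences, $b = 0$ for in-section montages, and the diagonal
$\Lambda$ pulls the solution toward its initialization $t_0$ — nominal
stage positions with identity linear parts, or a previous solve. The
regularization plays two roles: it fixes the gauge (without it, any global
affine applied to all tiles leaves the residual unchanged and $K$ is
singular), and it trades correspondence residual against tile distortion.

**Per-class regularization scaling.** The user-facing factors
`lambda_translation`, `lambda_linear`, `lambda_polynomial` are
dimensionless. Internally each parameter class is scaled by the mean
diagonal of $A^\top W A$ restricted to *its own* columns. A single global
scale would be dominated by the linear/quadratic columns, whose basis
entries are of order `tile_size`$^2$ and `tile_size`$^4$; the translation
factor would then be orders of magnitude stiffer than intended, which in
practice showed up as corrected-montage residuals pinned well above the
noise floor. With per-class scaling, `lambda_translation = 1e-5` is
genuinely soft (tiles move freely) while `lambda_linear = 1e3` keeps
linear parts near their initialization. Defaults: translation `1e-5`,
linear `1e3`, polynomial `1e5`, all relative.

**Residual metric.** The residual of a correspondence is the Euclidean
distance between its two mapped members. Pairs are summarized by their
mean, sections by the median of pair means. The stitching target adopted
throughout is a median residual of at most 5 px, with tile-scale MAD
(below) at most 0.005.

## Robust correspondence computation

Correspondence candidates come either from the geometric generator (the
default for speed and determinism — see below) or from images: a
difference-of-Gaussians keypoint ladder with descriptors sampled on a
rotated, scale-normalized patch grid and mean/sd-normalized for contrast
invariance, matched by nearest neighbor under a ratio test (default 0.92).
Candidates are filtered by a *locally optimized* RANSAC: hypotheses are
seeded from minimal samples as usual, but each hypothesis is refined by
alternating a full-inlier least-squares refit with an inlier-set update
until the set stabilizes; the largest stable set wins. The winner is then
trimmed by iteratively removing candidates whose residual magnitude
exceeds the mean plus three standard deviations of the residual
distribution under the refit transform, refitting after each pass. The
3-sigma rule uses residual magnitudes (not per-axis components), strict
inequality, and the $n-1$ standard-deviation denominator, so a degenerate
all-equal residual set removes nothing; trimming never drops the set below
the model's minimal sample size. Same-section consensus defaults to
affine; cross-section (low-scale) matching uses a similarity model to
tolerate section-level rotations.

## Lens-distortion estimation

The shared optical distortion of an acquisition system is estimated from a
high-overlap (≥ 0.4) calibration montage whose matches are kept in raw
(distorted) coordinates. The estimator alternates:

1. solve an affine montage on the currently corrected coordinates;
2. update a displacement field, parameterized by its values on a
   `grid_n` × `grid_n` node grid over the tile frame, by linearized least
   squares: perturbing the node displacements by $\delta$ changes each
   pair disagreement $v_k = T_q(\hat q_k) - T_p(\hat p_k)$ by
   approximately $(E(q_k) - E(p_k))\,\delta$, where $E$ is the
   interpolating-TPS evaluation operator over the nodes;
3. refit the interpolating TPS through the updated nodes.

Two identifiability issues shape the implementation, and both were
observed directly on synthetic calibration data before being addressed.
First, any *quadratic* component of the lens field can be absorbed
exactly by free per-tile affines (a quadratic's increment over a fixed
tile offset is affine in position), so most iterations run the inner
montage *stiff* (`lambda_stiff = 10` on the linear terms) to keep those
components observable, followed by a short *soft* phase
(`lambda_soft = 0.01`, one iteration) that lets tiles fit their own true
linear perturbations. Second, field components periodic in the tile pitch
are invisible to pair disagreements altogether; a grid-Laplacian
smoothness penalty on the *total* field (strength `smooth_beta = 1`
relative to the data term, applied to `disp + delta` so the alternation
cannot drift along unobservable directions) suppresses them without
biasing the smooth physical field appreciably. The returned TPS is
gauge-fixed to zero mean displacement and unit mean scale by removing the
best-fit affine of the node displacements — any affine component belongs
to the montage transforms, not the lens. An earlier realization that
averaged disagreement vectors per nearest grid node converged to roughly
twice the grid error of the regression form (per-cell averaging biases a
curved field) and was replaced.

Defaults: `grid_n = 10`, tolerance 0.05 px on node updates, 10 iterations
total. On the synthetic radial-distortion benchmark (12 px corner
displacement, 3×3 calibration grid at 50% overlap) the estimate lands
within ~0.3 px mean grid error of the truth field and cuts the corrected
montage residual to under a quarter of the uncorrected value.

## Quality control

* **Seams** — correspondences whose residual exceeds a threshold
  (default 5 px, matching the global target) are single-link clustered at
  a radius of twice the median match spacing; clusters of at least 5
  points are reported with centroid and the tile pairs involved. On
  planted 10 px tile shifts (twice the threshold) detection is expected in
  every trial; the false-positive budget on clean unit-noise montages is
  2% of trials.
* **Gaps** — a tile is flagged when a pre-solve neighbor (by nominal
  stage footprint overlap) is no longer overlapping after solving, or a
  retained neighbor's overlap fraction fell below a floor. Tiles that had
  no correspondences at all (resin/film or vessel interiors) are
  annotated *ignorable* and do not fail QC.
* **Scale MAD** — per-tile scale factors $s_x = \lVert M_{\cdot 1}\rVert$,
  $s_y = \det M / s_x$ (QR-style, so shear does not inflate both axes;
  orientation-reversing transforms are an error, not silently
  absolute-valued). The statistic is the *median* absolute deviation
  about the median scale, per axis — robust to a single distorted tile.
  The default acceptance cutoff is 0.005 in both axes.
* **Angular residuals** — for cross-section correspondences, the angle at
  the first section's point centroid between the vectors to the two
  mapped points; sections are summarized by their median. A pure rotation
  of one section about that centroid yields exactly the rotation angle.

All metrics are pure functions of tile specs and matches; recomputation is
bit-identical.

## Parameter optimization

`sweep_lambda()` solves the montage across a log-spaced grid of
`lambda_linear` (1e-2 … 1e6, translation kept soft at 1e-5), reusing the
assembled constraint matrix and updating only $\Lambda$. Each solution is
scored by median residual and MAD; accepted points meet both targets
(defaults 5 px, 0.005) and the chosen point minimizes residual, with ties
broken by smaller MAD$_x$+MAD$_y$, then larger `lambda_linear`.
`relax_and_select()` walks a relaxation schedule — strictest first at
(0.005, 0.005), then (0.006, 0.007) in x and y — until a candidate
montage exists, recording the level that succeeded; an exhausted schedule
returns a failure report carrying the best-achieved metrics, since such
montages can still be usable downstream at the operator's discretion.

Two empirical notes. The sweep's achieved MAD is monotone non-increasing
in `lambda_linear` as a sum over axes; per-axis monotonicity holds in the
regularization-dominated regime (λ ≥ 1) but can invert at the soft end
where sampling noise dominates the per-tile scales. And on noise-free
data the softest default grid point still carries a small (~0.04 px)
regularization bias toward the deliberately wrong stage initialization;
exact recovery requires λ around 1e-8, which the tests exercise
separately.

## Progressive 3D alignment

Sections are aligned as wholes: cross-section correspondences (computed on
downsampled montage renders and lifted to full resolution, or generated
geometrically) drive per-section transforms through a progressive
sequence — rotational, then affine, then thin plate spline — in which each
stage is initialized by and regularized toward the previous stage's
solution, with the more deformable stages increasingly regularized
(defaults: translation 1e-7, linear 1e-3, TPS nodes 1e-2, relative).

The rotational stage cannot be written in the independent-axis form (the
rotation couples x and y), so it is realized as a joint linear similarity
system — unknowns $(a, b, t_x, t_y)$ per section with $x' = ax - by + t_x$,
$y' = bx + ay + t_y$ — whose solution is re-orthogonalized to unit scale.
The TPS stage parameterizes each section by the positions of a rectangular
control grid of 25–49 nodes (requests outside that range are rejected);
evaluation at match points is linear in the node positions through the
interpolating-TPS operator, so the stage stays inside the same sparse
framework. Because each stage's family nests the previous solution and
regularizes toward it, the weighted residual cannot increase across
stages; the tests assert the median is non-increasing as well.

`realign_subset()` re-solves a chosen set of sections plus a two-section
margin whose regularization is multiplied by a large boost factor
(default 1e6), pinning the margin to its current alignment; sections
outside the margin are untouched bit-exactly.

**Chunk fusion.** Independently aligned chunks are registered on their
shared sections by a rigid-family fit and assembled down a layout tree
(parent transforms composed first, then interpolation in the root frame).
Overlap sections receive an interpolated transform
$p \mapsto (1-\lambda)T_a(p) + \lambda T_b(p)$ with $\lambda$ linear in
the z index across the overlap — 0 at the first chunk's edge, 1 at the
second's, 0.5 for a single shared section — so the fused mapping equals
the adjoining chunk exactly at either edge. An affine following a TPS is
folded back into a single TPS analytically, keeping fused metadata closed
under the transform vocabulary.

## Rendering

`render_bbox()` maps output pixels to global coordinates, selects
candidate tiles by footprint, and samples each through the inverse of its
full transform chain (analytic for the linear family; Newton iteration
from the affine-part inverse for TPS, tolerance 1e-6 px, 20 iterations)
with bilinear interpolation. Overlaps composite by nearest-tile-center —
deterministic, and deliberately seam-visible so rendered QC imagery stays
honest; averaging is available as an option. MIPmap levels are 2×
area-mean downsamples. TPS linear systems at raw pixel scales mix kernel
entries of order $10^6$ with unit polynomial columns and are numerically
singular as written; they are solved after symmetric diagonal
equilibration, which restores full working precision.

## The synthetic generator as study design

The generator emulates the geometry and noise structure of a TEM
acquisition: tiles on a nominal `(1 - overlap) * tile_size` pitch grid
(defaults 3840 px and 13% overlap, a common camera/overlap setting);
ground-truth placements perturbed per tile by rotation (sd 0.002 rad),
per-axis scale (sd 0.005), and translation (sd 20 px) about the tile
center; correspondences sampled uniformly in true overlap regions, mapped
through the inverse truths, with Gaussian noise (sd 1 px) on one side and
optional uniform outliers; featureless tiles (resin, vessel interiors)
yielding no matches; an optional radial lens distortion; and per-section
rigid-plus-smooth deformations for series. The placement-perturbation
magnitudes are the package's own choice of a realistic stage-error scale,
not measured values. Tile images sample a deterministic band-limited
texture — white noise blurred at 4 px and 32 px scales, periodic by
FFT construction — through the inverse truth transforms, so overlapping
tiles genuinely share (distorted) content.

What the generator does *not* emulate: beam/charging artifacts, focus
gradients, section folds, tissue-dependent texture statistics, or
correlated stage drift. Tests passing on this data demonstrate the
correctness and calibration of the solvers and metrics under the stated
noise model; they do not certify detector performance on real EM contrast.

Everything is seeded: substream seeds are derived per section and purpose
from the single user seed (all below $2^{31}$), and identical seeds give
bit-identical collections, matches, and images.

## Problem sizes and numerical choices

The test suite and the acceptance script run on a 10×10-tile section
(1000 px tiles, 342 overlapping pairs, 300 unknowns per axis) for the
headline residual/MAD numbers, 3×3 to 5×5 sections for solver properties,
a 3×3 calibration montage for lens recovery, and a 4-section 4×4-tile
series (with a missing section and a featureless tile) for the end-to-end
pipeline — sizes chosen so the full suite completes in about a minute
while every system is still large enough to exercise sparse assembly,
gauge handling, and the optimizer. Dense normal-equations oracles
cross-check every sparse solve up to 500 unknowns at 1e-8 relative
agreement (under moderate regularization; at the stiffest grid extreme
both factorizations are conditioning-limited and agree to ~1e-7).
Degenerate inputs are handled explicitly: collinear fits raise
rank-deficiency errors naming the transform kind, zero-weight systems
return their initialization exactly, disconnected montage graphs are
solved jointly (the regularization keeps $K$ definite) but flagged with
their component count, and empty sections are an error rather than an
empty result.

## Known limitations

* The keypoint detector is a compact DoG/patch-descriptor design with
  SIFT-like invariances, adequate for the synthetic textures and
  downsampled section matching; production EM data would swap in a full
  SIFT through the same candidate/consensus/trim interface.
* Lens estimation assumes one shared correction per acquisition group and
  does not track drift across calibration sessions.
* 3D alignment is per-section (rough); per-tile deformable fine alignment
  is explicitly out of scope and expected to be performed downstream.
* Rendering materializes plain TIFF/PNG; chunked cloud formats are out of
  scope.
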