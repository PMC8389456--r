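---
title: "Models and methods behind tomotools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tomotools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomotools)
```

tomotools supports subtomogram-averaging (STA) workflows in cryo-electron
tomography: it reads and writes the metadata formats the field actually
exchanges (RELION STAR, Dynamo tables, SerialEM mdoc), converts particle
orientations between arbitrary Euler-angle conventions, derives particle
poses from annotated supporting geometries, and aligns tilt series from
gold-bead fiducials with a robustly fitted projection model. This vignette
explains the models, the tunable parameters, and the choices made where the
design was genuinely open.

## Coordinate and rotation conventions

One global convention is used everywhere: rotation matrices act on column
vectors, the world frame is right-handed with z toward the viewer, and a
positive angle is a counter-clockwise rotation looking down the axis toward
the origin. Particle orientations are stored internally only as rotation
matrices in the "rotates the reference onto the particle" sense (the
particle z-axis is the third matrix column); Euler triplets appear only at
format boundaries.

An Euler convention is described by four declarative properties: the axis
order (12 valid three-letter strings over x/y/z), intrinsic versus
extrinsic composition, the sign sense, and whether the triplet rotates the
reference onto the particle or vice versa. Intrinsic conventions compose
as $R = R_1(\theta_1) R_2(\theta_2) R_3(\theta_3)$, extrinsic conventions
in the reverse order, and the reference/particle direction is a transpose.
The shipped presets are `"relion"` (ZYZ, intrinsic, ccw, reference onto
particle) and `"dynamo"` (ZXZ, extrinsic, ccw, particle onto reference).
These presets are validated by self-consistency (the interop round-trip
tests demand matrix-level equality through both), which is the strongest
guarantee available without the external software itself.

Angle extraction (`matrix_to_euler`) reduces every axis order to one of
two canonical cases (zxz, zyx) by conjugating with a signed permutation of
the axes, and returns the middle angle in the canonical branch:
$[0°, 180°]$ for proper Euler orders, $[-90°, 90°]$ for Tait-Bryan
orders. Within $10^{-6}$ degrees of gimbal lock only the sum or
difference of the outer angles is determined; we set the third angle to 0
and let the first absorb the freedom, so output is deterministic while
only the matrix is contractually meaningful. Angles are degrees at the API
boundary, matching RELION and Dynamo metadata; radians are internal.

## Metadata formats

STAR documents are held as ordered named blocks, each either a tag-value
map or a loop table; every cell is kept as a string, so placeholder values
such as `nan` or empty fields survive a round trip, and numeric views are
produced on request. Comments are skipped on read and not regenerated:
the round-trip contract is value-level, not byte-level. Values containing
whitespace are not quoted, following observed RELION practice; this is a
documented limitation of the dialect, not of the parser. Dynamo tables
use the fixed 1-based column map (tag 1, shifts 4–6, ZXZ angles 7–9,
cross-correlation 10, tomogram 20, position 24–26) with all other columns
carried opaquely. Reals are written with 12 significant digits, so a text
round trip is exact for integers and below $10^{-6}$ relative error for
reals. mdoc files are written with CRLF endings (SerialEM native) and
sequential `ZValue` sections numbered from 0; both line endings are
accepted on read.

## Geometrical particle picking

Sphere models are annotated by a center and an edge point; particle
positions are seeded on the sphere with a deterministic equal-area
(Fibonacci) spiral of $n = \mathrm{round}(4\pi r^2 / s^2)$ points for a
requested spacing $s$, which puts the median nearest-neighbour distance
within a few percent of $s$. Each particle's z-axis is the outward
normal; the in-plane angle is uniform random from a caller-supplied seed,
because an STA experiment should not inherit a preferred in-plane phase
from the seeding lattice.

Arbitrary surfaces are annotated as point groups on successive
tomographic slices. Each slice ring is ordered by polar angle about its
centroid and consecutive rings are zippered into a band of triangles, so
the mesh vertices are exactly the annotated points (a 2.5D construction;
fully three-dimensional surface reconstruction is out of scope). Face
normals are oriented per face toward a user-declared outside point, or
away from the global centroid by default. Seeding draws positions
area-uniformly over faces at a density of one particle per $s^2$.

Subboxing derives children at fixed offsets/rotations in each parent's
frame: $p_c = p + R\,o$, $R_c = R\,R_\mathrm{rel}$; it is exactly
invertible and commutes with rigid motions of the parent set, both of
which are tested. Duplicate exclusion is greedy by descending score with
ties broken toward the lower tag — the reference implementation in Dynamo
does not document its tie-breaking, so ours is stated and tested instead.
The lattice-neighbour filter counts, in a single pass on the input set,
neighbours within a fractional tolerance (default 0.2, a deliberate
choice: published descriptions say "at the expected distance" without a
tolerance) and keeps particles with at least `min_neighbors` of them.
Single-pass matters: it makes the filter idempotent in effect and keeps
boundary removals from cascading inward.

## The tilt-series projection model

A tilt series is modelled with a single in-plane tilt-axis angle $\psi$
for the whole series, per-image 2D shifts $d_i$, and tilt angles fixed at
their nominal values — deliberately the minimal parameterization that a
conservative fiducial alignment solves, leaving finer corrections to
downstream reference-based refinement:

$$ p_{ij} = \mathrm{Rot}_2(\psi)\, \Pi\, R_y(\theta_i)\, r_j + d_i $$

with $\Pi$ the orthographic projection onto the first two coordinates and
$r_j$ the 3D marker position in pixels. $\psi$ is measured
counter-clockwise from the image y-axis. Two exact invariances matter for
interpreting results: a global translation $t$ of the markers is absorbed
by $d_i \mapsto d_i + \mathrm{Rot}_2(\psi)\Pi R_y(\theta_i)t$ (we fix
this gauge by centering the marker cloud), and $\psi \mapsto \psi + 180°$
combined with $r_j \mapsto -r_j$ leaves all predictions unchanged
($\psi$ is reported in $[0°, 180°)$).

### Solving the model

Substituting $\tilde d_i = \mathrm{Rot}_2(-\psi) d_i$ rewrites the model
as $\mathrm{Rot}_2(-\psi) p_{ij} = \Pi R_y(\theta_i) r_j + \tilde d_i$ —
linear in $(r, \tilde d)$ with a design matrix independent of $\psi$.
Writing $\mathrm{Rot}_2(-\psi)p = \cos\psi\, a + \sin\psi\, b$, the
profiled weighted residual is a quadratic form in
$(\cos\psi, \sin\psi)$ assembled from two projected least-squares
residual vectors, so $\psi$ has a closed-form global minimizer for any
fixed weights, and markers and shifts follow by one weighted linear
solve. Robustness comes from iteratively reweighted least squares with
Tukey bisquare weights, tuning constant $4.685$ times the normalized
median absolute deviation of the per-observation residual norms (the
standard robust-regression choice), with the scale floored at 0.05 px so
a near-perfect fit does not reject mildly noisy inliers. An ablation
switch (`robust = FALSE`) exposes plain least squares; with 10% gross
outlier observations the robust solver recovers $\psi$ to well under
half a degree while plain least squares does not, and the tests assert
exactly that A/B separation. On noiseless synthetic observations the
solver reproduces $\psi$ and the shifts to numerical precision, which is
why the exact profiled formulation replaced a simpler alternating
scheme: block alternation converged too slowly to make that guarantee.

### The detection-to-model pipeline

`align_tilt_series` chains the stages with every parameter derived from
two user inputs, the fiducial diameter (nm) and pixel size (Å/px):

1. a binary disc template (side $4r+1$) detects candidates by normalized
   cross-correlation (FFT numerator, summed-area-table normalization),
   greedy peak picking with a $2r$ exclusion radius and 3-point parabolic
   subpixel interpolation;
2. the 300 best candidate subimages are averaged into a data-derived
   template for a second detection pass;
3. candidates whose subimage does not correlate with its own 90°/180°/270°
   rotations (mean correlation ≥ 0.3, after 3×3 box smoothing that keeps
   the statistic from being dominated by pixel noise) are discarded —
   beads are round, edge artifacts are not;
4. observations in tilt-adjacent images are linked into trails by mutual
   best patch correlation within a $5r$ radius, after registering the two
   candidate clouds by a consensus vote over pairwise displacements
   (tilt series straight off the microscope can jump by tens of pixels
   between exposures, more than any bead-scale search window);
5. trails at least half as long as the longest seed the model; the
   solver above fits $\psi$, shifts and markers;
6. all observations are then re-assigned from scratch to the nearest
   reprojected marker within a tight $2r$ gate, iterating assignment and
   solve to a fixed point — this deliberately discards the original
   links, healing trails contaminated where two beads cross in
   projection (a wide gate here measurably inflates marker RMSD);
7. images that contributed no observations are reintegrated by matching
   the reprojected constellation to their candidate cloud (consensus
   vote, then least-squares translation), and missing per-image marker
   observations are filled the same way; the observation count never
   decreases;
8. marker centers are refined against per-marker reference images
   (average of that marker's subimages, re-localized with subpixel
   interpolation, ≤ 5 passes or 0.05 px). The reference bead sits at
   the mean subpixel offset of its contributors, not at the patch
   center, so its dark-mass centroid is measured and the common offset
   removed — without this the whole trail inherits a constant bias;
9. markers with reprojection RMSD above $1.5r$ are pruned and the model
   re-solved once.

The chain contains no randomness: identical input gives bit-identical
results. Nominal tilt angles are carried through untouched and written
back bit-identically; the `.xf`/`.tlt` writers emit the IMOD grammar (six
floats per line encoding $\mathrm{Rot}_2(-\psi)$ and
$-\mathrm{Rot}_2(-\psi)d_i$; one angle per line).

## What the simulator emulates — and what it does not

`simulate_tilt_series` renders beads as Gaussian-blurred discs (analytic
edge profile, 2× supersampling so subpixel positions are honest) at
positions generated by the projection model, then adds white Gaussian
noise; SNR is peak bead contrast over noise sigma. The default recipe is
the validation condition used throughout: 41 images from −60° to +60° in
3° steps, 512² px, 15 beads of 5 px radius placed uniformly in a slab
with a minimum mutual distance of 6 bead radii, i.i.d. per-image shifts
up to ±30 px, random tilt axis in [0°, 180°), SNR 2 (validation sweeps
run SNR 1–3). Bead placement keeps all beads inside every view; the
package errors if a bead would never be visible.

The simulator does not model CTF, dose-dependent contrast loss, sample
thickness gradients, bead clumping, or non-rigid sample motion. Passing
tests therefore demonstrate the correctness of the geometry, detection
and robust-estimation machinery under controlled conditions — not
performance on pathological real data. One such pathology is visible even
in simulation: when two beads pass within about a template width in
projection, detection merges them and the affected marker's RMSD grows;
the RMSD pruning stage exists precisely for that case.

## Numerical choices

* Validation problem sizes: rotation properties use 200 random triplets
  per convention (all 12 × intrinsic/extrinsic × both sign senses);
  format round trips use 1000 randomized documents per format; interop
  uses 1000 random particles; alignment recovery uses 20 simulated series
  at the default recipe, asserting median $|\hat\psi - \psi| < 0.5°$ and
  median shift error < 0.5 px after gauge alignment.
* Orthonormality is validated at $10^{-6}$ on input and guaranteed below
  $10^{-10}$ on output; matrix round trips hold to $10^{-8}$.
* Comparisons against simulation ground truth must respect the two model
  invariances; `alignment_vs_truth` folds the half-turn branch, matches
  markers to beads by their (gauge-invariant) observed 2D tracks, and
  removes the translation gauge before reporting errors.
* Ties in duplicate exclusion break toward the lower tag; peak picking
  breaks ties by scan order; both are deterministic.

## Known limitations

Fiducial-less (patch-tracking) alignment, local/non-rigid alignment
models, tomogram reconstruction and CTF handling are out of scope, as are
Dynamo's catalogue database internals (represented only by plain-text
pairing of filtered visualization volumes with unfiltered extraction
volumes) and quantitative benchmarking against other alignment packages.
The STAR writer does not preserve comments or quote whitespace-containing
values. The surface mesher assumes slice-wise annotation with roughly
star-shaped rings per slice; strongly non-convex rings can zipper
incorrectly.
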