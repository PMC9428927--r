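---
title: "Osteological ROM mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Osteological ROM mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(romap)
```

## The problem

Skeletonised and fossil joints carry no cartilage, capsule or ligament, yet
the bones alone already constrain which joint configurations were possible
in life: a pose in which the femur passes through the acetabular wall was
not available to the living animal, whatever the soft tissues did. The
osteological range of motion (ROM) — the set of poses free of bone-mesh
interpenetration — is therefore an *upper envelope* on mobility, and how it
responds to *joint spacing* (the gap between subchondral surfaces, a proxy
for maximum articular-cartilage thickness) carries information about joint
congruence. `romap` implements this mapping for ball-and-socket joints.

## Model and procedure

**Primitive fitting.** A sphere is fitted to each articular surface by a
linear (algebraic) least-squares solve followed by Gauss–Newton refinement
of the orthogonal distances; the reported `rms_residual` is the RMS of
$\,\bigl|\,\lVert p_i - c\rVert - r\bigr|$. Long axes use a cylinder fit:
axis initialised from the first principal component, then axis, offset and
radius refined by Levenberg–Marquardt (`minpack.lm`). Both fits are
rotation/translation-equivariant; the cylinder axis sign is canonicalised
(positive Z, then X, then Y) because an axis is a line, not a vector.

**Rearticulation** superimposes the two fitted-sphere centers with a pure
translation. Orientation is *not* decided here but by the anatomical
coordinate system: the translation-only convention is stated explicitly
because disarticulated material gives no orientation cue beyond the shape
fits themselves.

**ACS and rotation order.** The joint frame has X = abduction (+) /
adduction (−), Y = flexion (+) / extension (−), Z = long-axis rotation
(external +). In the neutral pose (0°, 0°, 0°) the distal long axis points
to the ground, so Z is the ground normal. Poses compose in the fixed "XYZ"
order with X applied first,
$R = R_z(\mathrm{lar})\,R_y(\mathrm{fe})\,R_x(\mathrm{abad})$, about axes
held fixed in the proximal frame. Two genuinely open choices were decided
as follows and pinned by oracle tests so that a re-mapping is a one-line
change:

* *Axes fixed in the proximal frame*, not body-fixed in the femur: the ROM
  map is defined on a fixed grid of angle triples, which only has a single
  interpretation if the axes do not follow the moving bone.
* *Azimuth of X*: the socket and an axisymmetric femur do not determine
  where "anterior" is, so `build_acs()` takes a `reference_axis` hint
  (default +X of the mesh coordinates) and projects it into the plane
  normal to Z.

**Viability.** A pose is non-viable iff the meshes interpenetrate: some
triangle pair intersects (Möller's interval test), or one watertight mesh
lies entirely inside the other (ray-parity of a single vertex, with
direction retries on grazing hits). Contact semantics: surface contact
that does not cross — a shared vertex, edge, or interval-touching faces —
is *not* interpenetration (the criterion is penetration, and a configurable
`tol` can additionally ignore crossings shallower than `tol` mm);
coplanar faces with *overlapping area* (e.g. coincident surfaces) do
count. The test is accelerated by an AABB bounding-volume hierarchy on
each mesh, traversed with the pose transform applied on the fly; its
outcome is identical to the brute-force all-pairs test, which the suite
verifies on hundreds of random configurations and against an independent
edge-through-triangle implementation in R.

**DOF regimes.** The pose grid defaults to FE and LAR −180..180°, ABAD
−90..90° at 5° steps: 73·37·73 = 197,173 poses, enumerated abad-outer /
lar-inner for reproducibility. Three regimes share this grid:

* `3dof`: rotations about the joint center only.
* `4dof`: one *static* translation (a candidate joint spacing) before the
  rotations; the pivot stays at the proximal joint center.
* `6dof`: translations sampled dynamically over the vertices of a coarse
  UV "offset sphere" (default 8 axis × 4 height divisions → 26 vertices,
  32 faces) whose radius is the fitted-radii difference; a pose is viable
  iff it clears at **at least one** vertex (union semantics), and the
  rotation pivot moves with the sampled vertex. The sphere center (zero
  offset) is *not* among the sampled offsets by default
  (`include_center = FALSE`): the zero-offset 3-DOF case is reported
  separately, and for a tightly fitted joint it is typically fully
  interpenetrating. Because the 4-DOF pivot differs from the 6-DOF pivot,
  the "superset over constituent offsets" property is checked against
  single-vertex 6-DOF runs, which are exact sub-cases of the union.

**4-DOF offset direction.** The single translation axis defaults to +Y —
for a hip whose socket opens laterally along the flexion axis, that is the
out-of-socket direction. The direction is an explicit parameter
(`offset_direction`), and for the bundled axisymmetric synthetic joint,
whose cup opens along −Z, the sweeps pass `c(0, 0, -1)`: the scientifically
meaningful choice is "the direction that moves the distal element away
from the joint center", not a fixed world axis. The offset magnitude is
measured from the concentric (overlaid-centroid) configuration.

**Cosine-corrected shape space.** Euler coordinates distort volume near
gimbal alignment: in the composition above, as fe approaches ±90° the
first-applied (abad) rotation aligns with the last (lar) and its
coordinate degenerates. The default correction therefore maps
$(\mathrm{abad}, \mathrm{fe}, \mathrm{lar}) \mapsto
(\mathrm{abad}\cos \mathrm{fe}, \mathrm{fe}, \mathrm{lar})$; the axis
pairing is configurable because other conventions exist in the literature.
The correction is the identity on the fe = 0 plane and contracts volumes
($|\cos| \le 1$), which the suite checks numerically.

**Alpha-shape volumes.** ROM extent is summarised as the volume (degree³)
of the alpha complex of the corrected cloud: tetrahedra of the 3D Delaunay
triangulation with circumradius ≤ α. The Delaunay kernel is built in C++
(Bowyer–Watson with a single symbolic infinite vertex, so the finite
tetrahedra tile the convex hull exactly); coordinates are rescaled to a
unit box and jittered deterministically by ~1e-8 of the extent so the
massively cospherical grid clouds are decided consistently — the jitter
perturbs volumes at ~1e-8 relative, far below any reported precision, and
α → ∞ reproduces the convex hull to better than 1e-6 relative (checked
against an independent hull implementation). **α is a required, logged
parameter of every volume**: the default is 1.5 × the grid step (7.5 at
the 5° default) — large enough to connect diagonally adjacent grid cells,
small enough to preserve concavities and disconnected "islands" of
viability, which `n_components` reports. Angles are treated as a flat box
(the grid ranges are closed intervals); a torus-aware variant would
duplicate boundary points at ±360°, and is deliberately not the default
because the default ranges already cover the full circle edge to edge.

**Spacing scans and trends.** `scan_spacing()` runs the 4-DOF regime over
a ladder of spacings and reports viable counts and α-volumes;
`fit_trends()` adds OLS linear and quadratic fits (slope, adjusted R²,
two-sided p for the linear slope), the quadratic's stationary point when
it falls inside the scanned range, and a descriptive plateau onset: the
first spacing whose viable-count increment drops below 1% of the grid
size. The plateau is reported descriptively, not as a formal changepoint
test, because the underlying claim ("mobility stops growing") is about the
shape of the curve, not about an inferential threshold.

**Trace comparison.** Empirical joint-angle traces (time, fe, abad, lar)
are compared frame by frame: each frame snaps to the nearest grid cell
(ties toward zero, errors ≤ step/2), frames outside the grid are flagged
and unviable, and contiguous unviable runs are reported as excursions.
Nearest-cell membership, not interpolation, decides viability, because the
map is a binary set on a 5° lattice.

## The synthetic generator

`make_socket_joint()` emulates the geometry the method assumes — a
hip-like ball-and-socket — with full ground truth:

* distal element: head sphere (default r = 17.552 mm), cylindrical neck,
  conical flare and shaft, built as one closed surface of revolution with
  the long axis along −Z; default total length 289 mm;
* proximal element: spherical cup (default r = 20 mm, i.e. spacing
  2.448 mm) truncated at the rim polar angle `cup_coverage` and thickened
  into a closed 2 mm shell. The default scale mirrors a small hominin hip
  so that spacing and femoral-length scalings are realistic;
* optional Gaussian surface noise along vertex normals emulates the
  irregularity of real subchondral bone (real articular surfaces are not
  spheres; noise makes tight joints interpenetrate in the concentric pose,
  as real rearticulated joints do).

For the ideal geometry the viability boundary under a pure tilt has a
closed form — contact of the neck cylinder with the rim circle at

$$\phi^{*} = 180° - \texttt{cup\_coverage} - \arcsin(r_{neck}/r_{cup}),$$

and the classifier's boundary must sit within one grid step of it. On a
15° grid the default joint yields exactly 625 viable poses =
25 LAR values × 25 (abad, fe) pairs with
$\cos(\mathrm{fe})\cos(\mathrm{abad}) \ge \cos\phi^{*}$ — an end-to-end
combinatorial check.

What the generator does **not** emulate: aspherical (lunate) articular
facets, anteverted neck angles, surrounding pelvic geometry (a far
non-interacting plate stands in for the "other bones never collide first"
condition), and any soft-tissue constraint. Passing tests on synthetic
joints therefore validate the *machinery* — fitting, rigging, collision,
volumes — not anatomical conclusions about any real specimen.

## Study conditions and problem sizes

The validation battery and the acceptance script run at deliberately
desk-sized conditions: meshes around 1,200–5,000 vertices (collision
results are resolution-dependent; the clearance-cone check uses ≥2,000
vertices where the discretisation error of a 32-segment ring is ~0.5%),
a 15° grid (8,125 poses) for full-map work, the 5° default where only a
single-axis sweep is needed, and a six-step spacing ladder from 0 to
2.5 mm — the range over which a tight noisy joint goes from fully
interpenetrating to plateaued mobility; beyond it the fixture's shallow
cup starts to disarticulate and counts decline, which is also the reason
the scan stops there. Reference viable-pose counts and volumes bundled in
`inst/extdata/` let ratio-style summaries be exercised without any
external meshes; absolute viable-pose counts of real specimens are not
reproducible without those specimens' meshes and are not targets of the
test suite.

## Numerical choices

* Vertex de-duplication on load: 1e-8 mm (STL repeats vertices per facet).
* Rigid transforms are validated to orthonormality/det +1 at 1e-8.
* Sphere-fit refinement: Gauss–Newton, convergence at 1e-12 mm steps,
  50-iteration cap.
* Collision `tol` defaults to 0 mm: only true interpenetration counts.
* Delaunay jitter: deterministic (splitmix hash), 1e-8 of the cloud
  extent, escalated ×32 on the rare retries.
* Alpha filtering uses exact circumradii of the jittered tetrahedra;
  degenerate slivers get infinite circumradius and are excluded at any
  finite α (their volume is ~0, so α → ∞ totals are unaffected).
* Plateau rule: increment < 1% of grid size; quadratic vertex reported
  only inside the scanned range.

## Known limitations

* Collision outcomes depend on mesh resolution; the suite quantifies this
  only for the synthetic fixtures (boundary within one grid step at ≥2,000
  vertices).
* The union/quorum semantics of 6-DOF viability and the exact
  cosine-correction pairing are conventions; both are parameters, and maps
  generated under different conventions should not be compared.
* Soft-tissue constraints are out of scope: ROM maps are osteological
  upper envelopes.
* The 4-DOF plateau analysis is descriptive; with ladders of 5–8 spacings
  a formal changepoint model would be overfit.
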