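---
title: "Reconstructing acetabular bone defects: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing acetabular bone defects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`acetrecon` estimates the bone missing from a pathological hemipelvis: the
defect a surgeon faces at revision total hip arthroplasty. This vignette
explains the models behind each stage, the tunable parameters, the design
decisions taken where the problem is genuinely open, what the synthetic
phantom does and does not emulate, and the package's known limitations.

## The estimation problem

The input is a single watertight triangulated surface (millimetres) of a
hemipelvis containing an acetabular defect. "Missing bone" is only defined
relative to the anatomy the patient *would* have without disease, which is
unobservable; the package estimates it with a statistical shape model (SSM)
and defines the defect as the set difference

> defect = (estimated native solid) \ (pathological solid),

restricted to the acetabular neighbourhood and extracted by ray casting.

## Statistical shape model

`build_shape_model()` aligns corresponded training surfaces by generalized
Procrustes analysis with similarity transforms (translation, rotation,
uniform scale — inter-subject size variation is real but should not be spent
on shape modes), then performs PCA on the stacked vertex coordinates. A
shape is `mean + sum_k w_k * sd_k * mode_k` with weights in standard
deviations; modes are orthonormal and at most `n_training - 1` are retained.

`fit_shape_model()` alternates two convex subproblems until the update moves
no vertex by more than `tol` (default 0.001 mm):

* **Registration.** Each template vertex is paired with its exact closest
  point on the target *surface* (point-to-triangle, not nearest vertex:
  nearest-vertex pairing floors the registration at the target's edge
  length), and the similarity transform is re-estimated in closed form.
* **Weight solve.** The pulled-back residual is solved for the mode weights
  by ridge least squares and clamped to ±3 SD. Two details matter:
  * The seven similarity degrees of freedom are projected out of the
    residual and the mode matrix before solving. An infinitesimal scale or
    translation of the mean is almost exactly representable by some
    low-variance mode; without the projection the weight solve and the
    registration trade these off freely and individual weights become
    meaningless even though the surface is fitted perfectly.
  * The ridge (default 0.1 mm) is a standard-normal prior on the SD-unit
    weights. It leaves well-determined modes essentially untouched (bias
    `(ridge/sd_k)^2` ≈ 0.1% for millimetre-scale modes) but stops
    near-zero-variance modes from amplifying surface noise, which otherwise
    drives them into the ±3 SD clamps and destabilizes the alternation.

Ten registration-only warm-up iterations precede the first weight solve, so
a misaligned start cannot push weights into the clamps before the pose is
roughly right. With these defaults, weights of generated targets are
recovered to well under 0.05 SD, and the fit is equivariant under rigid
motion of the target.

`estimate_native()` is the two-pass procedure: fit the full pathological
surface, derive a provisional acetabular frame from the fitted surface,
exclude every template vertex within 2.5 acetabular radii of the hip joint
centre, and refit. The second pass is a local optimization over a reduced
(wall-only) surface with two distinct failure modes: started cold it can
wander to a translated local minimum (the excised surface constrains the
pose weakly), while started from pass 1 it can inherit a pose in which the
first fit sank the template cup into a massive defect. It is therefore run
twice — warm-started from pass 1's weights and transform, and cold — and
the fit with the lower residual over the retained surface is kept. The
first pass itself is capped at a modest iteration count: it only supplies
the provisional frame and the warm start, and fitting pathological geometry
exactly is neither needed nor possible. An excision that would remove more
than 70% of the surface is an error.

## Acetabular frame

The rim is detected as the sharp crease loop between the cup cavity and the
surrounding surface. Note that the rim of a cavity is a *convex* crease of
the solid (interior angle ≈ 90°, like a table edge), as are the phantom's
own block edges, so the sign of the dihedral cannot identify it; instead,
all crease components above the angle threshold (default 20°) are collected
and the one forming a near-circular loop (radial coefficient of variation
< 0.05) is taken — a rectangular block-edge loop has CV ≈ 0.11 and is
rejected, and surfaces without any qualifying loop (no cup) raise an error.
Nineteen equal-angle stations are resampled along the loop.

The sphere through the rim points is fitted algebraically (linear least
squares, exact on noiseless data, deterministic); exactly coplanar points
make the sphere non-identifiable and are an error — which is why the
phantom's rim is saddle-shaped (below). The acetabular plane is the
least-squares plane of the rim points; the polar axis is its normal
oriented away from the bone centroid; the superior axis is the in-plane
projection of a global superior hint. The hint defaults to `+x` because in
the phantom convention the polar axis is `+z` (lateral); a hint parallel to
the polar axis would project to nothing.

## Ray casting and defect extraction

Rays leave the hip joint centre on a Fibonacci lattice covering the full
sphere with approximately one direction per `angular_spacing`² square
degrees (41,253 at 1°). Uniform solid-angle coverage matters because defect
*point density* feeds the 200-point cluster filter; a latitude–longitude
grid would oversample the poles.

Per ray and mesh, the first four intersections within 2.5 acetabular radii
are kept. Inside/outside parity is reconstructed from each hit list with
the origin assumed outside bone (it sits in the joint space): hits pair up
into inside intervals, an odd count closes the last interval at the range
cutoff (the far cortex usually lies beyond 2.5r, so range truncation is the
normal case, not an error), and a list truncated at the four-hit cap while
still inside cannot be resolved — the ray is flagged invalid and excluded.
Defect intervals are `(inside native) AND NOT (inside pathological)`,
clipped to the range. Interval endpoints and midpoints are recorded and
densified to `point_step` (1 mm) spacing for surfacing.

Intervals thinner than `min_interval` (default two voxel pitches, 1 mm) are
discarded: the native estimate is accurate to a few tenths of a millimetre
and the pathological surface is voxel-quantized, so thinner gaps are
surface-localization noise, not bone loss. Without this filter, rays that
graze the periacetabular surface magnify a 0.3 mm model-vs-surface mismatch
into centimetre-long false intervals.

Defect points are clustered by single linkage at `linkage_radius` (default:
twice the arc length one ray spacing subtends at maximum range, plus the
densification step — adjacent rays through the same defect always link).
Clusters under 200 points are discarded. Kept points are surfaced by voxel
ball-closing: rasterize, dilate by `alpha` (default three linkage radii) via
an exact Euclidean distance transform, flood-fill enclosed cavities, erode
by `alpha`, and extract the boundary faces. For densely sampled solids this
reproduces the sampled shape; with large `alpha` on a convex cloud it tends
to the convex hull. (A Delaunay-based alpha shape would serve the same
role; the voxel route is exactly consistent with the package's Boolean
engine and guarantees watertightness by construction.)

The refinement Booleans are `(defect − pathological) ∩ native`, evaluated as
voxel CSG at `pitch` (0.5 mm) and surfaced; reported volumes are
divergence-theorem volumes of the refined watertight solid. Two
resolution-scale cleanups follow: a morphological opening of
`opening_radius` (default two pitches) removes sheets thinner than the
native-estimate accuracy, and disconnected fragments under
`min_component_cm3` (default 0.5 cm³) are dropped — the solid-level
counterpart of the 200-point rule. Both act far below the size of any
clinically meaningful defect (the smallest suite class is ~10 cm³).

## Regions and metrics

Four regions about the hip joint centre: superior, anterior and posterior
sectors bounded by the planes through the centre at 45° between the
superior and anterior axes (dominant-axis rule — deterministic, symmetric
under axis reflection), truncated at 2.2r (superior) and 1.9r
(anterior/posterior); and a medial-wall cylinder of radius 0.86r along the
polar axis. The cylinder's length is not specified anywhere; it extends
2.5r medially, matching the excision ball that bounds everything the
pipeline can see. Regions may overlap; no partition is implied.

* **ADV** is the defect volume inside a region (cm³).
* **RDV** is ADV relative to the regional native reference. The reference
  is the union of the native estimate and the defect solid — the estimated
  bone stock before loss; the union guards against the defect solid poking
  marginally outside the estimate. The total row uses the excision ball as
  its neighbourhood.
* **DD** is the mean, over rays with a positive depth, of (furthest
  in-range pathological intersection) − (first native intersection), floored
  at zero. Averaging only positive-depth rays keeps DD independent of ray
  resolution (averaging in zeros would dilute it with coverage density);
  the ray count is reported alongside. A ray is assigned to the region(s)
  containing its defect-interval midpoints. When the pathological model has
  no in-range hit at all along a defect ray (a through-hole), the furthest
  intersection is undefined and the interval end stands in for it.

Validation metrics are volumetric Dice on a shared voxel grid anchored at
the reference mesh's bounding-box corner (default pitch 1.0 mm, the upper
end of clinical CT slice thickness), volume MAE and MARE from mesh volumes,
and sampled symmetric Hausdorff distance (area-stratified deterministic
lattice, ≥10 points/mm², exact point-to-surface distances; the estimate
converges to the true Hausdorff from below as density grows). Two empty
masks get Dice 1: a correctly detected absence of defect is agreement.

## The synthetic phantom

Patient CT cannot ship with the package, so every stage is validated on a
parametric phantom: a rectangular bone block with a hemispherical cup
carved into one face. Defaults: block 150 × 150 × 110 mm around a 25 mm
cup. The proportions matter — the block extends beyond the 2.5r excision
ball in every direction except the periacetabular face, as the ilium,
ischium and pubis do around a real acetabulum. (An earlier, smaller design
left only ~35% of the surface after excision and the wall-only second-pass
fit was visibly under-constrained on large-cup draws.)

The rim carries a saddle-height modulation (amplitude `rim_saddle`, default
0.4 mm, rim height ≈ −2·`rim_saddle`·sin²φ), as real acetabular rims do.
This is not decoration: a perfectly planar rim makes the rim sphere fit
degenerate. The saddle rim still lies exactly on the cup sphere and within
1 mm of the ideal rim circle.

The training population draws a shared allometric scale factor (SD 6%)
multiplying all block extents and the cup radius, plus 2% SD independent
jitter per dimension and rim-saddle variation. The coupling is the
condition that makes the two-pass estimate work at all: after excision the
fit sees only bone away from the cup, and the cup radius is recoverable
only because overall skeletal size predicts it — exactly the property the
hemipelvis SSM exploits on real anatomy. The residual 2% jitter bounds
how well any method can do.

Carved defects are unions of spheres/ellipsoids evaluated analytically per
voxel centre at 0.5 mm pitch (below the clinical median slice thickness of
0.7 mm); the pathological solid is surfaced from the carved mask, which
also makes it segmentation-like (voxel-quantized) rather than ideally
smooth. Ground truth — defect mask, volume, regional membership, per-ray
depth — comes from this voxel oracle, which decides inside/outside by
x-axis crossing parity and counts voxels, a code path separate from the
pipeline's z-axis Booleans and divergence-theorem volumes. The three suite
presets were calibrated once against the oracle to land near 10, 30 and
80 cm³ (the clinically reported range from contained cavitary defects to
massive bone loss); four anatomies per class give the standard 12-case
suite.

What the phantom does **not** emulate: real cortical/trabecular structure,
segmentation and metal-artifact errors, osteophytes, screw holes, anatomy
whose shape lies outside the training distribution, and left-sided hips
(the generator is always right-sided by convention). Passing the suite
therefore demonstrates the geometric correctness and self-consistency of
the pipeline under known ground truth — not clinical accuracy on patient
CT, which requires cohort data.

## Numerical choices and degenerate inputs

* Voxel masks store voxel-centre membership; surfaced masks are boundary
  faces whose divergence-theorem volume equals `count × pitch³` exactly.
  Voxel pairs meeting only along an edge are repaired (one shared
  neighbour filled) so every surfaced solid is watertight and manifold
  along edges.
* Column-parity voxelization nudges sample columns by an irrational
  sub-micrometre offset so lattice-aligned vertices and edges cannot sit
  exactly on a sampling line; edge-on triangles are skipped (their crossing
  set has measure zero).
* Ray casting deduplicates grazing hits within 1e-6 mm; a ray with an
  unresolvable parity is excluded rather than guessed.
* The algebraic sphere fit centres and scales its input; a relative
  singular value below 1e-8 (coplanarity) is an error.
* Problem sizes used throughout the tests and the acceptance run — 12
  cases, 1° spacing, 0.5 mm working pitch, 1.0 mm comparison pitch, 57
  training shapes — are the method's published operating point where one
  exists and the package's standing choice otherwise.

## Limitations

* The defect is only as good as the native estimate; systematic SSM bias
  (e.g. pathological anatomy outside the training span) propagates
  directly. The paper's own validation shows the same dependence.
* The set-difference semantics reconstruct the published behaviour from its
  description; the original supplementary rule table is not public, so
  border cases (e.g. exactly which points each rule records) are this
  package's documented choices.
* Depth along a ray uses the furthest in-range pathological intersection,
  which can exceed the local crater depth when intact far bone lies within
  2.5r along the same ray; this mirrors the published definition.
* Voxel-based Booleans and surfacing quantize at the working pitch;
  volumes carry an error of order (surface area × pitch)/2 in the worst
  case, observed well under 1% on the suite.
* Screw holes and other true voids inside the remaining bone count as
  defect wherever the native estimate has bone there, as in the original
  method.
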