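---
title: "Swept-extrusion hexahedral cartilage meshing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swept-extrusion hexahedral cartilage meshing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexcart)
```

## The problem

Finite element studies of knee contact mechanics need hexahedral meshes for
the articulating cartilage layers: tetrahedra overestimate contact stiffness
and need many more elements. Building those meshes by hand takes a skilled
analyst the better part of a day per knee, which is the bottleneck that has
kept most knee FE studies at cohort sizes of one to a few dozen. `hexcart`
implements a fully automated pipeline from a segmented tissue label volume
to a simulation-ready model: triangular rigid-body bone surfaces, blended
hexahedral cartilage volumes, and template-mapped soft-tissue attachment
sites.

Cartilage is a *laminar* tissue: a thin solid bounded by a bone-side surface
and a joint-side surface, meeting at a free edge (and, in degenerated
joints, at the rims of focal holes). Everything in the mesher exploits that
structure. The pipeline does not attempt general-purpose all-hex meshing,
and it does not mesh the menisci.

## Synthetic phantoms as the test bed

The imaging data this kind of pipeline is normally run on (expert-segmented
knee MRI) is access-restricted, so the package ships a phantom generator
that emulates the geometric features the mesher has to survive:

* **Slab phantoms** (`make_slab_phantom()`): a cartilage plate of known
  thickness on a bone block, flat or wrapped onto a cylinder of known
  radius, with optional cylindrical through-holes emulating focal cartilage
  loss. Holes are right cylinders through the full depth.
* **Joint phantoms** (`make_joint_phantom()`): a cylindrical condylar shell
  (`femoral`), two flat plateau compartments with independent labels
  (`tibial`), and an elliptical patch (`patellar`).
* **A template atlas** (`make_template_atlas()`): an asymmetric ellipsoidal
  femur stand-in carrying 160 uniquely named attachment sites at
  deterministic surface locations plus two joint-axis landmarks. The
  asymmetric radial modulation is essential: a plain ellipsoid has flip
  symmetries that make registration ambiguous, which real femora do not.

Every phantom carries both an analytic surface representation and a
matching voxelization (cell-centred samples, half-voxel lattice offset so
voxel centres never sit exactly on an analytic boundary), plus a
ground-truth record. Phantoms are deterministic given their parameters.

Default phantom dimensions are chosen at the anatomical scale of the adult
knee: condylar curvature radius 30 mm, cartilage thickness 2–3 mm, plateau
compartments ~22 × 16 mm, voxel spacing 0.5 mm (the in-plane resolution of
typical knee MRI protocols is 0.3–0.7 mm). The bone block extends 6 mm
beyond the cartilage footprint, as bones do in the joint; the blending
stage relies on having bone to fuse onto.

What the phantoms deliberately do not model: MR intensity (there is no
segmentation stage here), population shape variation, osteophytes, and
segmentation noise beyond what voxelization itself introduces. Passing
tests on phantoms therefore demonstrates the geometric machinery, not
robustness to segmentation error.

## Reconstruction

`reconstruct_tissue()` runs, in order: morphological closing (cubic kernel,
5 voxels for cartilage, 3 for bone — a cubic kernel was chosen where the
kernel shape was unspecified), iso-surface extraction, largest-component
filtering, quadric decimation (80% triangle reduction), Laplacian smoothing
(9 iterations), and repair.

Two implementation choices deserve explanation:

* **Marching tetrahedra instead of table-based marching cubes.** Each grid
  cube is split into the six Freudenthal path tetrahedra sharing the main
  diagonal; per-tetrahedron triangulation is unambiguous, so the surface is
  topology-consistent by construction — the same property that motivates
  Lewiner-style marching cubes — without a 256-case table. Surfaces are
  extracted at iso 0.5 of a box-antialiased indicator field rather than the
  raw binary mask; midpoint interpolation on a raw binary mask produces a
  staircase whose area overestimates a sphere's by far more than the 5%
  accuracy the pipeline targets.
* **Smoothing relaxation.** The smoother moves each vertex toward its
  umbrella average by a relaxation factor. The reconstruction path uses
  0.1: at unit relaxation, nine iterations visibly collapse a 3 mm slab rim
  (millimetres of shrinkage), defeating the round-trip accuracy the
  pipeline promises (surface within two voxel diagonals of ground truth).
  Small relaxation factors remove voxel staircase noise while bounding
  shrinkage; `laplacian_smooth()` still exposes the full range.

Component filtering ranks closed components by divergence-theorem signed
volume; open components (whose signed volume is meaningless) rank below any
closed one, by area among themselves. Bone surfaces get full repair
(welding, degenerate/duplicate removal, consistent re-orientation,
watertightness check); cartilage repair only re-orients normals, because
physiological holes must survive untouched.

## Bone remeshing

`remesh_uniform()` builds isotropic rigid-body bone meshes by Voronoi
clustering: k-means vertex clusters become the output vertices (cluster
centroids projected back to the surface) and the cluster-adjacency dual
becomes the triangulation. The cluster count is `area / (√3/2 · target²)` —
one vertex per equilateral-tiling vertex area — which makes the triangle
count come out near `area / (√3/4 · target²)` and the mean edge near the
target (3 mm default).

Raw k-means labels are jagged along flat-face bisectors and produce
spurious triple junctions, so the partition is regularized first
(majority-vote label smoothing, then connectivity enforcement) and the dual
receives local surgery for residual four-valence junctions. A clustering
whose dual is still topologically degenerate (two clusters meeting along
disjoint segments — common on thin, sharp-edged solids) cannot be
triangulated at all; the remesher then retries with derived sub-seeds and
finally falls back to quadric simplification at the equivalent triangle
budget, which is watertight by construction. All paths are deterministic
given the seed.

## The swept-extrusion hex mesher

`mesh_cartilage()` orchestrates: sweep grid → sheet connection → degenerate
repair → stage-1 optimization (scaled Jacobian ≥ 0) → in-plane 2×2
subdivision → stage-2 optimization (≥ 0.5) → blending → depth subdivision
into four linearly spaced layers. Grid pitch is twice the 1 mm target edge,
so post-subdivision in-plane edges land near 1 mm.

**Sweep grids.** Femoral and patellar sites sweep origins along the
medial–lateral axis (the second principal axis of the surface) with a fan
of radial rays from the least-squares (Kasa) circle fit of the sagittal
profile; a flat patellar surface simply drives the fitted radius large and
the fan degrades to near-parallel rays. Tibial sites project along the
surface normal direction, discarding back faces, and lay a rectilinear
interior grid on the 0.9-scaled minimum-area bounding box of the footprint;
the outermost ring is then projected radially (per angular sector from the
footprint centroid) onto the cartilage silhouette. If a hole touches the
interior-grid edge that projection is ill-defined, and the strategy
signals failure so the orchestrator can fall back to a plain rectilinear
grid on the unscaled box. A strategy also fails if fewer than 60% of its
rays pierce both cartilage surfaces. The package adopts one orientation
convention throughout: tissues are posed with the joint surface superior
(+z), as in the phantoms and typical knee imaging.

**Degenerate elements.** Boundary cells with exactly three valid corners
become six-node wedges. Each is attributed to its invalid grid node; the
number and arrangement of wedges sharing that node classifies the
configuration — the package's documented patch table:

| incident wedges | arrangement        | class  |
|-----------------|--------------------|--------|
| 1               | invalid region touches the grid border | `peak` |
| 1               | invalid region is an interior hole      | `corner` |
| 2               | edge-adjacent (same topological index)  | `step` |
| 2               | diagonal           | `mirror` |
| 3               | L-shaped           | `stair` |

Anything else (e.g. an isolated interior invalid node surviving cleanup) is
an error naming the element ids, never silent. Repair is class-specific:
peaks are deleted (the minimal-change choice for a protruding lone corner);
all other classes create the missing node by parallelogram completion of
each member cell, averaged. The created pair is deliberately *not* snapped
to the surface: near a hole the nearest surface is the hole wall, and
snapping both the bone- and joint-side points there collapses the column.
Repair is idempotent, and ties between repair choices break toward the
smaller node-count change, then the lowest element id.

**Quality optimization.** Element quality is the scaled Jacobian: the
minimum over the eight corners of the determinant of the corner Jacobian
built from unit-normalized edge vectors (1 for a cube, ≤ 0 degenerate). The
optimizer alternates constrained Laplacian moves of the nodes of
below-threshold elements with re-projection onto the source surface, under
a monotone acceptance rule — an iteration that would increase the number of
below-target elements is rejected and retried at half step. The iteration
cap (200 per stage) turns the classic failure mode of this algorithm
family — oscillating forever on a misclassified configuration — into a
reported error carrying the worst elements and their qualities.

## Blending

A linearly subdivided brick mesh meets the bone in a stair-step edge that
catches on articulating meshes during sliding contact. Blending replaces
the step with a ramp, in four stages operating on the single-layer sheet:

1. **Initialization** (`init_blend_displacements()`): bone-side edge nodes
   stretch outward and joint-side nodes compress inward along the edge-face
   normals until the profile reaches a 45° slope, with the bone side doing
   80% of the work. With a bone surface present, displaced bone-side
   targets snap to its nearest point (search capped at twice the local
   depth; unfused nodes feed the provenance tiers: full / perimeter /
   unfused).
2. **Feature-angle enforcement**: fold angles are measured as
   deviation-from-flat between adjacent faces (0° coplanar, 90°
   perpendicular — one convention for both the 35° minimum here and the 30°
   joint-side stop below). Offending bone-side magnitudes are relaxed in
   10% decrements until every blended fold angle reaches 35°.
3. **Intersection resolution**: edge loops are smoothed per coordinate with
   a degree-3, window-7 Savitzky–Golay filter (the smallest symmetric
   window with margin over the degree; cubic arcs pass through unchanged),
   arc-ordered with periodic padding. The filter correction is scaled by
   the global relaxation level so that relaxing to zero provably reverts to
   the intersection-free raw edge; remaining face intersections reduce the
   level in 10% steps.
4. **Graduated front smoothing**: independent Laplacian smoothing of the
   bone- and joint-side quad surfaces over an advancing front, edge nodes
   fixed. The initial iteration count is `⌈550·n_surface/(n_surface −
   n_front)⌉` (quad face counts, capped at 2000 to bound runtime); the
   bone-side front advances from element depth two to five with the count
   halved per advance, the joint side advances once. Smoothing stops early
   rather than let interior elements fall below 0.5 or blended elements
   below 0.

Blending changes only coordinates — connectivity is untouched — and only
the five edge-most element layers move. Where the two angle thresholds
could have used different conventions, the package uses the single
deviation-from-flat convention everywhere and documents it in
`feature_angle()`.

## Attachment-site mapping

`register_icp()` estimates a 7-dof similarity transform (scale restores the
subject's original size on inversion; rigid mode available) by iterating
point-to-nearest-surface-point correspondences with a closed-form Umeyama
update. Initialization is centroid + principal axes; axis signs are
ambiguous, so all four proper flips are scored by closest-point RMS and the
best seeds the iteration — without this, near-symmetric shapes lock into
mirrored local optima. `map_attachment_sites()` matches each template site
to the nearest subject node in the template frame (ties to the lowest node
id) and returns subject-frame coordinates; the femur-driven transform is
applied to all tissues.

## Comparison metrics

`surface_deviation()` traces each predicted node to its nearest point on
the reference surface over element faces, not just vertices; rays deviating
more than 20° from the node normal (area-weighted average of incident face
normals) are excluded, and the retained percentage is the nodal coverage.
The measure is directional (predicted → reference) by design. Summaries use
only included nodes; the density estimate is a Gaussian KDE with Scott's
bandwidth. `dice_coefficient()` and `minmax_rms()` implement the standard
overlap and min-max-normalized RMS error; the RMS percentage is normalized
by the range of the *reference* series.

## Orchestration

`run_pipeline()` validates its configuration against a schema (unknown keys
are errors), reconstructs every tissue present, remeshes bones, meshes
cartilage with the fallback cascade — disable bone fusion → reduce blend
displacement → simplified tibial grid → early in-plane subdivision (the
grid is cast at final density and the subdivision stage skipped) — and
records which fallbacks fired in each mesh's provenance, together with
timings and per-layer quality summaries. Per-tissue failures are isolated;
the bundle reports partial success. Worker counts are honoured with a fork
pool where available, and the serial path is the reference: pooled and
serial runs are byte-identical, so parallelism is purely a throughput
contract. Every bundle carries the configuration hash and seed.

The Abaqus export writes 8-node linear continuum elements for cartilage,
3-node rigid shells for bones, and one named node set per attachment site,
with hex corners ordered bottom face counter-clockwise then top — the
ordering the scaled Jacobian sign convention assumes.

## Numerical choices and problem sizes

Coordinates are millimetres throughout; voxel index (i,j,k) maps to world
as `origin + index · spacing` with 0-based, cell-centred indices. Vertex
welds use 10⁻⁶ mm; duplicate-node checks in final meshes use the same
tolerance. Mesh file formats are plain text (STL/PLY/legacy VTK/ASCII VTU)
with coordinates at 12 significant digits; NIfTI label volumes go through
RNifti.

The shipped tests and the acceptance script run entirely on phantoms at
0.5 mm voxel spacing with grids of order 10⁴ voxels per axis slice and
meshes of 10²–10⁴ elements — sizes chosen so a full condyle meshes in
seconds on one core while still exercising every code path (holes,
fallbacks, fusion tiers). The same code paths scale to imaging-resolution
inputs without modification.

## Known limitations

* The tibial "radial sector" interior grid is implemented as a scaled-box
  rectilinear grid with radial rim projection; the original construction
  this emulates is not published in detail.
* Voronoi remeshing of thin, sharp-edged solids may fall back to quadric
  simplification; on such shapes the mean edge follows the triangle budget
  rather than strict isotropy.
* Blending assumes the cartilage edge loop is simple; severely fragmented
  edges (many touching holes) can exhaust the relaxation cascade, which is
  reported as a per-tissue failure rather than repaired.
* The pipeline neither segments images nor runs FE solves; it starts at
  label volumes and stops at the exported deck.
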