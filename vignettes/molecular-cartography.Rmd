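---
title: "Molecular cartography: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular cartography: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molcart)
```

## The problem

Protein function lives on the molecular surface, but surfaces are hard to
compare: unlike sequences or backbones there is no general alignment
machinery for them.  molcart follows the cartographic route: flatten a
triangulated solvent-excluded surface (as produced by MSMS at the usual
1.4 Å probe radius) into the plane, paint the map with biochemical and
geometric channels, and compare proteins as images.  Like any map of a
curved world, every flattening distorts; the package's job is to make the
distortion measurable and small.

An enclosed surface cannot be flattened at all without collapsing antipodal
regions onto each other, so the workflow first bisects the surface by the
three coordinate planes into six open half-sections (`bisect_by_planes()`)
and maps each section separately.  The cutting origin defaults to the
vertex centroid for translation invariance; pass `origin = "coordinate"` to
cut at the raw coordinate planes of the input frame instead.  Faces
straddling a cutting plane are dropped rather than clipped — clipping would
invent vertices with no atom assignment — and vertices exactly on a plane
belong to both half-spaces, so opposing sections share the boundary ring.

## Embedding methods

All methods consume a `trimesh3d` and return an `embedding2d`, vertex for
vertex:

* **PCA** (`embed_pca()`): projection onto the top two principal axes.
  Linear, instant, and the canonical baseline; on curved sections it
  collapses everything along the discarded axis.
* **Classical MDS** (`embed_mds()`): Torgerson scaling of the Euclidean
  distance matrix.  For Euclidean input this is PCA up to an orthogonal
  transform, so the two always score identically — a useful internal
  consistency check, which the test suite enforces to a Procrustes residual
  below 1e-8.
* **Sammon mapping** (`embed_sammon()`): minimizes the inverse-distance-
  weighted stress \((1/\sum d_{ij}) \sum (d_{ij}-\delta_{ij})^2/d_{ij}\)
  from the PCA start.  The PCA initialization (rather than a random one)
  makes the method deterministic; the weighting privileges short-range
  fidelity.
* **Isomap** (`embed_isomap()`): classical scaling of geodesic distances.
  Geodesics are shortest paths over the mesh's own connectivity, not over
  an ambient-space k-nearest-neighbor graph: the triangulation is the true
  surface topology, and ambient k-NN graphs are exactly what lets shortcut
  edges tunnel across folds.
* **Landmark Isomap** (`embed_landmark_isomap()`): geodesics from a seeded
  uniform sample of landmark vertices only; landmarks are embedded by
  classical scaling and the remaining vertices placed by the standard
  distance-based triangulation formula.  Converges to full Isomap as the
  landmark count approaches the vertex count.
* **SNE** (`embed_sne()`): Gaussian stochastic neighbor embedding.
  Per-vertex bandwidths are solved by bisection to match the perplexity
  (default 15, sized for the ~100-vertex benchmark sections; scale it with
  your mesh).  The Kullback-Leibler cost is minimized by gradient descent
  with an adaptive step: an accepted step grows the step size by 10%, a
  rejected one halves it.  This makes the cost monotonically non-increasing
  — with a fixed step the descent on these meshes oscillates and can
  diverge outright — and the returned cost never exceeds the initial one.
* **Sinusoidal projection** (`project_sinusoidal()`): the equal-area
  cartographic reference, \(x = \bar R(\lambda-\bar\lambda)\cos\varphi\),
  \(y = \bar R\varphi\) about the vertex centroid.  The mean longitude
  \(\bar\lambda\) is the circular mean (atan2 of mean sine and cosine): an
  arithmetic mean of wrapped angles is meaningless at the ±π seam.

### Geodesic distances

`geodesic_distances()` runs Dijkstra over a graph derived purely from the
mesh topology.  With `ring = 1` the graph is the mesh edges; the default
`ring = 2` additionally connects each vertex to its neighbors' neighbors by
their straight-line chord.  The reason is crystalline anisotropy: a path
restricted to mesh edges can only move in the few directions the
triangulation provides, so graph distances overestimate true surface
distances by up to tens of percent in directions between edge directions.
Two-ring chords double the available directions and roughly halve that
bias, while still spanning only a two-edge surface neighborhood — they
cannot tunnel across folds the way ambient k-NN edges can.  On the
developable cylinder oracle this is the difference between Isomap
recovering the development to an area score of 0.94 versus 0.997.

## Scoring a flattening

Two complementary numbers, computed by `score_map()`:

* **Area score**: Pearson's correlation between the areas of the surface
  triangles measured in 3-D and re-measured under the map coordinates
  (range −1 to 1).  Scale-free, so a map may be globally rescaled at will.
* **Neighbor score**: each vertex marks its k = 3 nearest other vertices —
  geodesically in 3-D, Euclideanly in the map — and the two connectivity
  matrices, linearized as bit vectors \(X, Y\), are compared by the
  Tanimoto coefficient \(T = X\cdot Y/(\|X\|^2+\|Y\|^2-X\cdot Y)\)
  (range 0 to 1; identical to the Jaccard similarity of the marked pair
  sets, which the tests verify against an independent set-based oracle).

Two implementation details matter on regular meshes.  First, the directed
k-NN matrix is linearized as-is by default; symmetrizing by union
(`symmetrize = "union"`) systematically inflates the score of good maps,
because a union forgives one-sided neighborhood losses.  Second,
equidistant neighbors are everywhere on regular triangulations, so
distances are rounded to 10 significant digits before ranking and ties are
broken by vertex index — otherwise two maps identical up to a rigid
rotation can rank tied neighbors differently on floating-point noise and
score differently, which would be absurd.

On the reference hemisphere (the 162-vertex, 320-triangle level-2 icosphere
cut at a center plane) the nonlinear methods (Isomap, Sammon, SNE) clearly
beat the linear and cartographic baselines in area score, with Isomap
leading; the benchmark below reproduces this ranking deterministically.

```{r benchmark, eval = FALSE}
run_benchmark(c("pca", "isomap", "sammon", "sinusoidal"))
```

## Synthetic surfaces

The generator module provides the study geometry in code, so every result
above is reproducible without any input files:

* `make_icosphere(level)`: recursive icosahedral subdivision with shared
  midpoints deduplicated and vertices projected to the unit sphere
  (10·4^L + 2 vertices, 20·4^L faces).  The standard cyclic golden-ratio
  coordinates put four vertices (and their midpoints) exactly on the
  z = 0 plane, so the center cut retains a clean equator ring.
* `reference_hemisphere()`: the level-2 icosphere cut at z ≥ 0 through the
  center — 89 vertices and 152 faces after the straddling equatorial faces
  are dropped.  How the original benchmark oriented its hemisphere and
  which faces it kept at the equator is not recoverable, which is why the
  reference scores are checked to a ±0.15 band rather than exactly.
* `make_cylinder_patch()`: an open cylinder sector, the developable oracle:
  its exact flattening is known in closed form (attached as the `"uv"`
  attribute), so embedding quality can be judged against ground truth.
  The grid uses checkerboard-alternating quad diagonals and linearly graded
  spacing in both directions (largest step twice the smallest).  Both
  choices remove artifacts of perfect regularity rather than add realism:
  a uniform single-diagonal grid has congruent triangles (zero area
  variance, so the area score is undefined) and is saturated with exactly
  equidistant neighbor pairs whose k-NN ranking is decided by rounding
  noise rather than geometry.  Protein surfaces have neither pathology.

What the synthetic surfaces do **not** emulate: pockets, tunnels, deep
concavities, and the sampling irregularity of real MSMS output.  Passing
the synthetic benchmarks shows the machinery is correct on surfaces of
known geometry; protein-scale behavior additionally depends on MSMS
density settings, which is why protein reproductions are supported (via
`read_msms()`) but not asserted by the tests.

## Feature channels

* **Hydrophobicity**: each vertex inherits the Kyte-Doolittle index of the
  residue owning its nearest atom — the MSMS per-vertex atom assignment
  when present, otherwise a 5 Å nearest-atom search.  Nearest-atom
  transfer (rather than distance-weighted smoothing) keeps residue
  boundaries sharp on the map.
* **Electrostatic potential**: a screened Coulomb sum
  \(\phi(v)=\sum_i q_i/(\epsilon(d_i) d_i)\) with the distance-dependent
  dielectric \(\epsilon(d)=4d\) and a 1 Å distance floor (surface vertices
  sit about a probe radius from any atom; the floor only guards malformed
  input).  Charges default to a formal-charge table at neutral pH, split
  over chemically equivalent atoms (Asp/Glu carboxylate oxygens −0.5 each,
  Lys NZ +1, Arg NH1/NH2 +0.5 each, His ring nitrogens +0.05 each, charged
  termini ±1) and are fully overridable.  This is a deliberate
  approximation: a finite-difference Poisson-Boltzmann solution is a
  project of its own, and the mapping pipeline is agnostic to the
  potential's provenance — a grid solved by an external PB solver can be
  imported (`load_potential_grid()`, OpenDX format) and sampled
  trilinearly instead.
* **Curvature**: discrete mean curvature from the cotangent
  Laplace-Beltrami operator with Meyer's mixed Voronoi vertex areas,
  signed positive on convex bumps (the mean-curvature vector opposes the
  outward normal) and negative in concavities.  Barycentric one-third
  areas were rejected: they misestimate the operator by ~14% at the
  icosahedron's original vertices, while mixed areas reproduce the 1/R
  sphere limit to 4 decimal places.  Boundary vertices of open sections
  have no well-defined Laplacian and receive their interior neighbors'
  average, flagged in the `"boundary"` attribute.
* **Annotation masks**: a plain `chain residue` list (e.g. active-site
  residues from any curated source) becomes a 0/1 vertex mask by the same
  nearest-atom rule.

## Images, registration, texture

`rasterize()` fits the map into a square raster (5% margin, aspect
preserved, isotropic scale) and splats each vertex as a small disc;
overlapping splats resolve to the nearest vertex, and each channel is
normalized to 8 bits over its clip range (hydrophobicity ±4.5; potential
and curvature symmetric at the 95th percentile), so a vertex's color never
depends on the raster resolution.  Default channel order is potential,
hydrophobicity, curvature → R, G, B.

`register_rigid()` does an exhaustive rotation search (2° grid by default,
optionally reflected); per rotation the best integer translation is found
by masked normalized cross-correlation computed via FFTs, counting only
pixels covered in both images and requiring a minimum overlap fraction so
tiny accidental overlaps cannot fake a perfect score.  NCC is the single
implemented metric.  Note the pixel convention: image rows grow downward,
so a map-space rotation by +θ is recovered as −θ in pixel space.

`texture_assign()` samples an image at each map point and
`colorize_mesh()`/`write_ply()` carry the colors back to 3-D, where any
PLY viewer interpolates them across triangles.  At a raster resolution of
at least 4√n per side the round trip is lossless — every vertex recovers
exactly its own color — which the acceptance tests assert on the
hemisphere.

## Numerical choices, in one place

* Spectral sign conventions are fixed (largest-magnitude coordinate
  positive per axis), making PCA/MDS/Isomap bit-reproducible across runs
  and BLAS builds.
* Sammon stops at a relative stress change below 1e-7 or 500 iterations;
  the result is never allowed to be worse than its initialization.
* SNE runs 1000 adaptive-step iterations from a seeded N(0, 1e-4) start;
  same seed, same map, bit for bit.
* The PCA/MDS equivalence check requires distinct top-two eigenvalues; on
  a perfect sphere the covariance is isotropic and "the top two axes" is
  ill-posed for both methods, so closed-surface checks use an
  anisotropically scaled sphere.
* Degenerate inputs fail loudly, never silently: rank-deficient vertex
  clouds, duplicate vertices under Sammon, disconnected meshes (reported
  with component sizes), zero-variance area vectors, constant images under
  NCC.

## Problem sizes

The test and benchmark surfaces are desk-scale by design: the 89-vertex
reference hemisphere, 20×20 cylinder patches, and the 642-vertex level-3
icosphere for the curvature limit.  All-pairs geodesics are quadratic in
vertex count and SNE is quadratic per iteration, so these sizes keep the
full suite in seconds while exercising every code path; the same routines
run unchanged (just longer) on the ~8000-vertex sections MSMS produces for
real proteins.

## Known limitations

* Sections are charts with seams: features crossing a cutting plane appear
  on two maps.  No atlas blending is attempted.
* The Coulomb channel ignores solvent screening beyond the ε(d) = 4d
  heuristic and ionic strength entirely; import a solved grid when
  quantitative electrostatics matter.
* Registration is rigid (rotation + translation + optional reflection).
  Maps of genuinely different proteins generally need deformable matching,
  which is out of scope.
* Landmark Isomap's out-of-sample placement inherits landmark sampling
  noise; with very few landmarks expect area-score spread of ±0.05 across
  seeds on the hemisphere.
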