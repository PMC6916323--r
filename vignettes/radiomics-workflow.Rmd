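---
title: "From DICOM-RT to annotated radiomic features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From DICOM-RT to annotated radiomic features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsem)
```

## The problem

Radiomics turns delineated regions of medical images into quantitative
descriptors — first-order intensity statistics, 3-D shape measures, and
texture features built on gray-level matrices. Two obstacles make such
features hard to compare across institutions: the same name ("entropy") can
denote different quantities, and the computation details (discretization,
resampling, software version) are usually lost by the time values reach a
spreadsheet. `radsem` addresses both: it computes a fixed 105-feature panel
with explicit, documented numerics, and publishes every value as an RDF
statement whose node links to its ontology code, VOI, patient, software and
settings, so that a basic graph-pattern query can recover the full
computational context of any number.

The pipeline is: DICOM series + RTSTRUCT → geometry-aware volume and planar
contours → binary mask per VOI → optional resampling / re-segmentation →
gray-level discretization → seven feature families → RDF graph + CSV.

## Coordinate conventions

Voxel indices are 0-based `(slice, row, col)`. A voxel center sits at
`origin + D %*% (spacing * index)`, with `D` a 3×3 matrix of unit columns
for the slice, row and column axes in the LPS patient frame. Series are
sorted by the projection of ImagePositionPatient onto the slice normal
(cross product of the row/column cosines), so reading is invariant to file
order. Non-uniform slice gaps beyond 0.001 mm are rejected rather than
silently interpolated — for a feature pipeline, refusing ambiguous geometry
is safer than guessing.

RTSTRUCT-to-series matching tries, in order: shared FrameOfReferenceUID,
the referenced SeriesInstanceUID, then co-location in the same case
directory. The fallback chain is this package's choice (DICOM offers no
single mandated linkage); the `matched_by` field of every pairing records
which rule fired, and directory fallbacks are logged.

## Mask rasterization

A voxel belongs to a VOI iff its **center** lies inside the even-odd
(parity) fill of the union of that slice's polygons, evaluated in the slice
plane. Multiple polygons on one slice combine by the even-odd rule, so an
inner contour cuts a hole — rings need no special casing. Contours are
assigned to the nearest slice, tolerance half a slice spacing; tilted
contours are projected with a warning. Centers exactly on an edge follow
the scan-line half-open convention (left/top edges inside), which makes
results deterministic; real clinical contours essentially never place a
vertex exactly on a voxel center, and the phantom generator keeps test
geometry off centers so both in-repo implementations must agree exactly.

Two rasterizers ship: the production scan-line fill, and an independent
per-voxel ray-casting oracle (`oracle_rasterize`) sharing no code with it.
Their Dice coefficient is asserted to be exactly 1.0 over randomized
rectangle / 64-gon circle / ring ROIs across multiple grid spacings — the
in-repo analogue of comparing independent converter implementations.
`dice()` returns 1 for two empty masks by convention.

## Preprocessing

* **Resampling** (off by default): trilinear for intensities, nearest
  neighbor for the mask, first-voxel-center alignment. The affine-pattern
  phantom makes trilinear interpolation exactly verifiable.
* **Re-segmentation** (off by default): drops masked voxels outside an
  intensity window.
* **Discretization**: fixed bin width `w = 25` intensity units by default,
  `level(x) = floor((x - min)/w) + 1`, bins anchored at the region minimum;
  or a fixed bin count `n` with the maximum mapped to level `n`. Anchoring
  at the region minimum (rather than a global constant) is a deliberate,
  recorded choice; because every run's settings are serialized into the
  output graph, nothing about the discretization is implicit.

The defaults (no resampling, no re-segmentation, bin width 25, all
families) constitute the package's "basic" panel of 105 features:
18 first order + 14 shape + 22 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM +
5 NGTDM.

## Feature numerics

All moments are population (biased) moments; kurtosis is the non-excess
Pearson form (normal → 3). Percentiles use the linear-interpolation
definition. First-order Entropy (`-Σ p log₂ p`) and Uniformity (`Σ p²`)
are computed on the discretized histogram; the remaining 16 first-order
features use raw intensities.

**Texture matrices.** Gray-level co-occurrence uses distance 1 and the 13
unique 3-D directions, symmetric accumulation, per-direction normalization,
features averaged over directions with equal weights (directions with no
valid pair are dropped). Run-length matrices are built per direction the
same way; size zones and dependence use 26-connectivity; the neighborhood
gray-tone difference table excludes voxels with no in-region neighbor. All
five constructions are validated against naive enumeration oracles (pair
loops, run walks, flood fill, neighbor counting) on random ≤5³ grids to
1e-9 relative.

Degenerate regions follow fixed conventions rather than erroring: a
constant region has zero gray-level entropies and unit uniformity/energy;
NGTDM Coarseness is capped at `1e6` (the `1/ε` guard with `ε = 1e-6`) when
`Σ p·s` vanishes; Contrast and Busyness are 0 when only one level is
occupied; a single-voxel region yields NaN skewness/kurtosis with a logged
reason. Note that GLDM *Dependence* Entropy is genuinely nonzero on a
constant region — dependence counts vary with position (corners, edges,
faces, center) even when levels do not.

**Shape.** Surfaces are closed triangle meshes extracted from the mask
indicator at iso-level 0.5 by tetrahedral decomposition of the voxel
lattice (six tetrahedra per cell, vertices by linear interpolation on
edges). Two extractions are combined deliberately:

* *Mesh volume* is measured on the raw midpoint mesh, which follows the
  voxel region faithfully for any shape (digitized r = 20 mm sphere:
  −0.4 %).
* *Surface area* is measured on a mesh of the indicator pre-filtered with a
  0.8-voxel Gaussian. The raw midpoint surface is staircase-shaped and its
  area does **not** converge to the true area of a smooth boundary (it
  overestimates a sphere by roughly a quarter — the classic Manhattan-
  staircase effect); the lightly anti-aliased surface does converge
  (sphere: +0.6 %).

Sphericity `(36π V²)^(1/3) / A` combines the two (sphere ≈ 0.991).
Structures too thin to survive the filter (for example single-slice
regions) fall back to the raw mesh area with a log note — their areas are
then exact for the staircase surface, not estimates of a smooth one. The
0.8-voxel width was chosen once as the smallest filter that removes the
staircase bias at millimeter grids; it is a property of the area estimator,
recorded here, not a per-dataset tuning knob. Axis lengths are
`4·sqrt(λ)` of the population PCA of voxel-center coordinates; maximum 3-D
and in-plane 2-D diameters use boundary voxel centers (a half-voxel-scale
difference from mesh-vertex definitions, accepted for robustness). A
single-voxel mask still meshes cleanly (a small closed polyhedron), so
surface and volume stay finite; only the PCA-derived features are NaN
there.

## Semantic export

Each run produces a triple graph: per feature a type link to its ontology
code, an `rdfs:label`, the value as a decimal literal with 15 significant
digits, and a link to its VOI; the VOI links to the patient; one software
node (name, version, programming language) and one settings node
(discretization kind, bin width/count, resampling, re-segmentation) are
shared by all features of the run. Feature IRIs embed a fingerprint of the
configuration and software, so merging graphs from different runs is plain
set union and can never collide. The built-in mapping table covers the full
roster; the two features whose IBSI identifiers the package pins are
Intensity Histogram Entropy (TLU2) and GLCM Joint Entropy (TU9B) — every
other feature carries a deterministic local code flagged `local`, and a
two-column CSV can override or extend the mapping.

Serialization targets N-Triples and Turtle (one triple per line, no
abbreviations), with a parser for the same subset, asserted to round-trip
exactly. The query engine implements exact basic-graph-pattern join
semantics only — the conjunctive core of SPARQL, enough for the
five-variable provenance query (patient, feature, language, version,
value) that distinguishes software implementations in a merged graph.
OPTIONAL, FILTER and property paths are out of scope by design: any real
triple store can ingest the serialized files.

The CSV writer uses the same 15-significant-digit representation as the RDF
literals, so the two outputs agree bit for bit.

The concordance correlation coefficient uses population moments:
`CCC = 2·cov(x,y) / (var x + var y + (mean x − mean y)²)`; two constant
equal vectors score 1 by convention. Under equal means and variances CCC
equals Pearson r — a useful algebraic identity for sanity checks (e.g.
`ccc(c(1,2,3), c(3,2,1))` is exactly −1).

## The phantom generator

Synthetic cases are complete DICOM Part-10 series (CT/PT/MR image storage,
explicit VR little endian, 16-bit pixels with exact rescale) plus an RT
Structure Set, with analytically known geometry: constant, axis-gradient,
uniform-random-level and sphere-lesion intensity patterns; rectangle,
circle and ring ROIs on chosen slices. Intensities are integers so storage
is exact and read-back tests can demand identity, not approximation. UIDs
derive deterministically from patient ID and seed (default 20190101), so
regenerating a case is byte-identical. One generator option produces a
30°-rotated in-plane orientation to exercise the geometry code.

What the phantoms deliberately do **not** emulate: anatomy, noise,
scanner point-spread, multi-frame DICOM, or inconsistent clinical metadata.
Green tests therefore certify the geometry, numerics and provenance
machinery — not robustness to malformed hospital exports, which varies in
the wild far beyond what a synthetic suite can represent.

## Problem sizes and runtime

The test-suite geometry is deliberately desk-scale: rasterization agreement
runs 100 random ROIs on 3×20×20 grids at two spacings; texture oracles use
50 random ≤5³ level grids; the shape benchmark is a digitized r = 20 mm
sphere at 1 mm spacing (~33 000 voxels); the batch tests run three
16×32×32 sphere-lesion cases. The full suite and the acceptance script
each complete in well under a minute on a single CPU.

## Known limitations

* Only explicit-VR little-endian DICOM is read — the transfer syntax the
  generator writes. Compressed or implicit-VR clinical archives need
  conversion first.
* The 2-D maximum diameters use voxel centers, not mesh vertices.
* Surface area of thin (single-slice) regions is the staircase value.
* No filtered-image (LoG/wavelet) feature classes; no per-slice 2-D
  feature variants; no DICOM-SEG or RT Dose objects.
* The query engine is conjunctive only; negation, optional patterns and
  aggregation belong to external SPARQL stores.
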