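---
title: "Three-dimensional meniscus allograft sizing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-dimensional meniscus allograft sizing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menisize)
```

## The problem

Meniscus allograft transplantation replaces a removed meniscus with donor
tissue, and the size match between the native meniscus and the graft is a
major determinant of outcome: undersized grafts concentrate load, oversized
grafts extrude from the compartment. Conventional sizing reduces the meniscus
to two numbers — width and length — measured either on radiographs via the
tibia plateau (the Pollard rule) or on MRI. `menisize` implements a
three-dimensional alternative: the healthy contralateral meniscus, mirrored
to the affected side, serves as a 3D template, and donor menisci are ranked
by how closely their whole surface matches the template after rigid
superimposition.

The package provides four coupled components:

1. a mesh data model with anatomical metadata and root landmarks, plus
   PLY/STL/OBJ input and output;
2. root-aligned oriented-bounding-box (OBB) morphometry giving meniscal
   width, length and height, and the radiographic / 2D sizing rules;
3. rigid superimposition by the iterative closest point (ICP) algorithm with
   mean (MeSD) and maximum (MaSD, Hausdorff) surface distances;
4. a synthetic-bank generator and a leave-one-out validation pipeline that
   compares allograft selection by the three sizing methods against the best
   possible selection.

## Coordinate conventions and morphometry

Meshes live in a canonical right-handed anatomical frame in millimetres:
x = anterior–posterior (length), y = medio-lateral (width), z =
inferior–superior (height). The measurement box is deliberately *not* a free
minimal-volume OBB: its z-axis is pinned to the canonical superior direction
and the box is only rotated about z until its x-axis is parallel to the
projection of the anterior-to-posterior root line onto the x–y plane. The
extents are then tightened to the min/max vertex projections. Once the axes
are fixed this tightening has no residual freedom, so the whole measurement
is deterministic and needs no manual adjustment.

Two design points deserve justification:

* **The superior axis comes from metadata, not estimation.** Estimating
  "up" from an isolated meniscus surface is ill-posed (the tibial base and
  femoral face of a flat wedge are easily confused); meshes are required to
  arrive in the canonical frame, which any segmentation pipeline knows.
  Consequently the measurement is exactly invariant under z-rotations and
  translations, but not under arbitrary 3D rotations — those change what
  "height" means.
* **The root line uses the two landmark points as given.** Root attachment
  areas are not modelled; the landmarks are part of the mesh contract and
  must lie within 2 mm of the surface.

The 2D (axial MRI) measurement is the same box restricted to the x–y
footprint; optional Gaussian noise (off by default) lets experiments degrade
2D sizing independently of 3D sizing. The radiographic rule derives width as
the tibia plateau width and length as 80% (medial) or 70% (lateral) of the
plateau length.

## Surface distances

Two meshes are compared after rigid superimposition:

* sampling: area-uniform stratified sampling, about `density` points per
  mm^2 (default 4, about 5,000 points per adult meniscus). Each face has its
  own counter-based RNG substream seeded from the mesh identity and
  topology — never from the coordinates — so the sample pattern commutes
  exactly with rigid motions and repeated calls are reproducible.
* ICP: point-to-point correspondences solved in closed form per iteration
  (Kabsch). Correspondences are taken against the *surface* of the target
  (exact closest point on its triangles, via a bounding-volume tree) rather
  than against its sampled points: point-to-sample correspondences leave a
  sampling-noise floor that biases distances on exact matches, while
  point-to-surface correspondences register an exact copy to machine
  precision. Initialisation aligns centroids and principal axes, trying all
  four proper sign combinations and keeping the lowest initial RMS.
  Iteration stops when the RMS change falls below 1e-6 mm or after 100
  iterations; non-convergence returns the best transform with a warning, not
  an error.
* distances: after the converged transform, exact point-to-triangle
  distances are computed from each mesh's samples to the other's surface.
  MeSD is the larger of the two directed means; MaSD is the classical
  Hausdorff distance (larger of the two directed maxima). Both statistics
  therefore take the "highest value" of the two directions.

Because ICP is run in one direction, the pair is always evaluated in a
canonical internal order derived from pose-invariant mesh properties
(identity, topology, surface area); this makes `surface_distance(a, b)` and
`surface_distance(b, a)` bitwise identical and keeps the distances invariant
when either mesh is moved rigidly. A selected allograft is flagged a good
fit when MeSD < 1 mm and MaSD < 3 × MeSD.

Numerical notes: closest-point queries use an axis-aligned bounding-box tree
with branch-and-bound pruning and triangle-inequality warm starts (the
distance of a point can change by at most its own displacement between ICP
iterations), which keeps a full pairwise bank comparison tractable on one
CPU. Ties in selection rankings (scores within 1e-9 mm) are broken by the
smaller candidate id, a deterministic rule chosen for reproducibility.

## The synthetic bank

Real meniscus meshes come from manual MRI segmentation and cannot ship with
a package, so every downstream stage is exercised on a parametric generator
(`generate_base_mesh()`, `generate_patient()`, `generate_bank()`). The shape
family is a crescent: an elliptical centerline arc (span 300° medial, 330°
lateral — medial menisci are longer and more open, lateral menisci rounder)
swept with a triangular wedge cross-section (flat tibial base, vertical
peripheral wall of the requested height, tapering inner rim), modulated by a
smooth low-order random radial/height field (Fourier modes 2–4 along the
arc). Roots sit at the arc-endpoint apices. After perturbation the mesh is
rescaled anisotropically until its OBB dimensions match the request, so the
three printed dimensions are controlled independently of residual 3D shape —
exactly the degeneracy that makes 2D sizing fall short of 3D sizing. The
default tessellation (72 arc stations × 26 profile points, about 1,900
vertices) keeps OBB dimensions resolution-stable well below 0.1 mm.

Default population parameters reproduce published statistics of 140 healthy
menisci per side: medial width/length/height 31.6 ± 3.3 / 46.8 ± 3.7 /
9.3 ± 1.4 mm, lateral 31.7 ± 3.7 / 35.3 ± 2.8 / 9.9 ± 1.4 mm, width–length
correlation R² ≈ 0.31, height independent of width and length (no
height correlation is reported, so independence is the least-assumptive
choice).

Remaining generator parameters were fixed once, before any validation runs,
as follows:

* **Shape perturbation amplitude, 0.8 mm RMS.** Calibrated so that the
  all-pairs mean MeSD of a default bank falls inside 1.0–1.8 mm, the range
  reported for real banks (a default bank measures about 1.3 mm); exact
  replication of the real inter-subject distance cloud is not claimed.
* **Contralateral asymmetry amplitude, 0.3 mm RMS.** Left menisci are
  mirror images of the right plus an independent smooth field of this
  amplitude; it is small enough that the mirrored partner is the bank's best
  shape match for ≥ 90% of patients, the premise of contralateral
  templating.
* **Radiograph model.** Tibia plateau dimensions are back-computed from each
  knee's true meniscal dimensions by inverting the Pollard relations and
  adding Gaussian noise of SD 2.9 mm (width) and 3.8 mm (length) — the
  published prediction errors of the Pollard method. This realises exactly
  the stated radiographic error and nothing more; plateau anatomy is not
  modelled, and each side carries its own plateau values because a single
  shared plateau cannot satisfy both sides' calibration when the two menisci
  are drawn independently.

What the generator does **not** emulate: real segmentation artefacts
(staircase surfaces from 2–3 mm slices, partial ligament inclusion),
non-mirror-symmetric anatomical asymmetries, any width–height coupling, and
realistic tibio-femoral context. Passing tests therefore demonstrate that
the pipeline's geometry, bookkeeping and statistics are correct and that 3D
sizing dominates 2D sizing *under this shape model*; they do not certify
effect sizes on clinical data.

## The validation simulation

`generate_bank(params, 50, 40)` creates the study design: 50 bilateral
virtual patients (the validation group, 100 menisci per side) plus 40
unilateral donors, 140 bank entries per side, all mirrored to right-sided
models. For each validation meniscus, both same-side menisci of that patient
are excluded (pool of 138 — the contralateral template itself is never
selectable), and four selections are compared:

* **best** — gold standard: closest MeSD to the original mesh itself
  (100 × 138 = 13,800 MeSD evaluations per side);
* **mri3d** — closest MeSD to the mirrored contralateral mesh;
* **mri2d** — smallest width/length error sum of squares against the
  contralateral 2D measurement;
* **rx2d** — the same, with Pollard-derived dimensions from the ipsilateral
  radiograph.

2D templates are scored against the bank's 3D-measured width/length by
default (`use_2d_bank = TRUE` switches both sides to 2D measurements),
mirroring how a tissue bank would actually catalogue its grafts. Each
selected meniscus is compared with the original by MeSD/MaSD and absolute
width/length/height differences; outliers are differences > 5 mm (width,
length), > 4 mm (height) or MaSD > 5 mm, all strict inequalities. Summaries
report mean/min/max/SD per method and Welch t tests between methods,
Bonferroni-corrected over the pairwise family and capped at 1 (matching how
multiply-compared method tables report p = 1.000); a paired test would be
statistically tidier for matched-by-case values, but the independent-sample
form is kept for comparability, with the correction removable via
`n_comparisons = 1`.

All pairwise surface distances are cached by unordered pair — the dominant
cost. The default problem sizes are chosen for a single CPU: the full
50 + 40 study at sampling density 1 point/mm^2 (about 18,000 registrations)
runs in roughly ten minutes; unit tests use coarser tessellations and
smaller banks.

## Rater reliability

`icc_absolute_agreement()` implements the two-way absolute-agreement
intraclass correlation from the two-way mean squares. With only two raters
the single- and average-measures forms cannot be distinguished by the study
design, so the single-measures ICC(A,1) is the default and the
average-measures form sits behind `form = "average"`. Interpretation bands:
poor < 0.5, moderate 0.5–0.75, good 0.75–0.9, excellent > 0.9.

## Worked example

```{r example, eval = FALSE}
params <- population_params(seed = 42)
bank <- generate_bank(params, n_bilateral = 6, n_unilateral = 5)
res <- run_validation(bank, density = 1)
res$outliers
aggregate(mesd ~ side + method, data = res$comparisons, FUN = mean)
```

On a small bank like this the characteristic ordering already emerges: mean
MeSD increases from the gold standard through 3D-MRI and 2D-MRI to 2D-RX
sizing.

## Known limitations

* The superior direction is metadata; meshes in arbitrary orientation must
  be brought to the canonical frame before measurement (surface distances,
  in contrast, are fully pose-invariant).
* ICP is point-to-point without trimming: appropriate for menisci, which
  overlap fully after initialisation, but not for partial overlaps.
* Scale-adapted matching (shrinking or enlarging the template on purpose)
  is only available by pre-scaling the query mesh; it is not an
  optimisation variable.
* The selection criterion is the closest MeSD alone; combined MeSD/MaSD
  criteria are not implemented.
* Synthetic banks share a single mesh topology; code paths that would have
  to cope with heterogeneous real segmentations (holes, islands) only face
  them through the validation step of mesh loading.
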