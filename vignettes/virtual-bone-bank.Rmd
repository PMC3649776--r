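---
title: "Virtual bone bank matching: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual bone bank matching: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbbank)
```

`vbbank` selects the best-matching structural bone allograft for a host
from a bank of CT-derived 3D donor models. This vignette is the package's
own account of the underlying models: what each stage assumes, which
parameters matter, what the synthetic-anatomy generator does and does not
emulate, and where the design was genuinely open.

## 1. From CT volume to bone model

A `voxel_volume` is a 3D intensity grid with physical spacing and origin;
voxel `(i, j, k)` (0-based) has its center at `origin + (i, j, k) * spacing`.
The world frame follows the file header (NIfTI via RNifti, or a minimal
NRRD reader for axis-aligned raw/gzip files); oblique acquisitions are out
of scope.

Bone is isolated by **dual-threshold classification**
(`threshold_segment`): a voxel is bone when its intensity lies in
`[low, high]`. The default `low = 300` (HU-equivalent) reflects the usual
cortical-bone convention for CT; there is no interactive region editing,
which a human operator would add in a clinical segmentation suite.
`largest_component` (default 26-connectivity) then removes disconnected
structures — other bones, the table, artifacts. Ties between equal-size
components are broken toward the component containing the smallest linear
voxel index, so results are deterministic.

The surface is extracted by **marching tetrahedra** (`extract_surface`):
each grid cube is split into the six tetrahedra sharing its main diagonal
and the iso-crossing on each cut edge is placed by linear interpolation.
This produces the same sub-voxel accuracy as the classical cube-table
approach while needing no case tables, and it cannot produce the
ambiguous-face holes that naive cube tables allow: the output is closed
and consistently outward-oriented whenever the iso-surface stays inside
the grid. For a binary mask the iso level defaults to 0.5, which places
the surface midway between inside and outside voxel centers — an unbiased
estimator of the true boundary, which is why enclosed volumes come out
within a fraction of a percent at 0.5 mm spacing (the test suite checks
1% on a 20 mm sphere; the measured error is about 0.3%). An optional
Gaussian pre-smoothing (`smooth_sigma_vox`, default 0 = off) is available
for noisy masks.

Two numerical details matter:

* Field values exactly equal to the iso level would place surface
  vertices exactly on grid points and create zero-area triangles that
  collapse under vertex merging (e.g. after an STL round-trip). Such
  values are nudged just below the level by `1e-4` of the field range —
  a geometric perturbation of a few micrometres at CT scales.
* Voxelization of a closed mesh (`rasterize_to_volume`) uses parity
  counting along +z rays through every voxel column, with a small fixed
  sub-voxel ray offset so rays never hit triangle edges exactly. Open
  meshes are rejected: inside/outside is undefined for them.

## 2. Mirror model and chirality bookkeeping

Tumoral hosts are geometrically incomplete, so the healthy contralateral
bone, reflected across the sagittal plane, serves as the geometric target.
`mirror_mesh` reflects vertices and reverses face winding, preserving
outward orientation; `mirror_landmarks` reflects the six points and keeps
their anatomical names (medial stays medial — reflection converts
left-side geometry into right-side geometry).

Reflections live *only* in the mirror operations. `rigid_transform`
refuses determinant −1 matrices, so no registration step can silently
flip a bone's handedness; screening by default only offers donors of the
same chirality as the resected side (`allow_contralateral` relaxes this).
The sagittal plane is a user input (the synthetic frame uses `x = 0`);
automatic symmetry-plane estimation is deliberately out of scope.

## 3. ABC landmarks and size screening

Six landmarks define three distances: `A = ‖ME − LE‖` (transepicondylar
width), `B = ‖MA − MP‖` (medial condyle anterior–posterior depth),
`C = ‖LA − LP‖` (lateral condyle AP depth). The landmark identities —
the epicondyle pair for A and the anterior/posterior extremes of each
condyle for B and C — are the only pairing consistent with the
measures' names; 3D Euclidean distances are used rather than projected
ones. Landmarks are operator inputs (JSON files); automatic detection is
a non-goal.

Screening ranks donors by `sqrt(wa·ΔA² + wb·ΔB² + wc·ΔC²)` with unit
default weights; "closest" admits several readings, so a `maxabs` metric
(largest weighted per-measure deviation) is exposed as an option, and
nearest-*k* (default `k = 5`) rather than a tolerance window is the
default forwarding rule. Ties are broken lexicographically by donor id,
making the ordering a total, deterministic one — the test suite holds it
equal to an exhaustive sort oracle, ties included.

## 4. Rigid registration

Initialization is closed-form landmark alignment (Kabsch with the sign
correction that excludes reflections) when both sides carry landmarks.
For diaphyseal and transepiphyseal segments, where natural landmarks
cannot be placed reliably, `principal_axes_init` aligns centroids and
principal axes and resolves the four proper axis-sign candidates by the
smallest post-alignment mean distance. Near-degenerate inertia (adjacent
principal-moment ratio below 1.01 — e.g. a sphere) triggers a warning and
a centroid-only fallback. Note that near-symmetric shapes make the sign
choice genuinely ambiguous; the refinement step resolves small
ambiguities but cannot rescue a 180° flip of a truly symmetric bone.

Refinement is **trimmed ICP** (`icp_register`): per iteration, (a) every
transformed source point finds its exact closest point on the target
surface (point-to-triangle via a bounding-volume hierarchy — never
point-to-vertex, because host and donor tessellations are unrelated),
(b) the worst `trim_fraction` of correspondences are discarded, (c) the
rigid transform is refit in closed form on the retained pairs. The
trimmed mean distance is non-increasing across iterations and
convergence is declared when it changes by less than
`convergence_tol_mm`.

Parameters, units and defaults:

| parameter | default | rationale |
|---|---|---|
| `trim_fraction` | 0.1 | tumoral hosts are partial; 10% absorbs moderate missing area, 0.2 suits large defects |
| `sample_size` | 5000 points | mean-distance standard error well under 0.01 mm on decimetre bones |
| `convergence_tol_mm` | 1e-4 mm | far below voxel noise; stops in tens of iterations |
| `max_iterations` | 100 | safety bound |
| `seed` | 1 | controls surface subsampling only |

Scaling is never estimated: the clinical question is whether the donor
*is* the right size, so a similarity fit would hide exactly the mismatch
being measured.

## 5. Match score and colorimetric mapping

`surface_distances` computes unsigned distances from host-mirror surface
samples to the registered donor surface. The direction is host→donor by
design: the host model may be incomplete, so donor→host distances would
penalize donor regions the host simply lacks. The headline score is the
**mean** distance; RMS, the 95th percentile (linear interpolation between
order statistics) and the one-directional maximum are reported but do not
drive the ranking. Ranking ties fall back to donor id.

`colorimetric_export` writes per-vertex colors
`colormap((clamp(d) − lower)/(upper − lower))` with a 0–5 mm default
range and a diverging palette; a JSON legend accompanies every PLY so the
scale stays interpretable. The workflow colors the *donor* surface by its
vertices' distances to the registered host mirror — the natural surface
to inspect — while the score itself remains host→donor.

## 6. The synthetic anatomy generator

No clinical data ships with the package; `generate_femur` provides a
parametric distal-femur-like shape so every stage is testable end to end.
The shape is the smooth union (polynomial smooth-minimum, 8 mm blending
radius) of two condylar ellipsoids and a shaft capsule, meshed by
marching tetrahedra over its signed-distance field in a fixed frame:
x = medial–lateral, y = anterior–posterior, z = proximal–distal, sagittal
plane at x = 0. The A, B, C parameters are generative ground truth:
landmarks are placed by construction so `compute_abc` returns them
*exactly* at zero noise, and `side = "left"` is the exact mirror of
`side = "right"`. Surface noise displaces vertices along outward normals;
landmark placement uncertainty is drawn with per-coordinate standard
deviation `noise_sd/√2`, calibrated so each ABC measure has standard
deviation ≈ `noise_sd`. Tumor-like defects (`apply_defect`) remove all
vertices within a sphere and leave the boundary open — no hole filling —
to emulate incomplete tumoral models.

Bank generation draws ABC triples from independent normals (defaults
80/60/62 ± 4/3/3 mm, an adult distal-femur population), rejection-sampled
to keep each donor plausible (positive, condylar depths ≤ width), and the
stored table is always re-measured from the stored landmark files.
Regeneration from the same seed is byte-identical.

What the generator does **not** emulate: real cortical/trabecular
intensity structure (rasterized volumes are binary plus optional Gaussian
noise), anatomical shape variation beyond three diameters, cartilage,
soft tissue, or metal artifacts. Passing tests therefore demonstrate the
*pipeline's* geometric correctness — sub-voxel reconstruction, exact
mirror bookkeeping, metric fidelity, robust registration — not clinical
segmentation performance on pathological scans.

## 7. Validation conditions and problem sizes

The package's tests and the `scripts/acceptance.R` report run at the
acquisition conditions the workflow targets — 0.5 mm voxels for
reconstruction fidelity checks — and at these sizes, chosen as the
package's own validation design: spheres of r = 20 mm (analytic oracle),
synthetic femurs meshed at 2–2.5 mm, ICP with 2000–5000 source points,
screening oracles over hundreds of random banks of up to 50 donors, and
planted-donor recovery over seeded end-to-end trials (banks of 10, one
donor sharing the host's parameters, surface noise 0.2 mm). In every
trial the planted donor must outrank nine decoys, and inflating it by
+5 mm in all three dimensions must strictly worsen its mean score.

## 8. Known limitations

* Rigid-only registration; no non-rigid or affine modes.
* Global thresholding cannot reproduce an operator's manual edits; very
  low-contrast (osteopenic) bone may need a lowered threshold.
* Landmark-free initialization can pick a flipped pose on nearly
  symmetric segments.
* The distance direction choice (host→donor) means a donor strictly
  larger than the host scores well at equal shape; clinical judgment on
  oversize tolerance stays with the surgeon, aided by the per-measure
  deltas reported at screening.
* STL files carry no units; millimetres are assumed throughout.
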