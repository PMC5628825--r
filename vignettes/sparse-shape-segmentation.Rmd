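---
title: "Sparse prior statistical shape models for CT organ segmentation"
author: "spssm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse prior statistical shape models for CT organ segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spssm)
```

## The model

`spssm` segments a blob-like organ (prototypically the liver) from a CT-like
volume by deforming a statistical shape prior that is expressed *sparsely*: a
patient's surface is reconstructed as a sparse weighted combination of whole
training shapes rather than as a mean shape plus PCA modes. The motivation is
that PCA truncation smooths away exactly the high-curvature corners and
grooves where livers are hardest to segment, while a sparse combination of a
few whole exemplars preserves them.

The pipeline has three stages.

**1. Prior normalization and dictionaries.** Training surfaces with shared
vertex correspondence (established, if needed, by
`downsample_with_correspondence()`: quadric decimation of a reference member,
then closest-surface-point mapping after rigid-ICP pre-alignment) are aligned
by generalized Procrustes analysis (`gpa()`): iterate
translate-to-origin, similarity-align to the running mean, recompute the mean
`S_bar = (1/k) sum S_i`, rescale the mean to unit centroid size, until the
mean stops changing. Fixing the mean's scale each round is the classic guard
against the shrink-drift degeneracy of unnormalized GPA. The aligned family
is stacked column-wise into the shape dictionary `D_S` (one flattened shape
per column, vertex-major with xyz contiguous) and its row restriction to the
seven landmark vertices forms the landmark dictionary `D_L`.

**2. Sparse instantiation from landmarks.** Seven named anatomical mark
points (hepatic dome, right-lobe tip, porta hepatis, ...) are observed in the
target image. `fit_transfer()` alternates (a) a similarity transform carrying
the observed points into the aligned model frame (pairwise Procrustes on the
seven-point sets) and (b) orthogonal matching pursuit of the transferred
observation against `D_L` under a hard sparsity budget `k1`, optionally with
a sparse error vector `e` (budget `k2`) that absorbs grossly mis-placed
landmarks. Applying the code to `D_S` and inverting the transfer instantiates
the full surface in image coordinates — the initialization is therefore
already patient-shaped and patient-posed.

**3. Energy-driven deformation.** Each iteration moves every vertex along its
outward normal by a gated sum of two data terms, then applies one Laplacian
smoothing pass:

* *Region (intensity) energy.* A five-component weighted Gaussian mixture is
  fit by EM to the volume histogram (background excluded by an Otsu
  threshold); the organ component is the one with maximal peak height
  `w/sigma`, and its band is `mu +/- 1.5 sigma`. The region term walks the
  profile outward from the vertex while consecutive samples stay in band and
  proposes that distance — a pure inflation force inside the organ, zero
  outside it.
* *Boundary (edge) energy.* An `M = 31` sample profile is searched with an
  `m = 11` sample window. The *statistical* term scores each window position
  by trained per-vertex profile statistics (`mu_ij`, `sigma_ij` over the
  training pairs, kernel-weighted Gaussian likelihood); the *specific* term
  scores inner/outer contrast (`f1`, kernel-weighted absolute mean
  difference) plus inner/outer spread difference (`f2`). Both are min-max
  normalized to unit sum and combined with weights `alpha = beta_w = 0.5`;
  the argmax window, converted to a signed offset from the profile centre,
  is the proposed displacement.
* *Sparse-matching gate.* Training volumes are filtered per-slice with a
  small Gabor bank; `9 x 9 x 3` patches at training boundary vertices are
  standardized and compressed into a K-SVD dictionary. At run time each
  vertex's patch is sparse-coded and its reconstruction error `L` gates the
  vertex: `omega = 0` when `L <= sigma_gate` (the vertex has found
  boundary-like texture and its data terms switch off), `omega = L`
  otherwise. Displacements are scaled by `omega / max(omega)` and capped at
  one profile step per iteration. The run stops when every gate is closed,
  when displacements plateau, or at 50 iterations.

## Design choices in the open corners

Several components are under-determined by the method description; the
choices below are the package's own, made once and kept.

* **Gabor response combination.** The bank's per-kernel responses are
  combined as the *sum of even-phase (real-part) responses*, a signed
  band-pass edge feature. The seemingly natural alternative — the maximum
  response *magnitude* — produces a smooth, everywhere-positive field whose
  standardized patches are easier to reconstruct in the organ interior than
  on the boundary, which inverts the gate's discrimination: measured on
  phantoms, 99 % of vertices 6 mm *inside* the organ gated versus 83 % on
  the boundary, and the model froze several millimetres short. With the
  signed even-phase feature the ordering is correct (86 % gated on the
  boundary versus 4–11 % at ±4 mm).
* **Patch standardization.** Patches are mean-subtracted and scaled to unit
  norm before coding, in training and at run time alike. The raw
  reconstruction error is scale-dependent: near-flat interior patches have
  tiny norms and therefore tiny errors, so an unstandardized gate closes in
  featureless regions first. After standardization the error measures
  texture match; a patch with no structure at all scores the maximal error 1
  and never gates.
* **Gate threshold.** `sigma_gate` is the 60th percentile of the training
  patches' own reconstruction errors. The patch window (13.5 mm in-plane at
  1.5 mm voxels) contains the boundary ridge well before the vertex is
  centred on it, so permissive thresholds (90th percentile) gate vertices
  1–3 mm early; the stricter quantile trades later gate closure for a
  measurably closer fit (phantom VOE 11 % to 6–8 %).
* **Gating and smoothing.** Gating zeroes a vertex's *data* displacement
  only; the Laplacian smoothing pass still couples it to its neighbours, and
  gates are re-evaluated every iteration. A vertex frozen in place outright
  can never re-open its gate (its patch never changes); with smoothing
  coupling, a wrongly-gated vertex is dragged along by its neighbours onto
  fresh image content and re-opens. The all-gated state returns unchanged
  and is the fixed point that stops the run.
* **Profile reach.** `M = 31` samples at 1 mm (reach ±15 mm). Landmark fits
  under 3 mm landmark noise can start more than 10 mm from the true surface;
  a ±10 mm profile cannot see the boundary from there.
* **Region-walk convention.** The in-band walk starts at the centre sample
  and moves outward only; an out-of-band centre proposes zero. Other
  readings (walking the whole profile) double-count the edge term's job.
* **Normalization of energies.** "Normalization" is concretized as min-max
  to `[0, 1]` followed by scaling to unit sum; all-equal inputs degenerate
  to the uniform vector, which makes ties explicit and keeps the combination
  well-defined on constant profiles.
* **Numerical floors.** Profile SDs are floored at `1e-3` intensity units
  (the trained likelihood would otherwise be singular wherever training
  volumes agree exactly); EM variances are floored the same way and flagged.
  Reflection cases in the Procrustes rotation are corrected by flipping the
  smallest-singular-value column, so `det(R) = +1` always.
* **Eq-level conventions.** The planar Procrustes formulas are applied in
  3-D by summing the z term analogously; the profile formula is read with
  `u` the unit normal direction and `L` the total physical profile length
  (any other reading double-counts the spacing); vertex indices are 0-based
  in landmark files and 1-based in R objects.

## The phantom generator

Real abdominal CT with expert contours cannot ship with a package, so every
stage is exercised on synthetic phantoms built by `phantom_spec()` /
`generate_training_bundle()`:

* **Shapes.** An icosphere (642 vertices by default) radially perturbed by
  low-order spherical-harmonic modes (l = 2, 3) with per-shape Gaussian
  coefficients (SD 0.03 relative radius, mean radius 60 mm). Shared topology
  gives exact correspondence; seven landmarks sit at fixed parametric
  extremes (pole, antipode, equatorial extremes) named after the anatomical
  groups.
* **Volumes.** 128³ voxels at 1.5 mm. Five intensity classes emulate the
  five histogram modes the intensity model assumes: air-like background
  (20 ± 12), a fat/body ellipsoid (70 ± 22), the organ (120 ± 8), an
  *adjacent confounder* ellipsoid whose mean sits only 20 units above the
  organ (emulating the spleen/stomach problem), and a bone-like ellipsoid
  (220 ± 15); independent Gaussian noise (SD 4) is added on top. Gold masks
  come from the exact voxelization of the generating mesh (centre-inside
  rule).
* **Landmark noise.** Held-out test landmarks are jittered by a configurable
  SD (3 mm in the standard study), emulating imprecise manual mark-point
  selection.

What the phantoms deliberately do **not** model: lobed liver geometry and
concave grooves, partial-volume and reconstruction artefacts, anisotropic
slice spacing, intensity inhomogeneity, lesions, and contact surfaces with
more than one confounder. Passing the phantom suite therefore demonstrates
that the machinery is implemented correctly and converges under the model's
own assumptions — not clinical-grade accuracy on real CT.

## Problem sizes and runtime

The standard study (20 phantoms, each with its own 8-member family,
leave-one-out training, 128³ volumes) was chosen so the whole suite trains
and segments in minutes on one core: per case, volume synthesis takes a few
seconds, prior training a few seconds (the Gabor transforms dominate, so the
patch dictionary pools patches from an evenly spaced subset of 4 training
volumes), and the deformation about 0.2 s per iteration for 642 vertices.
Surface metrics use exact nearest-neighbour distances between border-voxel
point sets (computed blockwise with BLAS), so ASSD/RMSSSD/MSSD on 128³ masks
cost a few seconds per case.

## Known limitations

* Axis-aligned volumes only; no direction cosines (the method never uses
  them, but oblique NIfTI files are refused rather than resampled).
* The gate needs boundary texture that is distinguishable from the interior
  in the Gabor domain; on very small organs (under ~25 voxels radius) the
  kernel envelope spans most of the object and gating degenerates — the
  filter frequencies and patch size must then be raised/shrunk via the
  configuration.
* The sparse shape space is spanned by the training family: a target organ
  far outside the family's convex-ish hull cannot be instantiated well, and
  the deformation stage can only recover errors within the profile reach.
* `run_segmentation()` typically stops at the iteration cap with a minority
  of gates still open (sub-voxel oscillation of the remaining vertices), so
  the cap and the plateau tolerance are part of the stopping contract, not
  merely safety rails.
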