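# spssm — sparse prior statistical shape models for CT organ segmentation

`spssm` is an R implementation of liver-style CT organ segmentation with a
**sparse a-priori statistical shape model**: instead of a mean shape plus PCA
modes, a patient's surface is written as a sparse weighted combination of
whole training shapes,

```
argmin_{x, e, beta}  || T(y, beta) - D x - e ||_2^2    s.t. ||x||_0 <= k1, ||e||_0 <= k2
```

where the columns of `D` are vertex-corresponding prior surfaces aligned by
generalized Procrustes analysis, `y` holds seven named anatomical mark points
observed in the target image, `T(., beta)` is a similarity transfer into the
model frame, and `e` absorbs grossly mis-placed landmarks. The instantiated
surface then deforms iteratively under

```
F_external = omega_external * ( E_edge + E_region )
```

with `E_region` an outward walk inside the organ's intensity band (from a
five-component weighted Gaussian mixture of the histogram, organ component =
maximal peak height `w/sigma`, band `mu +/- 1.5 sigma`), `E_edge` the argmax
of a trained profile-statistics term plus an inner/outer contrast term along
each vertex normal, and `omega_external` a per-vertex gate from the sparse
reconstruction error of the vertex's Gabor-domain patch against a K-SVD
boundary dictionary — a vertex whose patch "looks like boundary" stops
moving, and the run ends when all gates close or displacements plateau.

The package ships mesh/volume/landmark I/O (PLY/OBJ/STL, NIfTI/MetaImage,
JSON), the full training and segmentation pipeline, the standard evaluation
metrics (VOE, RVD, ASSD, RMSSSD, MSSD with challenge-style scores), a
synthetic CT phantom generator so everything is testable without external
data, and a small command line front end (`inst/exec/spssm.R` with
`simulate`, `build-priors`, `segment`, `evaluate`).

It is aimed at researchers in medical image analysis who want a fully
inspectable, dependency-light reference implementation of sparse shape
composition with appearance-driven deformation.

## Worked example

Everything below runs from scratch in about half a minute; the phantom study
generates its own training family, trains the dictionaries, and segments a
held-out case whose landmarks were jittered by 3 mm.

```r
library(spssm)

spec   <- phantom_spec(seed = 11, landmark_jitter = 3)   # k = 8 priors, 128^3 volume
bundle <- generate_training_bundle(spec)                 # leave-one-out split
priors <- train_priors(bundle$train$shapes, bundle$train$volumes,
                       bundle$landmark_indices)
seg    <- run_segmentation(bundle$test$volume, priors, bundle$test$landmarks)
print(seg)
#> <spssm_seg> 50 iterations (iteration cap); 642 vertices; 252723 voxels segmented

report <- evaluate_segmentation(seg$mask, bundle$test$mask,
                                spacing = bundle$test$mask$spacing)
print(report)
#> <metrics_report>
#>   VOE       6.75 %   (score  73.6)
#>   RVD      -6.57 %   (score  65.0, |RVD| = 6.57)
#>   ASSD      1.45 mm  (score  63.9)
#>   RMSSSD    1.65 mm  (score  77.1)
#>   MSSD      4.74 mm  (score  93.8)
#>   total score  74.7
```

`VOE` is the volumetric overlap error between the segmented and gold masks
(0 % = perfect); `RVD` the signed relative volume difference; the three
surface distances are the mean, RMS and maximum of exact nearest-neighbour
distances between the masks' border voxels in mm. The scores map each error
onto a 0-100 scale (100 = perfect, 75 at the reference error). A mean VOE of
~7 % on a 60 mm organ at 1.5 mm voxels corresponds to a mean surface error
around one voxel.

`plot(seg)` shows the per-iteration mean displacement and the fraction of
gated vertices; `summary(seg)` adds the fitted intensity band and the sparse
landmark fit.

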