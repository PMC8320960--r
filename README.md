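# mcclassify

Computer-aided diagnosis of clustered microcalcifications (MCs) in 2-D
mammogram patches.  MCs are bright calcium deposits a few pixels wide;
a cluster — clinically, at least three MCs within 1 cm² — is one of the
earliest mammographic signs of breast cancer, and its morphology and
spatial arrangement separate benign from malignant disease.  The package
is aimed at medical-image-analysis researchers who want a fully tested,
reproducible reference implementation of a classical morphology-plus-
ensemble CADx chain that runs end-to-end without any clinical image
database.

The pipeline:

1. **Enhancement** — 3-level separable db4 wavelet decomposition; detail
   sub-bands amplified by a gain driven by the scalar sharpness index
   `SSI = Σ w·TLE_ℓ` (per-level total log-energies, weight `w = 0.10`),
   boosting blurrier images more.
2. **Segmentation** — local background estimated by per-30×30-subregion
   medians with bicubic-spline upsampling; Image A = top 5% of positive
   background differences (single-pixel removal, 3×3 erosion, a
   low-contrast fallback at half the recorded threshold when coverage
   < 10%); Image B = top 5% of the response to a zero-sum 9×9
   contrast-enhancement kernel (centre 80); Image C = A AND B.
3. **Cluster rules** — components of ≤ 2 px removed, 2×2 erosion,
   8-connected labeling; the patch is tiled into 1 cm² blocks
   (`round(10000/spacing_µm)` px: 143 @ 70 µm, 200 @ 50 µm) and every
   block with fewer than 3 blob centroids is emptied.
4. **Evaluation** — Dice overlap between the filled convex hull of the
   segmented MCs inside the radiologist outline and the outline mask.
5. **Features** — an ordered 51-slot descriptor (17 size, 17 shape, 17
   texture: geometry aggregates, centroid-distance statistics,
   first-order and gray-level co-occurrence texture).
6. **Selection** — CFS merit `k·r̄_cf / √(k + k(k−1)·r̄_ff)` with
   best-first search; features selected from both the unenhanced (α) and
   enhanced (β) tables, keeping the intersection; refitted per training
   fold inside CV.
7. **Classification** — nine base learners (kNN k=5, MLP, tree, random
   forest, naive Bayes, four SVM kernels); majority-vote ensemble
   (malignancy fraction = votes/9) and stacked generalization with a
   naive Bayes meta-classifier on out-of-fold votes; stratified 10-fold
   CV repeated over seeds 1, 2, …, reporting accuracy and rank-based AUC
   as mean ± sd.

A synthetic phantom generator (`generate_dataset()`) produces
ground-truth patches whose benign/malignant morphology axes (count,
size variance, irregularity, dispersion, linear arrangement) carry the
class signal, so every stage is testable offline.  See the methods
vignette (`vignettes/mc-cadx-methods.Rmd`) for models, parameters and
design decisions.

## Worked example

```r
library(mcclassify)

samples <- generate_dataset(n_benign = 15, n_malignant = 15, effect = 1, seed = 42)
s <- samples[[16]]                       # a malignant phantom
s$patch
#> <image_patch 'malignant_001'> 160 x 160 px, 70 um/px, 12-bit, range [341, 662]

seg <- segment_patch(s$patch)            # Images A/B/C + cluster rules
seg$blobs
#> <blob_set> 14 blobs, 125 pixels

evaluate_segmentation(seg$mask, s$outline)
#> <dice_report> dice = 0.6545 (TP 679, FP 0, FN 717)

report <- run_pipeline(samples, pipeline_config(seeds = 1:3))
report
#> <pipeline_report> 30 samples (30 used, 0 excluded), config cfcb16e0
#>   selected features: cluster_hull_area, cluster_density, centroid_dist_mean,
#>     blob_eccentricity_sd, blob_elongation_mean, cluster_elongation,
#>     cluster_solidity, intensity_range
#>   stacked:  <eval_report> stack / 10fold on 30 samples (3 runs)
#>   accuracy 100.00 +/- 0.00 %   AUC 1.000 +/- 0.000
#>   ensemble: <eval_report> ensemble / 10fold on 30 samples (3 runs)
#>   accuracy 100.00 +/- 0.00 %   AUC 1.000 +/- 0.000
```

Reading the output: 14 MC candidates survived the clinical cluster rule
on this patch; the hull of the detections overlaps the (deliberately
dilated) annotation with Dice 0.65 — eroded blob cores cover the cluster
extent but not every annotated pixel; and on 30 well-separated phantoms
both classifiers are at ceiling.  At this sample size a 100% accuracy
simply reflects the generator's default effect size — the chance-level
control (`effect = 0`) sits near 50%.

The command-line front end wraps the same functions:

```sh
inst/scripts/mcclassify synth --n-benign 10 --n-malignant 10 --out data/
inst/scripts/mcclassify segment --in data/benign_001.pgm --spacing 70 \
    --out-mask seg.png --out-blobs blobs.csv
inst/scripts/mcclassify run --n-benign 30 --n-malignant 30 --out run1/
```

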