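---
title: "Methods: microcalcification cluster segmentation and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microcalcification cluster segmentation and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mcclassify)
```

Clustered microcalcifications (MCs) — groups of small, bright calcium
deposits a few pixels wide — are among the earliest mammographic signs of
breast cancer, and the morphology and spatial arrangement of a cluster
carry most of the benign/malignant signal a radiologist reads.  This
package implements a complete computer-aided diagnosis chain for 2-D
mammogram patches: contrast enhancement, MC candidate segmentation with a
clinical cluster rule, a fixed 51-slot feature descriptor,
correlation-based feature selection, and ensemble / stacked
classification with cross-validated reporting.  This vignette documents
the model behind each stage, the tunable parameters and their defaults,
the numerical choices, what the synthetic phantoms do and do not emulate,
and the design decisions taken where the method left room.

## Wavelet enhancement

The patch is decomposed with a 3-level separable Daubechies-4 discrete
wavelet transform.  For each level the log-energies
$E_{\ell,o} = \ln(\varepsilon + \sum c^2)$ of the three orientation
sub-bands are summed into a total log-energy (TLE), and the scalar
sharpness index is the weighted combination
$\mathrm{SSI} = \sum_\ell w\,\mathrm{TLE}_\ell$ with per-level weight
$w = 0.10$.  Higher SSI means a sharper image.  Detail coefficients are
then amplified by the gain

$$g = \max\!\left(1,\; 1 + w\,\frac{\mathrm{SSI}_{\mathrm{ref}} - \mathrm{SSI}}{|\mathrm{SSI}_{\mathrm{ref}}|}\right),$$

so images blurrier than a sharp reference receive a stronger boost and
images already at reference sharpness pass through unchanged; the
reconstruction is clipped to the bit-depth range.  The reference SSI
defaults to that of the package's default synthetic phantom
(`reference_ssi()`) and is configurable.  The gain law itself is this
package's instantiation — the published description fixes the constants
(3 levels, weight 0.10, weights above 0.8 giving no further benefit,
which we enforce as `weight` $\le 0.8$) but not the exact filtering
equation — so the enforced contracts are the property-level ones: exact
decompose/reconstruct round trip, identity at weight 0, contrast gain on
blob phantoms monotone in the weight, and SSI ordering sharp > blurred.

Two numerical choices matter here.  First, the transform is implemented
as an orthonormal periodized (circulant-matrix) filter bank: the inverse
is the transpose, so perfect reconstruction holds to machine precision
for any image size (odd extents are padded by edge reflection per level
and cropped back, which preserves exactness).  We chose periodization
over symmetric extension because the Daubechies-4 filter is not
symmetric, and exact invertibility is a contract we test at `1e-8`.
Second, sub-band gains are applied uniformly across levels; with
`levels = 3` and `weight = 0.10` the boost is mild by construction.

## MC candidate segmentation (Images A, B, C)

The segmentation estimates the local tissue background, subtracts it,
and keeps pixels that are bright *relative to their neighbourhood*:

1. **Background surface.** The patch is tiled into 30 × 30-px subregions
   (last row/column truncated), each summarised by its **median** — robust
   against the very calcifications the surface must not absorb — and the
   coarse grid is interpolated back to full resolution with a separable
   natural cubic (bicubic) spline.  30 px trades off over- against
   under-segmentation: larger subregions leak cluster brightness into the
   surface in low-contrast patches, smaller ones absorb the MCs
   themselves.
2. **Image A.** Among strictly positive difference pixels the top 5% are
   selected; the smallest selected value is recorded as the threshold
   $t$.  Isolated single pixels are removed and a 3 × 3 all-ones erosion
   applied.  If the surviving mask covers less than 10% of the patch, the
   low-contrast fallback adds all pixels with difference above $t/2$ —
   the guard against under-segmentation of badly exposed images.
3. **Image B.** A 9 × 9 contrast-enhancement kernel — centre 80, all 80
   off-centre entries $-1$, hence zero-sum — is applied with symmetric
   boundary handling, and the top 5% of the response is kept.
4. **Image C** is the pixelwise AND of A and B.

One genuinely open point was *which* image the 9 × 9 kernel filters.
Reading it as the blob-suppressed background surface makes Image B a map
of smooth background curvature, statistically independent of the MCs, and
the conjunction A∧B then destroys nearly every true detection — it would
break the pipeline's own recovery contract.  We therefore filter the
patch itself (equivalently, its bicubic resampling at native resolution,
which is the identity): the kernel then responds exactly at sharp bright
spots, and Image B acts as a sharpness gate on the brightness gate of
Image A.  `highpass_filter()` remains a pure operation on any 2-D grid.

Percentile cut-offs use `ceiling(fraction * n)` with ties broken in
raster (row-major) order, making every mask deterministic across
platforms.

## Clinical cluster rules

A cluster is clinically significant when at least three MCs share a
1 cm² area.  At pixel spacing $s$ µm the block side is
$\mathrm{round}(10000/s)$: 143 px for 70 µm digital detectors, 200 px for
50 µm digitized film.  Image C is pre-cleaned (components of one or two
pixels removed as artifacts, then a 2 × 2 all-ones erosion), 8-connected
components are labelled, the patch is tiled into blocks from the top-left
(last row/column truncated), each blob is assigned to the block holding
its **centroid**, and every block with fewer than `min_per_block = 3`
blobs is emptied.  Two conventions we fixed: the even 2 × 2 erosion
element has no centre, so its origin is anchored at the top-left cell
(deterministic and documented); and boundary-straddling objects count in
the block of their centroid, which is unambiguous and counts whole
objects.  A `block_side = 100` override reproduces the non-clinical
100-px-block variant; sliding-window block placement is out of scope.

## Segmentation evaluation

Reference masks are filled annotation polygons (boundary pixels
included).  Segmented blobs whose centroid lies inside the reference
contribute all their pixels to a convex hull, and the filled hull is
scored against the reference with the Dice coefficient
$2|X \cap Y|/(|X|+|Y|)$.  Two empty masks score 1 (perfect agreement on
absence).  Hulls of fewer than three non-collinear pixels degrade to the
pixels themselves.

## The 51-feature descriptor

Features describe either individual MCs (aggregated over the cluster) or
the cluster as a whole, in three categories of 17 — size, shape, texture
— with a fixed order and naming held in `feature_registry()` (also
exported as CSV by the pipeline for auditability).  The clinically named
quantities — summation of per-MC mean intensities, variance of the
centroid distances, cluster convex-hull area, mean MC perimeter, total
cluster area, mean MC size — occupy explicit slots; the remaining slots
are standard aggregates (mean/sd/min/max) of per-blob geometry, and
first-order plus gray-level co-occurrence texture statistics.

Conventions: perimeters are inner-boundary crack lengths (each exposed
pixel edge counts 1, a reproducible integer); circularity $4\pi A/P^2$
uses the Euclidean perimeter estimated as crack length × π/4 so a disk
scores ≈ 1; eccentricity and elongation come from second central moments
with the 1/12 pixel-variance term; single-pixel blobs are imputed
(eccentricity 0, elongation 1, circularity 1, solidity 1) so vectors stay
finite; "variance of the distances" is the variance of per-blob
centroid-to-cluster-centroid distances.  GLCM features use 32 gray levels
quantized over the observed range of the cluster bounding box (bit-depth
independent — rescaling intensities leaves them bit-identical), symmetric
counts at distance 1, averaged over the four offsets.  Cluster hull area
is the rasterised hull pixel count, which exceeds the polygon (shoelace)
area by roughly half the hull perimeter; tests compare the two at that
tolerance.

## Feature selection

Subset merit follows the correlation-based form
$\mathrm{Merit}(S) = k\,\bar r_{cf} / \sqrt{k + k(k-1)\bar r_{ff}}$,
rewarding feature–class correlation and penalising redundancy.
Correlations are absolute point-biserial (feature vs class) and Pearson
(feature–feature) — a continuous-data simplification of the
discretised symmetric-uncertainty variant, swappable behind
`correlation_tables()`.  Search is best-first from the empty set with
single-feature additions and deletions and a stale limit of 5
consecutive non-improving expansions (the customary default), with ties
broken by feature order.  On up to 12 features it matches exhaustive
enumeration on all tested random instances.  The α∩β protocol selects on
the unenhanced-patch table (α) and the enhanced-patch table (β) and
keeps the common features; an empty intersection falls back to α with a
warning.  Inside cross-validation, selection is refitted on every
training fold so no test information leaks into the feature choice.

## Classification

Nine base learners vote benign/malignant: kNN (k = 5), an MLP with
(n_features + n_classes)/2 hidden units, a classification tree, a
100-tree random forest, naive Bayes, and SVMs with RBF, sigmoid, linear
and polynomial kernels.  Remaining hyperparameters are library defaults;
we note that the tree is `rpart` (CART) rather than C4.5 — the published
confidence 0.25 / 3 pruning folds have no direct counterpart — and the
MLP is BFGS-trained `nnet`, so the printed learning rate 0.3 and
validation threshold 20 (consecutive worsening epochs, in their original
tool's semantics) likewise do not transfer; the hidden-layer rule does.
The 100-tree forest is the default of the toolkit the method was
originally run in.  Features are z-scored on the training fold for kNN
and the MLP; SVMs scale internally; SVM votes come from the predicted
class with decision values as scores.

The **ensemble** divides malignant votes by the total (9): eight of nine
gives 8/9 ≈ 89% malignancy, and the label is malignant above 0.5 (a tie
is impossible with an odd count).  **Stacked generalization** trains the
same nine learners as level-0 models and a naive Bayes meta-classifier
(votes treated as nominal features, Laplace smoothing) on their
out-of-fold predictions from an internal stratified 5-fold split of the
training data — the leakage guard stacking requires; an AdaBoost.M1
meta-learner over decision stumps is available as `meta = "ada"`.

Evaluation uses stratified 10-fold cross-validation repeated with seed
values 1, 2, … (seed 1 for the first run, incremented each run), each
observation tested exactly once per run, reporting accuracy and AUC as
mean ± sd over runs; LOOCV is a single deterministic run.  AUC is the
rank-sum (concordant-pair) statistic with half credit for ties, which
equals the trapezoidal area under the ROC curve; it is cross-checked in
the tests against an independent ROC implementation.

## Synthetic phantoms

The generator emulates what the segmentation and classification stages
actually consume: a smooth low-frequency tissue field (coarse Gaussian
grid, bicubic-upsampled, correlation length 80 px ≈ half the patch),
additive white noise (σ = 5 on a 12-bit scale), and anti-aliased
elliptical blobs deformed by harmonic boundary perturbations.  Defaults
are 160 × 160 px at 70 µm, so the clinical 143-px block covers the
cluster.  Benign clusters: 6–10 round, uniformly sized blobs (4–9 px)
scattered over a 45-px radius.  Malignant clusters (`effect = 1`): 13–19
pleomorphic, size-varied blobs (3–13 px, irregularity 0.6) tightly and
linearly arranged over 25 px.  These axes were chosen so that the
clinically named discriminative features — cluster area, blob size,
density, centroid-distance spread — are the true signal carriers, making
feature-selection recovery meaningful.  `effect` interpolates every
class-conditional parameter linearly (0 = identical distributions);
per-sample seeds derive from the master seed by a counter scheme, so
datasets extend without reshuffling.

What the phantoms do **not** emulate: curvilinear and textured fibro-
glandular structure, vessel calcifications, pectoral muscle and skin
lines, detector blur and scatter, or annotation error.  Passing the
recovery tests therefore shows the chain is correct and well-calibrated
on its own model of the problem, not that clinical accuracy figures
transfer; on real databases the absolute numbers will differ.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale, chosen as
the package's own study conditions: 50 phantoms for segmentation
recovery (recall, false positives, hull Dice), 100 + 100 patches with
seeds 1–10 for classification recovery at `effect = 1`, 100 + 100 with
three seed runs for the chance-level control at `effect = 0`, and 50
random instances per brute-force oracle comparison.  Every random step —
phantom generation, fold shuffles, learner initialisation — draws from a
seed derived from the run's master seed, and the pipeline report is
reproduced bit-for-bit for an identical configuration and seed; each run
records a configuration hash alongside the seed.

## Known limitations

- The enhancement gain law and the SSI reference are reconstructions
  constrained by printed constants and monotonicity properties, not by a
  published equation.
- Blob→block assignment by centroid means a cluster straddling a block
  boundary can be split below the count threshold; the sliding-window
  remedy is deliberately out of scope.
- CFS on continuous correlations can differ from the discretised
  symmetric-uncertainty variant on strongly non-linear features.
- The Dice of two empty masks is defined as 1; callers comparing against
  non-empty references are unaffected.
- PNG patch output is 8-bit; deeper data round-trips through TIFF or
  PGM.
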