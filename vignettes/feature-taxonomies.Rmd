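---
title: "Building appearance-based taxonomies of facial features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building appearance-based taxonomies of facial features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facetax)
```

## The problem and the procedure

Describing human facial features with a shared vocabulary matters in
ergonomics, forensics, surgery and avatar design, yet human judges agree
poorly when asked to classify isolated eyes, noses or mouths: people process
faces holistically (the part–whole effect), and inter-observer error on
feature atlases is large. facetax implements an automatic alternative: it
groups feature images by their *global appearance* rather than by landmark
geometry, producing a coded taxonomy per feature kind that can classify new
features without human judgement.

The procedure is a pipeline of standard, deliberately simple components:

1. **Extraction.** Each whole-face photograph comes with 49 facial
   landmarks. For every feature a polygon is formed from its landmarks,
   filled, and thickened by isotropic disc dilation; the masked region is
   cropped to its bounding box. Left eyes are mirrored horizontally so all
   eyes share one orientation. Mouths are "shaved": the outer-mouth polygon
   is enlarged by 5 px, the binary mask is blurred with a Gaussian
   (sigma = 2), and the blurred mask multiplies the image, so facial hair
   around the lips fades smoothly into the black background.
2. **Alignment.** Features of one kind are translated so their polygon
   centroids coincide with the center of a common canvas sized by the
   largest polygon bounding box in the set, which crops away as much skin
   as possible.
3. **Eigenface encoding.** Each aligned image is standardized (zero mean,
   unit variance per image), the set is mean-centered, and its principal
   components are computed. Every feature is then described by its first
   M = 45 projection coefficients.
4. **Clustering.** K-means runs 10 times for every K from 5 to 30. For each
   solution, Dunn's Index — the minimum between-cluster distance divided by
   the maximum within-cluster diameter — scores compactness and separation.
   The selected K maximizes the per-K best Dunn's Index subject to having at
   most 2 single-element clusters (SECs: size 1 for mouths and noses, size
   ≤ 2 for eyes, because the two eyes of one person should travel together).
   SECs are then screened: a member whose polygon is oversized (> 60% of its
   canvas) or rotated (principal axis > 15° off horizontal) marks its
   cluster as a preprocessing casualty and removes it.
5. **Coding.** Kept clusters are ranked by membership percentage (over the
   pre-removal subset size) and coded ethnic letter + kind letter +
   two-digit rank (`WM01` is the most populated cluster of White mouths).
   The member nearest its centroid becomes the cluster's representative.
   Whole faces are coded by concatenation, e.g. `A-M01N01E01`.
6. **Survey validation.** A multi-stage forced-choice survey measures how
   often an evaluator, shown a target feature and four representatives at a
   time (the winner of each stage carries into the next, with unseen
   representatives filling the other corners until all have appeared),
   finally picks the target's own cluster — or a cluster close to it in
   representative-coefficient distance.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `thicken_px` | 5 | px | mask dilation for eyes and noses |
| `shave_enlarge_px` | 5 | px | outer-mouth polygon enlargement |
| `shave_sigma` | 2 | px | Gaussian blur of the shaving matte |
| `m` | 45 | – | eigenfaces kept per feature subset |
| `k_min`, `k_max` | 5, 30 | – | K-means sweep range |
| `runs_per_k` | 10 | – | restarts per K (coherence check) |
| `max_secs` | 2 | – | SEC cap for an admissible K |
| `area_threshold` | 0.6 | fraction | SEC screen: oversized polygon |
| `rotation_threshold` | 15 | degrees | SEC screen: rotated polygon |
| `n_targets` | 200 | trials | survey size per feature kind |

The enlargement, blur, eigenface count, sweep range, run count and SEC cap
are the procedure's standard settings; the mask thickening radius is not
fixed by the procedure's description, so it defaults to the same 5 px as the
mouth enlargement and is configurable. The SEC screen thresholds encode the
two failure modes the review targets (oversized and rotated features) and
are likewise configurable.

## Design choices in the open spots

Several steps admit more than one reasonable reading; facetax fixes them as
follows and exposes them as parameters where sensible.

* **Pre-PCA normalization.** Each image vector is z-scored (zero mean, unit
  variance) before the eigenface decomposition, and the per-image
  parameters are stored so training features can be de-normalized after
  reconstruction. Standardization removes per-photograph brightness and
  contrast, which would otherwise dominate the leading components. A
  consequence worth knowing: identities such as "the mean image encodes to
  zero" hold exactly in the model's standardized space (`normalize = FALSE`
  in `encode_features()`), and only approximately for raw images, because
  z-scoring is not a linear map of pixel space.
* **Eigen-decomposition.** The components come from a thin SVD of the
  n × p centered matrix (n images, p pixels, n ≪ p) — the snapshot method —
  which is exact and cheap at these sizes; a test checks agreement with the
  explicit covariance eigendecomposition to 1e-8. Each component's sign is
  fixed by making its largest-magnitude entry positive, so models are
  reproducible.
* **K-means.** Lloyd's algorithm with k-means++ seeding under an explicit
  seed, run to an assignment fixed point or 300 iterations; a cluster
  emptied mid-run is re-seeded with the point currently farthest from its
  centroid. The per-K aggregate over the 10 runs keeps the run with the
  highest Dunn's Index; the across-run standard deviation is reported as
  the coherence diagnostic.
* **Dunn's Index.** The original variant: single-linkage between-cluster
  distance over complete-diameter within-cluster distance, Euclidean. If
  every cluster has zero diameter the index is defined as `+Inf` with a
  warning. Ties in `select_k()` break toward smaller K (parsimony).
* **Geometry.** Polygon rasterization includes boundary pixels; "enlarged in
  every direction" is read as isotropic disc dilation; the shaving mask is
  blurred before cropping; centroid alignment uses integer shifts
  (rounding the sub-pixel centroid) to avoid resampling blur.
* **Survey fill rule.** When fewer than three unseen representatives remain
  for a stage, already-seen, non-selected representatives fill the free
  corners, preserving both the four-corner layout and the guarantee that
  every representative is shown at least once. Corner position is not
  modeled as influencing choice; only the stage-order bias is analyzed
  (`stage_position_bias()` shows that, under a uniformly random evaluator,
  representatives first appearing in later stages are selected more often —
  the tournament's known bias).
* **Evaluators.** Human participants are replaced by models operating on
  eigenface coefficients: `evaluator_nearest()` (the reference: always the
  closest representative) and `evaluator_softmax(temperature)` (choice
  probability ∝ exp(−distance/temperature)), which models human
  variability; agreement degrades monotonically as temperature grows.

## What the synthetic data does and does not emulate

`generate_faces()` draws cartoon faces — two eyes with eyebrows, a nose, a
mouth, optionally a mustache band — on a flat background, with all 49
landmarks placed at integer pixel positions consistent with the drawn
shapes. Integer landmarks make the horizontal mirror map exact in floating
point, so a face generated with `eye_symmetry = TRUE` yields a mirrored
left eye that equals the right eye *bit for bit* through rasterization,
dilation, cropping and alignment; these faces therefore give a sharp test
of the eye-pair coherence indicator (both eyes of a face must co-cluster).
`generate_planted_features()` builds image populations from G procedural
prototype blobs plus i.i.d. Gaussian pixel noise, quantized to the 8-bit
grid, with the true label of every image recorded.

What passing on this data shows: the geometry, linear algebra and selection
logic are correct, planted cluster structure is recovered (K and
memberships), and the survey protocol behaves. What it does not show:
robustness to the variation of real photographs — pose, illumination,
occlusion, landmark-detector error, skin-texture variation — none of which
the generator models, and no claim about the representativeness of any
taxonomy built from a particular photograph collection.

## Problem sizes used by the tests

The extraction bookkeeping check uses 290 faces on 160 × 140 px canvases
(about ten seconds). Planted-K recovery draws G from 5..12 with 15 members
per cluster on 16 × 16 px prototypes, encodes with M = 20, and sweeps K
from 5 to 15 with 10 runs per K across 10 seeds. Eye-pair coherence uses 40
symmetric faces; the survey checks use 8 planted clusters, 240 images and
200 targets. These sizes were chosen so each property is tested at a scale
where failure would be visible, while the whole suite stays quick enough to
run habitually.

## Known limitations

* Features are aligned by translation only; rotation and scale are not
  normalized, matching the procedure but limiting invariance.
* M is global per run; a variance-threshold alternative can be had by
  inspecting `tidy(model)` and refitting, but subsets are deliberately
  encoded with a common M to keep coefficient spaces comparable.
* Eigenface models are fit per subset; a taxonomy's codes and distances are
  meaningful only within the dataset the model was fit on.
* The automatic SEC screens need feature polygons; when clustering bare
  coefficient tables (no geometry), SEC review retains everything unless a
  manual removal list is given.

## A minimal run

```{r example, eval = FALSE}
faces <- generate_faces(60, seed = 1)
cfg <- pipeline_config(out_dir = "taxonomies", m = 20, k_min = 2, k_max = 8,
                       runs_per_k = 5, seed = 1)
res <- run_pipeline(cfg, faces = faces)
tidy(res$taxonomies$mouth)
autoplot(res$taxonomies$mouth)
```
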