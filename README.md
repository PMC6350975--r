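# facetax

Automatic, appearance-based taxonomies of human facial features (eyes,
noses, mouths).

Human observers classify isolated facial features poorly — the part–whole
effect makes individual features hard to judge, and inter-observer agreement
on feature atlases is low. facetax replaces that judgement with an automatic
procedure aimed at ergonomics, forensics and avatar-design workflows: it
extracts feature images from whole-face photographs using 49-point facial
landmarks, encodes each feature's global appearance with eigenfaces, groups
the features with K-means, and validates the grouping with a simulated
forced-choice survey.

## The method in brief

For each feature kind the pipeline:

1. builds a polygon mask from the feature's landmarks, thickens it (disc
   dilation, 5 px), and crops the masked region; left eyes are mirrored
   horizontally, and mouths are *shaved* — the outer-mouth polygon is
   enlarged by 5 px, Gaussian-blurred (σ = 2), and used as a multiplicative
   alpha matte that removes facial hair around the lips;
2. aligns all features of a kind by polygon centroid and crops to the
   biggest bounding box over the set;
3. standardizes each image (zero mean, unit variance), computes the
   principal components of the set (eigenfaces), and describes every
   feature by its first M = 45 projection coefficients;
4. runs K-means 10 times for every K in 5..30 and scores each solution with
   **Dunn's Index**
   `D = min inter-cluster distance / max intra-cluster diameter`;
   the selected K maximizes the per-K best index subject to at most two
   single-element clusters (SECs: size 1 for mouths/noses, size ≤ 2 for
   eyes); SECs whose members fail geometry screens (oversized or rotated
   polygons) are eliminated as preprocessing outliers;
5. ranks the kept clusters by membership percentage and codes them
   ethnic letter + kind letter + rank (`WM01`, `AN03`, …); the member
   nearest each centroid is the cluster's representative; whole faces are
   coded as e.g. `W-M01N01E01`;
6. optionally simulates the validation survey: a target feature faces four
   representatives per stage, the winner carries over until every
   representative has been shown, and the final pick's cluster is compared
   with the expected one by representative-distance rank.

A synthetic-data module generates cartoon faces with known landmarks
(optionally with exactly mirror-symmetric eyes, so that a correct pipeline
must put both eyes of a face in the same cluster) and planted-cluster image
populations, which makes the entire pipeline testable without any external
photograph collection.

## Worked example

```r
library(facetax)

faces  <- generate_faces(60, seed = 1)            # synthetic faces + landmarks
feats  <- extract_features(faces)                 # 120 eyes, 60 noses, 60 mouths
mouths <- dplyr::filter(feats, kind == "mouth")

model  <- fit_eigenmodel(mouths, m = 20)
model
#> <eigen_model> 15 x 39 px, 60 images, M = 20, 100.0% variance explained

coeffs <- encode_features(mouths, model)
sw     <- sweep_k(coeffs, k_min = 5, k_max = 12, runs_per_k = 5, seed = 1)
sol    <- select_k(sw, kind = "mouth")            # K = 12, Dunn = 0.953

tax <- build_taxonomy(sol, coeffs, ethnic_code = "W", kind_code = "M")
tidy(tax)
#> # A tibble: 12 × 5
#>   code   rank  size percentage representative_id
#> 1 WM01      1    10       16.7 face0049_mouth
#> 2 WM02      2     9       15   face0005_mouth
#> 3 WM03      3     7       11.7 face0033_mouth
#> 4 WM04      4     6       10   face0034_mouth
#> # ... 8 more rows
```

`WM01` is the most populated cluster of mouths (16.7% of the subset), and
`face0049_mouth` is its representative — the member closest to the cluster
centroid in coefficient space. A noisy evaluator then rates how well the
taxonomy matches perceived similarity:

```r
ag <- simulate_survey(tax, coeffs, n_targets = 40,
                      evaluator = evaluator_softmax(2), seed = 2)
head(ag, 2)
#>       outcome count percent cum_percent
#> 1    Expected    39    97.5        97.5
#> 2 1st closest     1     2.5       100.0
agreement_summary(ag, 3)     # % of trials within the 3 closest clusters
#> [1] 100
```

With 40 targets, 39 final picks landed in the expected cluster (97.5%) and
the rest within the closest clusters. `autoplot()` methods plot the K-sweep
diagnostics, scree curves, taxonomy membership and agreement tables;
`run_pipeline(pipeline_config(...))` chains all stages and writes taxonomy
JSON, coefficient CSVs, per-K reports and a run manifest. A thin CLI over
the same functions ships at `inst/cli/featuretax`
(`featuretax extract | encode | cluster | survey | run`).

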