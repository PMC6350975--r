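Package: facetax
Title: Appearance-Based Taxonomies of Facial Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds taxonomies of human facial features (eyes, noses, mouths)
    from whole-face photographs by global appearance. Feature images are
    extracted with landmark-driven polygon masks (mirroring left eyes,
    "shaving" mouths with a blurred alpha matte), aligned by polygon centroid
    and cropped to a common canvas, encoded as eigenface coefficients, and
    clustered with K-means; the number of clusters is selected by Dunn's
    Index subject to a cap on single-element clusters. The resulting clusters
    are coded, ranked by membership, and summarized by representative
    features. A simulated multi-stage forced-choice survey quantifies
    agreement between the taxonomy and a distance-based evaluator. A
    synthetic-data module generates face images with known landmarks and
    planted cluster structure so the whole pipeline is testable without any
    external photograph collection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
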