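test_that("k-means finds the obvious partitions and is deterministic", {
  # points already at K distinct locations -> zero inertia
  x <- matrix(c(0, 0, 5, 5, 10, 10), ncol = 2, byrow = TRUE)
  sol <- run_kmeans(x, 3, seed = 1)
  expect_equal(sol$inertia, 0)
  expect_equal(length(unique(sol$assignments)), 3)

  # 1-D {0,1,2, 10,11,12}, K = 2: compare with the exhaustive best partition
  y <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  best_wss <- Inf; best_split <- NULL
  for (code in 1:(2^6 - 2)) {
    lab <- as.integer(intToBits(code))[1:6]
    if (length(unique(lab)) < 2) next
    wss <- sum(unlist(lapply(split(y[, 1], lab), function(g) sum((g - mean(g))^2))))
    if (wss < best_wss) { best_wss <- wss; best_split <- lab }
  }
  expect_equal(sort(which(best_split == best_split[1])), 1:3)  # oracle sanity
  sol2 <- run_kmeans(y, 2, seed = 3)
  expect_equal(sol2$inertia, best_wss)
  expect_equal(length(unique(sol2$assignments[1:3])), 1)
  expect_equal(length(unique(sol2$assignments[4:6])), 1)
  expect_true(sol2$assignments[1] != sol2$assignments[4])

  # determinism and fixed point: re-running assignment changes nothing
  sol3 <- run_kmeans(y, 2, seed = 3)
  expect_identical(sol2$assignments, sol3$assignments)
  expect_true(sol2$converged)
  expect_error(run_kmeans(y, 7, seed = 1), class = "facetax_parameter_error")
})

test_that("k-means matches the inertia reached by stats::kmeans", {
  x <- withr::with_seed(10, matrix(rnorm(200), ncol = 4))
  # best of 10 seeded runs, as the K sweep uses, vs 25 restarts of stats::kmeans
  mine <- min(vapply(1:10, function(s) run_kmeans(x, 4, seed = s)$inertia,
                     numeric(1)))
  ref <- withr::with_seed(2, stats::kmeans(x, 4, nstart = 25,
                                           algorithm = "Lloyd", iter.max = 100))
  expect_lte(mine, ref$tot.withinss * 1.05)
})

test_that("Dunn's Index matches hand computations and the brute-force oracle", {
  # {0,1} vs {10,11}: min inter = 9, max intra = 1
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(dunn_index(x, c(1, 1, 2, 2)), 9)

  # a cluster wider than every gap gives an index < 1
  y <- matrix(c(0, 6, 7, 8), ncol = 1)
  expect_lt(dunn_index(y, c(1, 1, 2, 2)), 1)

  # random instances against the O(n^2) loop oracle (exact)
  for (s in 1:20) {
    z <- withr::with_seed(s, matrix(rnorm(60), ncol = 2))
    lab <- withr::with_seed(s + 1000, sample(1:3, 30, replace = TRUE))
    if (length(unique(lab)) < 2) next
    expect_equal(dunn_index(z, lab), dunn_oracle(z, lab), tolerance = 0)
  }

  # all points identical: +Inf with a warning
  w <- matrix(1, 4, 2)
  expect_warning(v <- dunn_index(w, c(1, 1, 2, 2)), regexp = "Inf")
  expect_identical(v, Inf)
})

test_that("SEC rules differ between eyes and mouths/noses", {
  lab <- c(rep(1, 5), 2, rep(3, 7))
  expect_equal(count_secs(lab, "nose"), 2L)
  expect_equal(count_secs(lab, "mouth"), 2L)
  pairing <- setNames(paste0("face", c(1:5, 6, 7:13)), paste0("f", 1:13))
  # eyes: size <= 2 is a SEC, whether or not the two eyes share a face
  lab_eye <- c(1, 1, 2, 3, 3, 3)
  names(lab_eye) <- paste0("f", 1:6)
  expect_equal(count_secs(lab_eye, "eye", pairing), c(1L, 2L))
  expect_error(count_secs(lab_eye, "eye"), class = "facetax_parameter_error")
  # eye cluster of size 3 is not a SEC
  expect_false(3L %in% count_secs(lab_eye, "eye", pairing))
})

test_that("sweep_k produces the full grid and select_k applies the rules", {
  pc <- planted_coeffs(g = 8, members = 12, noise_sd = 0.02, seed = 6)
  sw <- sweep_k(pc$coeffs, 5, 12, runs_per_k = 4, seed = 9)
  expect_equal(nrow(sw), (12 - 5 + 1) * 4)
  expect_error(sweep_k(pc$coeffs, 10, 5), class = "facetax_parameter_error")

  # planted G = 8: per-K best Dunn is maximized at K = 8
  best <- summarize_sweep(sw)
  expect_equal(best$k[which.max(best$dunn)], 8)

  sol <- select_k(sw, "nose")
  expect_equal(sol$k, 8)
  expect_s3_class(sol, "facetax_kmeans")

  # reruns of the sweep with the same seed are identical
  sw2 <- sweep_k(pc$coeffs, 5, 12, runs_per_k = 4, seed = 9)
  expect_identical(sw$dunn, sw2$dunn)

  # hand-built sweep: max Dunn with SEC <= max_secs wins; ties -> smaller K
  mk <- function(k, labels, dunn) {
    s <- structure(list(k = k, assignments = setNames(labels, paste0("f", seq_along(labels))),
                        centroids = matrix(0, k, 2), inertia = 0,
                        iterations = 1L, converged = TRUE),
                   class = "facetax_kmeans")
    tibble::tibble(k = k, run = 1L, dunn = dunn, inertia = 0,
                   converged = TRUE, solution = list(s))
  }
  fake <- dplyr::bind_rows(
    mk(2, c(1, 1, 2, 2, 2, 2), 1.5),
    mk(3, c(1, 1, 2, 2, 3, 3), 1.5),
    mk(4, c(1, 2, 3, 3, 4, 4), 9.9))  # two SECs of size 1 + high Dunn
  class(fake) <- c("facetax_sweep", class(fake))
  pick <- select_k(fake, "nose", max_secs = 0)
  expect_equal(pick$k, 2)  # K = 4 blocked by SECs; 2 vs 3 tie -> smaller K
  pick2 <- select_k(fake, "nose", max_secs = 2)
  expect_equal(pick2$k, 4)
  expect_equal(sort(pick2$sec_clusters), c(1L, 2L))
  expect_error(select_k(fake[3, ], "nose", max_secs = 0),
               class = "facetax_selection_error")
})

test_that("SEC review removes only geometry outliers; taxonomy stays consistent", {
  # three clusters: sizes 3, 1 (oversized polygon), 1 (clean)
  co <- matrix(c(0, 0, 0.1, 0, 0, 0.1, 10, 10, 20, 20), ncol = 2, byrow = TRUE)
  rownames(co) <- paste0("f", 1:5)
  sol <- run_kmeans(co, 3, seed = 4)
  sol$sec_clusters <- count_secs(sol, "nose")
  big_poly <- cbind(x = c(1, 10, 10, 1), y = c(1, 1, 8, 8))    # 63% of canvas
  small_poly <- cbind(x = c(4, 7, 7, 4), y = c(5, 5, 7, 7))
  feats <- tibble::tibble(
    feature_id = paste0("f", 1:5), kind = "nose",
    pixels = replicate(5, matrix(0.5, 10, 10), simplify = FALSE),
    polygon = list(small_poly, small_poly, small_poly, big_poly, small_poly))
  rev <- review_secs(sol, feats)
  removed_ids <- unlist(rev$removed_secs$member_ids)
  expect_equal(removed_ids, "f4")
  expect_equal(rev$removed_secs$reason, "oversized")

  # rotated polygon triggers the second screen
  rot <- cbind(x = c(4, 8, 9, 5), y = c(4, 8, 8, 4))  # 45-degree principal axis
  feats$polygon[[5]] <- rot
  rev2 <- review_secs(sol, feats)
  expect_true(any(grepl("rotated", rev2$removed_secs$reason)))

  # manual mode removes exactly the listed clusters
  rev3 <- review_secs(sol, auto = FALSE, remove = sol$sec_clusters)
  expect_equal(nrow(rev3$removed_secs), length(sol$sec_clusters))

  # taxonomy percentages are over the pre-removal size; codes are ranked
  tax <- build_taxonomy(sol, co, "W", "N", review = rev)
  expect_equal(tax$clusters$code[1], "WN01")
  expect_equal(tax$clusters$percentage[1], 60)  # 3 of 5
  total_pct <- sum(tax$clusters$percentage) +
    100 * length(unlist(tax$removed_secs$member_ids)) / tax$n_total
  expect_equal(total_pct, 100, tolerance = 1e-9)
  expect_true(all(diff(tax$clusters$percentage) <= 0))
})

test_that("representatives, classification and face codes behave", {
  pt <- planted_taxonomy(g = 5, members = 10, seed = 8)
  tax <- pt$taxonomy
  co <- pt$coeffs
  m <- facetax:::as_coef_matrix(co)

  # a cluster of one member is its own representative
  # (and in general the representative belongs to its cluster)
  for (i in seq_len(nrow(tax$clusters))) {
    expect_true(tax$clusters$representative_id[i] %in% tax$clusters$member_ids[[i]])
  }

  # each representative classifies into its own cluster
  reps <- classify_encoded(tax, m[tax$clusters$representative_id, , drop = FALSE])
  expect_equal(reps$code, tax$clusters$code)

  # the reconstruction of a centroid classifies into that cluster
  model <- pt$solution
  emodel <- fit_eigenmodel(pt$pop, m = 15)
  for (i in c(1, nrow(tax$clusters))) {
    img <- reconstruct(emodel, tax$clusters$centroid[[i]])
    expect_equal(classify_feature(emodel, tax, img, normalize = FALSE),
                 tax$clusters$code[i])
  }

  # holdout images from the same prototypes land in their planted cluster
  holdout <- generate_planted_features(make_prototypes(5), 6, noise_sd = 0.02,
                                       seed = 99)
  hco <- encode_features(holdout, emodel)
  hm <- facetax:::as_coef_matrix(hco)
  got <- classify_encoded(tax, hm)
  # map planted labels to the majority taxonomy code
  map <- tapply(classify_encoded(tax, m)$code, pt$pop$label,
                function(v) names(sort(table(v), decreasing = TRUE))[1])
  expect_gte(mean(got$code == map[holdout$label]), 0.95)

  expect_equal(face_code("A", "AM01", "AN01", "AE01"), "A-M01N01E01")
  expect_equal(face_code("W", "WM03", "WN12", "WE07"), "W-M03N12E07")
  expect_equal(face_code("L", "LM01", "LN01", "LE01"), "L-M01N01E01")
  expect_error(face_code("A", "AM01", "BN01", "AE01"),
               class = "facetax_parameter_error")
  expect_error(face_code("A", "A101", "AN01", "AE01"),
               class = "facetax_parameter_error")
})
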