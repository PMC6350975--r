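test_that("polygon masks match a brute-force rasterization oracle", {
  # 10x10 px axis-aligned square, inclusive boundary: 11 x 11 = 121 pixels
  sq <- cbind(x = c(5, 15, 15, 5), y = c(5, 5, 15, 15))
  mask <- facetax:::rasterize_polygon(sq, 20, 20)
  expect_equal(sum(mask), 121)

  # random simple (convex) polygons against the independent oracle
  for (s in 1:10) {
    poly <- withr::with_seed(s, {
      ang <- sort(runif(6, 0, 2 * pi))
      r <- runif(6, 3, 8)
      cbind(x = 12 + r * cos(ang), y = 12 + r * sin(ang))
    })
    mask <- facetax:::rasterize_polygon(poly, 24, 24)
    oracle <- matrix(0, 24, 24)
    for (y in 1:24) for (x in 1:24) {
      oracle[y, x] <- as.numeric(point_in_poly_oracle(x, y, poly))
    }
    expect_identical(mask, oracle)
  }
})

test_that("mask thickening dilates monotonically", {
  f <- generate_face("d1", seed = 6)
  m0 <- build_feature_mask(f$landmarks, "nose", thicken_px = 0, shape = dim(f$image))
  m3 <- build_feature_mask(f$landmarks, "nose", thicken_px = 3, shape = dim(f$image))
  expect_true(all(m3$mask[m0$mask == 1] == 1))
  expect_gt(sum(m3$mask), sum(m0$mask))
  expect_equal(sum(m0$mask),
               sum(facetax:::rasterize_polygon(m0$polygon, nrow(f$image), ncol(f$image))))
})

test_that("extract_feature masks, crops and reports local geometry", {
  img <- matrix(0.5, 12, 14)
  full <- list(mask = matrix(1, 12, 14), polygon = cbind(c(1, 14, 14, 1), c(1, 1, 12, 12)))
  out <- extract_feature(img, full)
  expect_identical(out$pixels[[1]], img)

  mask <- matrix(0, 12, 14); mask[4:9, 6:11] <- 1
  poly <- cbind(x = c(6, 11, 11, 6), y = c(4, 4, 9, 9))
  ft <- extract_feature(img, list(mask = mask, polygon = poly))
  px <- ft$pixels[[1]]
  expect_equal(dim(px), c(6, 6))
  expect_true(all(px == 0.5))
  expect_equal(unname(feature_centroid(ft)), c(3.5, 3.5))
  expect_error(extract_feature(img, list(mask = matrix(0, 12, 14), polygon = poly)),
               class = "facetax_geometry_error")
  expect_error(extract_feature(img, list(mask = matrix(1, 3, 3), polygon = poly)),
               class = "facetax_parameter_error")
})

test_that("extracted eye boxes agree with generator ground truth", {
  f <- generate_face("gt1", seed = 12)
  thicken <- 4
  m <- build_feature_mask(f$landmarks, "eye", "right", thicken, dim(f$image))
  keep <- which(m$mask > 0, arr.ind = TRUE)
  truth <- dplyr::filter(f$boxes, kind == "eye", side == "right")
  expect_lte(abs(min(keep[, 2]) - truth$xmin), thicken)
  expect_lte(abs(max(keep[, 2]) - truth$xmax), thicken)
  expect_lte(abs(min(keep[, 1]) - truth$ymin), thicken)
  expect_lte(abs(max(keep[, 1]) - truth$ymax), thicken)
})

test_that("mirroring is an involution that reverses column sums", {
  f <- generate_face("mi1", seed = 8, eye_symmetry = TRUE)
  feats <- extract_features(tibble::tibble(face_id = "mi1", image = list(f$image),
                                           landmarks = list(f$landmarks)),
                            align = FALSE)
  left_raw <- extract_feature(f$image,
                              build_feature_mask(f$landmarks, "eye", "left", 5,
                                                 dim(f$image)),
                              "mi1_eye_L", "mi1", "eye", "left")
  once <- mirror_left_eye(left_raw)
  twice <- mirror_left_eye(once)
  expect_identical(twice$pixels[[1]], left_raw$pixels[[1]])
  expect_identical(twice$polygon[[1]], left_raw$polygon[[1]])
  expect_equal(colSums(once$pixels[[1]]), rev(colSums(left_raw$pixels[[1]])))
  expect_error(mirror_left_eye(dplyr::filter(feats, kind == "nose")),
               class = "facetax_parameter_error")

  # constructed symmetry: mirrored left equals right, pixel for pixel
  eyes <- dplyr::filter(feats, kind == "eye")
  expect_identical(eyes$pixels[[which(eyes$side == "left")]],
                   eyes$pixels[[which(eyes$side == "right")]])
})

test_that("mouth shaving removes the surroundings but not the mouth interior", {
  f1 <- generate_face("sh1", seed = 44, mustache = TRUE)
  shaved <- shave_mouth(f1$image, f1$landmarks)

  # band outside the shaving matte: compare shaved vs unshaved means on the
  # full canvas (the matte is the polygon + 5 px, blurred with sigma = 2)
  poly <- f1$landmarks$points[32:43, ]
  h <- nrow(f1$image); w <- ncol(f1$image)
  inner <- facetax:::rasterize_polygon(poly, h, w)
  alpha <- facetax:::blur_mask(facetax:::dilate_mask(inner, 5), 2)
  sh_canvas <- f1$image * alpha
  band <- facetax:::dilate_mask(inner, 12) - facetax:::dilate_mask(inner, 9)
  band_shaved <- mean(sh_canvas[band == 1])
  band_unshaved <- mean(f1$image[band == 1])
  expect_lte(band_shaved, 0.05 * band_unshaved)

  # interior far from the matte edge is untouched
  cen <- round(facetax:::polygon_centroid(poly))
  local <- round(feature_centroid(shaved))
  expect_equal(shaved$pixels[[1]][local["y"], local["x"]],
               f1$image[cen["y"], cen["x"]], tolerance = 1e-6)

  # sigma = 0 gives a hard-edged mask: all outside pixels exactly 0
  hard <- shave_mouth(f1$image, f1$landmarks, blur_sigma = 0)
  hmask <- facetax:::dilate_mask(inner, 5)
  hk <- which(hmask > 0, arr.ind = TRUE)
  sub <- hmask[min(hk[, 1]):max(hk[, 1]), min(hk[, 2]):max(hk[, 2])]
  expect_true(all(hard$pixels[[1]][sub == 0] == 0))

  expect_error(shave_mouth(f1$image, f1$landmarks, enlarge_px = -1),
               class = "facetax_parameter_error")
})

test_that("alignment is translation-invariant and sized by the biggest bbox", {
  f <- generate_face("al1", seed = 17)
  img2 <- facetax:::shift_image(f$image, 3, -4)
  pts2 <- f$landmarks$points
  pts2[, 1] <- pts2[, 1] - 4; pts2[, 2] <- pts2[, 2] + 3
  faces <- tibble::tibble(
    face_id = c("a", "b"),
    image = list(f$image, img2),
    landmarks = list(landmark_set("a", f$landmarks$points),
                     landmark_set("b", pts2)))
  feats <- extract_features(faces, align = TRUE)
  noses <- dplyr::filter(feats, kind == "nose")
  expect_identical(noses$pixels[[1]], noses$pixels[[2]])

  # single feature: canvas is its own polygon bbox, centroid at center
  one <- align_and_crop(dplyr::filter(feats, feature_id == "a_nose"))
  bb <- facetax:::polygon_bbox(one$polygon[[1]])
  expect_equal(dim(one$pixels[[1]]),
               c(bb["ymax"] - bb["ymin"] + 1, bb["xmax"] - bb["xmin"] + 1),
               ignore_attr = TRUE)
  cen <- feature_centroid(one)
  expect_lte(abs(cen["x"] - (ncol(one$pixels[[1]]) + 1) / 2), 0.51)
  expect_lte(abs(cen["y"] - (nrow(one$pixels[[1]]) + 1) / 2), 0.51)
  expect_error(align_and_crop(feats[0, ]), class = "facetax_parameter_error")
})

test_that("extraction bookkeeping counts 2n eyes, n noses, n mouths", {
  faces <- generate_faces(10, seed = 3)
  faces$landmarks[3] <- list(NULL)
  expect_warning(feats <- extract_features(faces), regexp = "skipping face")
  counts <- table(feats$kind)
  expect_equal(unname(counts[c("eye", "nose", "mouth")]), c(18L, 9L, 9L),
               ignore_attr = TRUE)
  expect_equal(attr(feats, "n_failed"), 1L)

  one <- extract_features(faces[1, ])
  expect_equal(unname(table(one$kind)[c("eye", "nose", "mouth")]), c(2L, 1L, 1L),
               ignore_attr = TRUE)
})
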