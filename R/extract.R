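# Feature extraction: landmark-driven masks, masked cropping, eye mirroring,
# mouth shaving, and centroid alignment with biggest-bounding-box cropping.
#
# A feature table is a tibble with one row per extracted feature image:
#   feature_id, face_id, kind ("eye"/"nose"/"mouth"), side ("left"/"right"/
#   "none"), pixels (list of matrices), polygon (list of two-column (x, y)
#   matrices in the feature image's own 1-based coordinates).

feature_row <- function(feature_id, face_id, kind, side, pixels, polygon) {
  tibble(feature_id = feature_id, face_id = face_id, kind = kind, side = side,
         pixels = list(pixels), polygon = list(as_polygon(polygon)))
}

#' Centroid of a feature's landmark polygon
#'
#' @param feature One row of a feature table.
#' @return Named numeric `c(x, y)`.
#' @export
feature_centroid <- function(feature) polygon_centroid(feature$polygon[[1]])

#' Build a binary mask for one feature from landmarks
#'
#' Fills the feature's landmark polygon (boundary pixels included) and
#' thickens it by isotropic disc dilation.
#'
#' @param landmarks A [landmark_set()].
#' @param kind `"eye"`, `"nose"` or `"mouth"`.
#' @param side For eyes, `"left"` or `"right"` (image side).
#' @param thicken_px Dilation radius in pixels (>= 0). Default 5 px.
#' @param shape `c(height, width)` of the source image.
#' @param schema Landmark schema (see [read_schema()]).
#' @return A list: `mask` (binary matrix of `shape`), `polygon` (the source
#'   polygon), `thicken_px`.
#' @export
build_feature_mask <- function(landmarks, kind, side = "none", thicken_px = 5,
                               shape, schema = default_schema()) {
  stopifnot(inherits(landmarks, "facetax_landmarks"))
  if (thicken_px < 0) ftx_abort("thicken_px must be >= 0", "parameter_error")
  key <- switch(kind,
                eye = paste0(side, "_eye"),
                nose = "nose",
                mouth = "mouth",
                ftx_abort(paste("unknown feature kind:", kind), "parameter_error"))
  idx <- schema$features[[key]]
  poly <- landmarks$points[idx, , drop = FALSE]
  mask <- rasterize_polygon(poly, shape[1], shape[2])
  list(mask = dilate_mask(mask, thicken_px), polygon = poly, thicken_px = thicken_px)
}

#' Extract a masked feature image
#'
#' Applies the mask to the face image, crops to the mask's bounding box, and
#' translates the polygon into the cropped frame. Pixels outside the mask
#' are exactly 0.
#'
#' @param image Grayscale face matrix.
#' @param mask A mask list from [build_feature_mask()] (or a binary matrix of
#'   the same shape as `image`, in which case `polygon` must be given).
#' @param feature_id,face_id,kind,side Provenance fields for the output row.
#' @param polygon Polygon in source coordinates, when `mask` is a bare matrix.
#' @return A one-row feature table.
#' @export
extract_feature <- function(image, mask, feature_id = "feature", face_id = "face",
                            kind = "nose", side = "none", polygon = NULL) {
  if (is.list(mask) && !is.matrix(mask)) {
    polygon <- polygon %||% mask$polygon
    mask <- mask$mask
  }
  if (!identical(dim(mask), dim(image))) {
    ftx_abort("mask shape must equal image shape", "parameter_error")
  }
  if (!any(mask > 0)) ftx_abort("empty mask", "geometry_error")
  keep <- which(mask > 0, arr.ind = TRUE)
  r0 <- min(keep[, 1]); r1 <- max(keep[, 1])
  c0 <- min(keep[, 2]); c1 <- max(keep[, 2])
  out <- (image * mask)[r0:r1, c0:c1, drop = FALSE]
  poly <- as_polygon(polygon)
  poly[, 1] <- poly[, 1] - (c0 - 1)
  poly[, 2] <- poly[, 2] - (r0 - 1)
  feature_row(feature_id, face_id, kind, side, out, poly)
}

#' Mirror a left-eye feature horizontally
#'
#' Flips the pixels about the vertical axis and reflects the polygon's x
#' coordinates. Provenance (`side = "left"`) is kept so eye pairs remain
#' traceable. Mirroring twice restores the original.
#'
#' @param feature A one-row feature table with `kind = "eye"`,
#'   `side = "left"`.
#' @return The mirrored one-row feature table.
#' @export
mirror_left_eye <- function(feature) {
  if (feature$kind != "eye" || feature$side != "left") {
    ftx_abort("mirror_left_eye() applies only to left-eye features", "parameter_error")
  }
  px <- feature$pixels[[1]]
  w <- ncol(px)
  poly <- feature$polygon[[1]]
  poly[, 1] <- w + 1 - poly[, 1]
  feature$pixels <- list(px[, rev(seq_len(w)), drop = FALSE])
  feature$polygon <- list(poly)
  feature
}

#' Extract a "shaved" mouth
#'
#' Forms the outer-mouth landmark polygon, enlarges it by `enlarge_px` in
#' every direction (disc dilation), Gaussian-blurs the binary mask
#' (`sigma = blur_sigma`) and multiplies the face by the blurred mask, so the
#' transition from skin (and any facial hair) to the black background is
#' smooth. `blur_sigma = 0` skips the blur and leaves a hard-edged mask.
#'
#' @param image Grayscale face matrix.
#' @param landmarks A [landmark_set()].
#' @param enlarge_px Polygon enlargement in pixels. Default 5.
#' @param blur_sigma Gaussian blur standard deviation. Default 2.
#' @param feature_id,face_id Provenance fields.
#' @param schema Landmark schema.
#' @return A one-row feature table (`kind = "mouth"`).
#' @export
shave_mouth <- function(image, landmarks, enlarge_px = 5, blur_sigma = 2,
                        feature_id = "mouth", face_id = "face",
                        schema = default_schema()) {
  if (enlarge_px < 0) ftx_abort("enlarge_px must be >= 0", "parameter_error")
  if (blur_sigma < 0) ftx_abort("blur_sigma must be >= 0", "parameter_error")
  idx <- schema$features$mouth_outer
  poly <- landmarks$points[idx, , drop = FALSE]
  mask0 <- rasterize_polygon(poly, nrow(image), ncol(image))
  mask <- dilate_mask(mask0, enlarge_px)
  alpha <- blur_mask(mask, blur_sigma)
  matte <- image * alpha
  keep <- which(mask > 0, arr.ind = TRUE)
  r0 <- min(keep[, 1]); r1 <- max(keep[, 1])
  c0 <- min(keep[, 2]); c1 <- max(keep[, 2])
  out <- matte[r0:r1, c0:c1, drop = FALSE]
  lpoly <- as_polygon(poly)
  lpoly[, 1] <- lpoly[, 1] - (c0 - 1)
  lpoly[, 2] <- lpoly[, 2] - (r0 - 1)
  feature_row(feature_id, face_id, "mouth", "none", out, lpoly)
}

#' Align features by polygon centroid and crop to the biggest bounding box
#'
#' All features of one kind are placed on a common canvas whose size is the
#' element-wise maximum of the per-feature polygon bounding boxes. Each
#' feature is translated by an integer shift so its polygon centroid sits at
#' the canvas center; pixels translated off the canvas are dropped and
#' revealed pixels are 0. The result is translation-invariant: where a
#' feature sat in its source face does not affect its aligned image.
#'
#' @param features A feature table of a single kind.
#' @return The feature table with same-size `pixels` and updated polygons.
#' @export
align_and_crop <- function(features) {
  if (nrow(features) == 0) ftx_abort("no features to align", "parameter_error")
  if (length(unique(features$kind)) != 1) {
    ftx_abort("align_and_crop() expects features of a single kind", "parameter_error")
  }
  bbs <- map(features$polygon, polygon_bbox)
  heights <- map_dbl(bbs, ~ floor(.x["ymax"]) - ceiling(.x["ymin"]) + 1)
  widths <- map_dbl(bbs, ~ floor(.x["xmax"]) - ceiling(.x["xmin"]) + 1)
  ht <- as.integer(max(heights)); wt <- as.integer(max(widths))
  cy <- (ht + 1) / 2; cx <- (wt + 1) / 2
  for (i in seq_len(nrow(features))) {
    px <- features$pixels[[i]]
    poly <- features$polygon[[i]]
    cen <- polygon_centroid(poly)
    dy <- round(cy - cen["y"]); dx <- round(cx - cen["x"])
    canvas <- matrix(0, ht, wt)
    src_r <- seq_len(nrow(px)); src_c <- seq_len(ncol(px))
    dst_r <- src_r + dy; dst_c <- src_c + dx
    ok_r <- dst_r >= 1 & dst_r <= ht; ok_c <- dst_c >= 1 & dst_c <= wt
    canvas[dst_r[ok_r], dst_c[ok_c]] <- px[src_r[ok_r], src_c[ok_c], drop = FALSE]
    poly[, 1] <- poly[, 1] + dx; poly[, 2] <- poly[, 2] + dy
    features$pixels[[i]] <- canvas
    features$polygon[[i]] <- poly
  }
  features
}

#' Extract all features from a set of faces
#'
#' Per face: the two eyes (left mirrored horizontally), the nose, and the
#' shaved mouth — 2n eyes, n noses, n mouths for n faces. Faces whose
#' landmarks are missing or invalid are skipped with a warning; the failure
#' count is available as `attr(result, "n_failed")`.
#'
#' @param faces Tibble with `face_id`, `image` (list of matrices) and
#'   `landmarks` (list of [landmark_set()]s), e.g. from [generate_faces()]
#'   or [read_faces()].
#' @param schema Landmark schema.
#' @param thicken_px Mask thickening radius (eyes and noses). Default 5.
#' @param shave_enlarge_px,shave_sigma Mouth-shaving parameters
#'   (see [shave_mouth()]). Defaults 5 and 2.
#' @param align Align and crop each kind to a common canvas (default TRUE).
#' @return A feature table (all kinds stacked).
#' @export
extract_features <- function(faces, schema = default_schema(), thicken_px = 5,
                             shave_enlarge_px = 5, shave_sigma = 2,
                             align = TRUE) {
  rows <- list()
  n_failed <- 0L
  for (i in seq_len(nrow(faces))) {
    fid <- faces$face_id[i]
    res <- tryCatch({
      img <- faces$image[[i]]
      lms <- faces$landmarks[[i]]
      if (!inherits(lms, "facetax_landmarks")) {
        ftx_abort("missing or invalid landmarks", "schema_error")
      }
      if (any(lms$points[, 1] < 1 | lms$points[, 1] > ncol(img) |
              lms$points[, 2] < 1 | lms$points[, 2] > nrow(img))) {
        ftx_abort("landmarks fall outside the image", "schema_error")
      }
      eye_r <- extract_feature(img,
                               build_feature_mask(lms, "eye", "right", thicken_px,
                                                  dim(img), schema),
                               paste0(fid, "_eye_R"), fid, "eye", "right")
      eye_l <- mirror_left_eye(
        extract_feature(img,
                        build_feature_mask(lms, "eye", "left", thicken_px,
                                           dim(img), schema),
                        paste0(fid, "_eye_L"), fid, "eye", "left"))
      nose <- extract_feature(img,
                              build_feature_mask(lms, "nose", "none", thicken_px,
                                                 dim(img), schema),
                              paste0(fid, "_nose"), fid, "nose", "none")
      mouth <- shave_mouth(img, lms, shave_enlarge_px, shave_sigma,
                           paste0(fid, "_mouth"), fid, schema)
      bind_rows(eye_r, eye_l, nose, mouth)
    }, facetax_error = function(e) {
      rlang::warn(sprintf("skipping face '%s': %s", fid, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[length(rows) + 1L]] <- res
  }
  out <- bind_rows(rows)
  if (align && nrow(out) > 0) {
    out <- bind_rows(lapply(split(out, out$kind), align_and_crop))
    out <- arrange(out, .data$face_id, .data$kind, .data$side)
  }
  attr(out, "n_failed") <- n_failed
  out
}

#' Read faces (images + landmark files) from directories
#'
#' Pairs every image in `images_dir` (PNG/JPEG) with a landmark file of the
#' same base name (`.json` or `.csv`) in `landmarks_dir`.
#'
#' @param images_dir,landmarks_dir Input directories.
#' @param schema Landmark schema.
#' @return A faces tibble as accepted by [extract_features()]. Faces without
#'   a landmark file get `landmarks = NULL` (and are skipped downstream with
#'   a warning).
#' @export
read_faces <- function(images_dir, landmarks_dir, schema = default_schema()) {
  paths <- list.files(images_dir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(paths) == 0) ftx_abort("no images found", "format_error")
  ids <- tools::file_path_sans_ext(basename(paths))
  lms <- lapply(ids, function(id) {
    for (ext in c(".json", ".csv")) {
      p <- file.path(landmarks_dir, paste0(id, ext))
      if (file.exists(p)) {
        return(tryCatch(read_landmarks(p, schema, face_id = id),
                        facetax_error = function(e) NULL))
      }
    }
    NULL
  })
  tibble(face_id = ids, image = lapply(paths, read_face_image), landmarks = lms)
}
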