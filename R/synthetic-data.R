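# Synthetic inputs with known ground truth: cartoon faces with exact 49-point
# landmarks (optionally perfectly mirror-symmetric eyes, optionally a
# mustache), and planted-cluster image populations drawn from G prototype
# appearances plus pixel noise. Everything is deterministic given its seed,
# and intensities are quantized to the 8-bit grid as a real photograph's
# would be.

# Sample the per-face geometry (all integer pixel coordinates, so that the
# mirror map x -> w + 1 - x is exact and symmetric eyes survive rasterization
# bit-for-bit).
sample_placements <- function(canvas) {
  h <- canvas[1]; w <- canvas[2]
  jit <- function(k) sample(seq(-k, k), 1)
  list(
    eye_rx = sample(8:11, 1), eye_ry = sample(4:6, 1), iris_r = sample(2:3, 1),
    eye_cy = round(0.33 * h) + jit(3),
    eye_cx_right = round(0.72 * w) + jit(2),
    # used only when eyes are asymmetric
    eye_ry_left = sample(4:6, 1),
    nose_cx = floor((w + 1) / 2) + jit(1),
    nose_top = round(0.52 * h) + jit(2),
    nose_base = round(0.62 * h) + jit(2),
    nose_halfwidth = sample(11:15, 1),
    mouth_cx = floor((w + 1) / 2) + jit(1),
    mouth_cy = round(0.82 * h) + jit(2),
    mouth_rx = sample(15:19, 1), mouth_ry = sample(5:7, 1)
  )
}

eye_polygon <- function(cx, cy, rx, ry) {
  hx <- floor(rx / 2)
  cbind(x = cx + c(-rx, -hx, hx, rx, hx, -hx),
        y = cy + c(0, -ry, -ry, 0, ry, ry))
}

# Draw one eye (plus its eyebrow) on a zero canvas; returns canvas + touched set.
draw_eye_patch <- function(h, w, cx, cy, rx, ry, iris_r) {
  tmp <- matrix(NA_real_, h, w)
  tmp <- draw_ellipse(tmp, cx, cy, rx, ry, 0.30)
  tmp <- draw_ellipse(tmp, cx, cy, rx - 1, ry - 1, 0.92)
  tmp <- draw_ellipse(tmp, cx, cy, iris_r, iris_r, 0.12)
  # eyebrow: short thick arc above the eye
  bx <- cx + c(-rx, -floor(rx / 2), 0, floor(rx / 2), rx)
  by <- cy - ry - 9 + c(0, -2, -3, -2, 0)
  for (i in seq_along(bx)) tmp[by[i] + 0:1, bx[i] + 0:1] <- 0.28
  tmp
}

mirror_x <- function(x, w) w + 1 - x

#' Generate one synthetic face with known landmarks
#'
#' Draws a cartoon face (two eyes with eyebrows, a nose, a mouth) on a flat
#' skin-toned canvas and places all 49 landmarks of the default schema at
#' integer pixel positions consistent with the drawn features. With
#' `eye_symmetry = TRUE` the left half of the eye region is the exact
#' horizontal mirror of the right half, pixel for pixel. With
#' `mustache = TRUE` a dark band surrounds the mouth polygon.
#'
#' @param face_id Identifier string.
#' @param canvas `c(height, width)` in pixels.
#' @param eye_symmetry Left eye is the exact mirror of the right eye.
#' @param mustache Draw dark pixels around the mouth polygon.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param placements Optional named list overriding sampled geometry
#'   (see the source of `sample_placements()` for the names).
#' @return A list with `face_id`, `image` (matrix in \[0, 1\], 8-bit grid),
#'   `landmarks` (a [landmark_set()]), and `boxes`, a tibble of ground-truth
#'   polygon bounding boxes per feature.
#' @export
generate_face <- function(face_id = "face001", canvas = c(160, 140),
                          eye_symmetry = TRUE, mustache = FALSE, seed = 1,
                          placements = NULL) {
  h <- canvas[1]; w <- canvas[2]
  p <- withr::with_seed(seed, sample_placements(canvas))
  if (!is.null(placements)) p[names(placements)] <- placements
  if (eye_symmetry) p$eye_ry_left <- p$eye_ry

  cxr <- p$eye_cx_right
  cxl <- mirror_x(cxr, w)

  poly_eye_r <- eye_polygon(cxr, p$eye_cy, p$eye_rx, p$eye_ry)
  poly_eye_l <- if (eye_symmetry) {
    cbind(x = mirror_x(poly_eye_r[, 1], w), y = poly_eye_r[, 2])
  } else {
    eye_polygon(cxl, p$eye_cy, p$eye_rx, p$eye_ry_left)
  }
  poly_nose <- cbind(
    x = c(p$nose_cx, p$nose_cx + c(-p$nose_halfwidth, -floor(p$nose_halfwidth / 2), 0,
                                   floor(p$nose_halfwidth / 2), p$nose_halfwidth)),
    y = c(p$nose_top, rep(p$nose_base, 5))
  )
  ang12 <- seq(0, 330, by = 30) * pi / 180
  poly_mouth <- cbind(x = p$mouth_cx + round(p$mouth_rx * cos(ang12)),
                      y = p$mouth_cy + round(p$mouth_ry * sin(ang12)))
  inner_rx <- max(3, p$mouth_rx - 6); inner_ry <- max(2, p$mouth_ry - 3)
  ang6 <- seq(0, 300, by = 60) * pi / 180
  poly_mouth_in <- cbind(x = p$mouth_cx + round(inner_rx * cos(ang6)),
                         y = p$mouth_cy + round(inner_ry * sin(ang6)))

  check_face_layout(list(left_eye = poly_eye_l, right_eye = poly_eye_r,
                         nose = poly_nose, mouth = poly_mouth),
                    h = h, w = w, margin = 6)

  img <- matrix(0.80, h, w)
  # eyes (and eyebrows): right drawn once, left either mirrored or redrawn
  patch_r <- draw_eye_patch(h, w, cxr, p$eye_cy, p$eye_rx, p$eye_ry, p$iris_r)
  patch_l <- if (eye_symmetry) patch_r[, rev(seq_len(w))] else
    draw_eye_patch(h, w, cxl, p$eye_cy, p$eye_rx, p$eye_ry_left, p$iris_r)
  img[!is.na(patch_r)] <- patch_r[!is.na(patch_r)]
  img[!is.na(patch_l)] <- patch_l[!is.na(patch_l)]
  # mustache below/around the mouth, drawn before the lips so it surrounds them
  if (mustache) {
    img <- draw_ellipse(img, p$mouth_cx, p$mouth_cy, p$mouth_rx + 6, p$mouth_ry + 6, 0.12)
  }
  # nose: triangle rendered as stacked rows + nostrils
  for (y in p$nose_top:p$nose_base) {
    half <- p$nose_halfwidth * (y - p$nose_top) / (p$nose_base - p$nose_top)
    cols <- max(1, floor(p$nose_cx - half)):min(w, ceiling(p$nose_cx + half))
    img[y, cols] <- 0.62
  }
  img <- draw_ellipse(img, p$nose_cx - floor(p$nose_halfwidth / 2), p$nose_base - 1, 2, 2, 0.30)
  img <- draw_ellipse(img, p$nose_cx + floor(p$nose_halfwidth / 2), p$nose_base - 1, 2, 2, 0.30)
  # mouth: lips + darker opening
  img <- draw_ellipse(img, p$mouth_cx, p$mouth_cy, p$mouth_rx, p$mouth_ry, 0.35)
  img <- draw_ellipse(img, p$mouth_cx, p$mouth_cy, inner_rx, inner_ry, 0.15)
  img <- quantize8(img)

  pts <- matrix(NA_real_, 49, 2)
  brow <- function(cx, rx) cbind(cx + c(-rx, -floor(rx / 2), 0, floor(rx / 2), rx),
                                 p$eye_cy - p$eye_ry - 9 + c(0, -2, -3, -2, 0))
  pts[1:5, ] <- brow(cxl, p$eye_rx)
  pts[6:10, ] <- brow(cxr, p$eye_rx)
  pts[11:14, ] <- cbind(p$nose_cx,
                        round(seq(p$nose_top, p$nose_base - 6, length.out = 4)))
  pts[15:19, ] <- poly_nose[2:6, ]
  pts[20:25, ] <- poly_eye_l
  pts[26:31, ] <- poly_eye_r
  pts[32:43, ] <- poly_mouth
  pts[44:49, ] <- poly_mouth_in

  boxes <- bind_rows(
    box_row("eye", "left", poly_eye_l), box_row("eye", "right", poly_eye_r),
    box_row("nose", "none", poly_nose), box_row("mouth", "none", poly_mouth)
  )
  list(face_id = face_id, image = img,
       landmarks = landmark_set(face_id, pts), boxes = boxes)
}

box_row <- function(kind, side, poly) {
  b <- polygon_bbox(poly)
  tibble(kind = kind, side = side,
         xmin = b["xmin"], xmax = b["xmax"], ymin = b["ymin"], ymax = b["ymax"])
}

check_face_layout <- function(polys, h, w, margin) {
  boxes <- lapply(polys, function(p) polygon_bbox(p) + c(-margin, margin, -margin, margin))
  for (nm in names(boxes)) {
    b <- boxes[[nm]]
    if (b["xmin"] < 1 || b["ymin"] < 1 || b["xmax"] > w || b["ymax"] > h) {
      ftx_abort(sprintf("feature '%s' does not fit the canvas", nm), "geometry_error")
    }
  }
  nms <- names(boxes)
  for (i in seq_along(nms)[-1]) for (j in seq_len(i - 1)) {
    a <- boxes[[i]]; b <- boxes[[j]]
    if (a["xmin"] <= b["xmax"] && b["xmin"] <= a["xmax"] &&
        a["ymin"] <= b["ymax"] && b["ymin"] <= a["ymax"]) {
      ftx_abort(sprintf("feature placements overlap: %s and %s", nms[i], nms[j]),
                "geometry_error")
    }
  }
  invisible(TRUE)
}

#' Generate a population of synthetic faces
#'
#' @param n Number of faces.
#' @param canvas,eye_symmetry,mustache As in [generate_face()]; the last two
#'   are recycled to length `n`.
#' @param seed Master seed; per-face seeds are derived from it.
#' @param prefix Face id prefix (`prefix` + zero-padded index).
#' @return A tibble with columns `face_id`, `image` (list of matrices),
#'   `landmarks` (list of [landmark_set()]), `boxes` (list of tibbles).
#' @export
generate_faces <- function(n, canvas = c(160, 140), eye_symmetry = TRUE,
                           mustache = FALSE, seed = 1, prefix = "face") {
  stopifnot(n >= 1)
  eye_symmetry <- rep_len(eye_symmetry, n)
  mustache <- rep_len(mustache, n)
  face_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  faces <- purrr::pmap(list(ids, eye_symmetry, mustache, face_seeds),
                       function(id, sym, mus, s)
                         generate_face(id, canvas, sym, mus, seed = s))
  tibble(face_id = ids,
         image = map(faces, "image"),
         landmarks = map(faces, "landmarks"),
         boxes = map(faces, "boxes"),
         eye_symmetry = eye_symmetry, mustache = mustache)
}

#' Write synthetic faces to disk (PNG + landmark JSON per face)
#'
#' @param faces Tibble from [generate_faces()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic_faces <- function(faces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(faces))) {
    write_face_image(faces$image[[i]], file.path(dir, paste0(faces$face_id[i], ".png")))
    write_landmarks(faces$landmarks[[i]], file.path(dir, paste0(faces$face_id[i], ".json")))
  }
  invisible(dir)
}

#' Procedural prototype images for planted-cluster benchmarks
#'
#' Draws `g` blob prototypes — ellipses of varying width, height and
#' darkness placed at distinct positions around the canvas — so the
#' appearances stay well separated even after per-image standardization.
#'
#' @param g Number of prototypes (>= 2).
#' @param shape `c(height, width)` of each prototype.
#' @return List of `g` matrices in \[0, 1\] (8-bit grid), with attribute
#'   `separation`, the minimum pairwise Euclidean distance.
#' @export
make_prototypes <- function(g, shape = c(16, 16)) {
  stopifnot(g >= 2)
  h <- shape[1]; w <- shape[2]
  cy0 <- (h + 1) / 2; cx0 <- (w + 1) / 2
  ang <- 2 * pi * (seq_len(g) - 1) / g
  cxs <- round(cx0 + 0.22 * w * cos(ang))
  cys <- round(cy0 + 0.22 * h * sin(ang))
  rxs <- round(seq(0.18, 0.30, length.out = g) * w)
  rys <- round(seq(0.30, 0.18, length.out = g) * h)
  vals <- rep(c(0.08, 0.35), length.out = g)
  protos <- lapply(seq_len(g), function(i) {
    img <- matrix(0.9, h, w)
    quantize8(draw_ellipse(img, cxs[i], cys[i],
                           max(2, rxs[i]), max(2, rys[i]), vals[i]))
  })
  d <- as.matrix(dist(t(vapply(protos, as.vector, numeric(h * w)))))
  attr(protos, "separation") <- min(d[upper.tri(d)])
  protos
}

#' Generate a planted-cluster image population
#'
#' Each image is its prototype plus i.i.d. Gaussian pixel noise, clipped to
#' \[0, 1\] and quantized to the 8-bit grid; the true label of every image is
#' recorded.
#'
#' @param prototypes List of same-shape grayscale prototype matrices
#'   (e.g. from [make_prototypes()]).
#' @param members_per_cluster Images per prototype (>= 1).
#' @param noise_sd Pixel-noise standard deviation (>= 0, intensity units).
#' @param seed Integer seed.
#' @return Tibble with `image_id`, `label` (1-based prototype index),
#'   `pixels` (list of matrices).
#' @export
generate_planted_features <- function(prototypes, members_per_cluster,
                                      noise_sd, seed = 1) {
  g <- length(prototypes)
  if (g < 2) ftx_abort("need at least 2 prototypes", "parameter_error")
  if (members_per_cluster < 1) ftx_abort("members_per_cluster must be >= 1", "parameter_error")
  if (noise_sd < 0) ftx_abort("noise_sd must be >= 0", "parameter_error")
  shp <- dim(prototypes[[1]])
  if (!all(vapply(prototypes, function(p) identical(dim(p), shp), TRUE))) {
    ftx_abort("all prototypes must have the same shape", "parameter_error")
  }
  labels <- rep(seq_len(g), each = members_per_cluster)
  imgs <- withr::with_seed(seed, lapply(labels, function(l) {
    noise <- if (noise_sd > 0) matrix(rnorm(prod(shp), 0, noise_sd), shp[1], shp[2]) else 0
    quantize8(clip01(prototypes[[l]] + noise))
  }))
  tibble(image_id = sprintf("img%04d", seq_along(labels)),
         label = labels, pixels = imgs)
}
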