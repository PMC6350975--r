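# Internal geometry and image helpers.
#
# Images are numeric matrices with rows = y (top to bottom), columns = x,
# intensities in [0, 1]. Polygons are two-column matrices (x, y) of vertex
# coordinates in the 1-based pixel grid of the image they refer to.

ftx_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("facetax_", class), "facetax_error"), ...)
}

as_polygon <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2 || nrow(p) < 3 || !is.numeric(p) || any(!is.finite(p))) {
    ftx_abort("a polygon needs >= 3 finite (x, y) vertices", "geometry_error")
  }
  colnames(p) <- c("x", "y")
  p
}

# Shoelace area of a simple polygon (absolute value).
polygon_area <- function(poly) {
  p <- as_polygon(poly)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_centroid <- function(poly) {
  p <- as_polygon(poly)
  c(x = mean(p[, 1]), y = mean(p[, 2]))
}

polygon_bbox <- function(poly) {
  p <- as_polygon(poly)
  c(xmin = min(p[, 1]), xmax = max(p[, 1]), ymin = min(p[, 2]), ymax = max(p[, 2]))
}

# Orientation of the polygon's principal axis, degrees in [-90, 90].
# 0 means the long axis is horizontal.
polygon_rotation <- function(poly) {
  p <- as_polygon(poly)
  cx <- sweep(p, 2, colMeans(p))
  cv <- crossprod(cx) / (nrow(p) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  v <- ev$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  ang
}

# Rasterize a polygon into a binary h x w mask, inclusive of boundary pixels.
# Pixel (row r, col c) is tested at the point (x = c, y = r).
rasterize_polygon <- function(poly, h, w) {
  p <- as_polygon(poly)
  if (polygon_area(p) == 0) {
    ftx_abort("degenerate (zero-area) polygon cannot be rasterized", "geometry_error")
  }
  mask <- matrix(0, h, w)
  xr <- max(1L, floor(min(p[, 1]))):min(w, ceiling(max(p[, 1])))
  yr <- max(1L, floor(min(p[, 2]))):min(h, ceiling(max(p[, 2])))
  if (length(xr) == 0 || length(yr) == 0) return(mask)
  gx <- rep(xr, times = length(yr))
  gy <- rep(yr, each = length(xr))
  inside <- pracma::inpolygon(gx, gy, p[, 1], p[, 2], boundary = TRUE)
  mask[cbind(gy[inside], gx[inside])] <- 1
  mask
}

# Isotropic morphological dilation by a disc of radius r pixels.
dilate_mask <- function(mask, r) {
  stopifnot(r >= 0)
  if (r == 0) return(mask)
  brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  EBImage::imageData(EBImage::dilate(EBImage::Image(mask), brush))
}

# Gaussian blur with a compact kernel; values far from support stay exactly 0.
blur_mask <- function(mask, sigma) {
  if (sigma <= 0) return(mask)
  EBImage::imageData(EBImage::gblur(EBImage::Image(mask), sigma = sigma))
}

# Integer translation; pixels shifted out are dropped, revealed pixels fill.
shift_image <- function(img, dy, dx, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Quantize intensities to the 8-bit grid (stored as k/255).
quantize8 <- function(x) round(clip01(x) * 255) / 255

# Fill an ellipse on a canvas; returns the modified canvas.
draw_ellipse <- function(img, cx, cy, rx, ry, value) {
  h <- nrow(img); w <- ncol(img)
  xr <- max(1L, floor(cx - rx)):min(w, ceiling(cx + rx))
  yr <- max(1L, floor(cy - ry)):min(h, ceiling(cy + ry))
  for (y in yr) {
    dx2 <- 1 - ((y - cy) / ry)^2
    if (dx2 < 0) next
    half <- rx * sqrt(dx2)
    cols <- xr[xr >= cx - half & xr <= cx + half]
    if (length(cols)) img[y, cols] <- value
  }
  img
}

# Columns of a coefficient table that hold metadata, not coordinates.
.id_cols <- c("feature_id", "face_id", "image_id", "kind", "side", "label")

# Accept a numeric matrix or a tibble with id columns + numeric coefficient
# columns; return a numeric matrix with rownames taken from feature ids.
as_coef_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.data.frame(x)) {
    ids <- intersect(names(x), .id_cols)
    num <- setdiff(names(x), ids)
    m <- as.matrix(x[num])
    if (!is.numeric(m)) ftx_abort("coefficient columns must be numeric", "parameter_error")
    rn <- if ("feature_id" %in% names(x)) x$feature_id else if ("image_id" %in% names(x)) x$image_id
    if (!is.null(rn)) rownames(m) <- rn
    return(m)
  }
  ftx_abort("expected a matrix or data frame of coefficients", "parameter_error")
}

coef_colnames <- function(m) sprintf("e%02d", seq_len(m))
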