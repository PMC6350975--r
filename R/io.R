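# Readers and writers for images, landmarks, schemas, taxonomies and
# coefficient tables. All readers validate and fail with typed errors;
# they never return partially-filled objects.

#' Default 49-point landmark schema
#'
#' The 49-point layout groups landmarks as: eyebrows 1–10, nose 11–19
#' (bridge 11–14 top to bottom, base 15–19 left to right), left eye 20–25,
#' right eye 26–31 (six points around each eye, image left/right), outer
#' mouth contour 32–43, inner mouth contour 44–49. The exact index-to-part
#' mapping is a configurable assumption: pass any JSON schema file with the
#' same structure to override it.
#'
#' @param path Optional path to a schema JSON file. Defaults to the schema
#'   shipped with the package.
#' @return A `facetax_schema`: a list with `name` and `features`, the latter
#'   a named list of 1-based landmark index vectors (`left_eye`, `right_eye`,
#'   `nose`, `mouth`, `mouth_outer`), each ordered around its polygon.
#' @export
read_schema <- function(path = NULL) {
  path <- path %||% system.file("extdata", "schema_49.json", package = "facetax")
  if (!file.exists(path)) ftx_abort("schema file not found", "format_error")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- lapply(raw$features, function(v) as.integer(v) + 1L)  # file is 0-based
  schema <- structure(list(name = raw$name %||% basename(path), features = feats),
                      class = "facetax_schema")
  validate_schema(schema)
  schema
}

#' @rdname read_schema
#' @export
default_schema <- function() read_schema()

validate_schema <- function(schema) {
  f <- schema$features
  need <- c("left_eye", "right_eye", "nose", "mouth", "mouth_outer")
  if (!all(need %in% names(f))) {
    ftx_abort(paste("schema must define:", paste(need, collapse = ", ")), "schema_error")
  }
  idx <- unlist(f)
  if (any(idx < 1L | idx > 49L)) ftx_abort("schema indices must lie in 0..48", "schema_error")
  if (length(intersect(f$left_eye, f$right_eye)) > 0) {
    ftx_abort("eye index lists must be disjoint", "schema_error")
  }
  if (any(vapply(f, length, 1L) < 3L)) {
    ftx_abort("every feature polygon needs >= 3 landmark indices", "schema_error")
  }
  invisible(schema)
}

#' Construct a landmark set
#'
#' @param face_id Identifier of the source face.
#' @param points A 49 x 2 matrix or data frame of (x, y) pixel coordinates,
#'   1-based, x = column, y = row, origin top-left.
#' @param schema_name Name of the index-to-feature-part mapping in use.
#' @return A `facetax_landmarks` object.
#' @export
landmark_set <- function(face_id, points, schema_name = "schema_49") {
  points <- as.matrix(points)
  if (nrow(points) != 49L || ncol(points) != 2L) {
    ftx_abort("a landmark set has exactly 49 (x, y) points", "schema_error")
  }
  if (!is.numeric(points) || any(!is.finite(points))) {
    ftx_abort("landmark coordinates must be finite numbers", "parse_error")
  }
  colnames(points) <- c("x", "y")
  structure(list(face_id = as.character(face_id), points = points,
                 schema_name = schema_name),
            class = "facetax_landmarks")
}

#' @export
print.facetax_landmarks <- function(x, ...) {
  cat("<facetax_landmarks> face", x$face_id, "-", nrow(x$points), "points\n")
  invisible(x)
}

#' Read a face image as a grayscale intensity matrix
#'
#' RGB images are converted with ITU-R BT.601 luma weights
#' (0.299, 0.587, 0.114).
#'
#' @param path A PNG or JPEG file.
#' @return A numeric matrix, rows = y, columns = x, intensities in \[0, 1\].
#' @export
read_face_image <- function(path) {
  img <- tryCatch(suppressWarnings(EBImage::readImage(path)),
                  error = function(e) ftx_abort(paste("cannot decode image:", path),
                                                "format_error", parent = e))
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3L) {
    if (dim(d)[3] >= 3L) {
      d <- 0.299 * d[, , 1] + 0.587 * d[, , 2] + 0.114 * d[, , 3]
    } else {
      d <- d[, , 1]
    }
  }
  clip01(t(d))  # EBImage stores x in the first dimension
}

#' Write a grayscale image matrix to a PNG (or JPEG) file
#'
#' @param img Numeric matrix in \[0, 1\], rows = y.
#' @param path Output path; format from the extension.
#' @export
write_face_image <- function(img, path) {
  EBImage::writeImage(EBImage::Image(t(clip01(img))), path)
  invisible(path)
}

#' Read facial landmarks from JSON or CSV
#'
#' JSON files follow `{"face_id": ..., "points": [[x, y] * 49]}`; CSV files
#' have a header `x,y` and 49 rows. File coordinates are 0-based pixel
#' positions (x = column, y = row, origin top-left); the returned object is
#' 1-based to match R matrix indexing.
#'
#' @param path Landmark file (`.json` or `.csv`).
#' @param schema A `facetax_schema` used downstream (recorded by name).
#' @param face_id Face identifier; defaults to the JSON field or the file
#'   base name for CSV.
#' @return A `facetax_landmarks` object.
#' @export
read_landmarks <- function(path, schema = default_schema(), face_id = NULL) {
  if (!file.exists(path)) ftx_abort(paste("no such landmark file:", path), "format_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e) ftx_abort("cannot parse landmark JSON",
                                                  "parse_error", parent = e))
    pts <- raw$points
    face_id <- face_id %||% raw$face_id %||% tools::file_path_sans_ext(basename(path))
  } else if (ext == "csv") {
    raw <- tryCatch(read.csv(path),
                    error = function(e) ftx_abort("cannot parse landmark CSV",
                                                  "parse_error", parent = e))
    if (!all(c("x", "y") %in% names(raw))) {
      ftx_abort("landmark CSV needs columns 'x' and 'y'", "schema_error")
    }
    pts <- as.matrix(raw[, c("x", "y")])
    face_id <- face_id %||% tools::file_path_sans_ext(basename(path))
  } else {
    ftx_abort("landmark files must be .json or .csv", "format_error")
  }
  pts <- as.matrix(pts)
  if (is.null(dim(pts)) || nrow(pts) != 49L || ncol(pts) != 2L) {
    ftx_abort(sprintf("expected 49 landmark points, found %s",
                      if (is.null(dim(pts))) length(pts) else nrow(pts)),
              "schema_error")
  }
  if (!is.numeric(pts) || any(!is.finite(pts))) {
    ftx_abort("non-numeric landmark coordinates", "parse_error")
  }
  landmark_set(face_id, pts + 1, schema_name = schema$name)
}

#' Write landmarks as JSON (0-based file coordinates)
#'
#' @param landmarks A `facetax_landmarks` object.
#' @param path Output `.json` path.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "facetax_landmarks"))
  pts <- unname(landmarks$points) - 1
  obj <- list(face_id = landmarks$face_id,
              points = lapply(seq_len(nrow(pts)), function(i) pts[i, ]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

TAXONOMY_FORMAT_VERSION <- "1.0"

#' Write / read a taxonomy as JSON
#'
#' The round trip is lossless: cluster codes and order, member ids,
#' percentages, representative ids and centroid coefficients are preserved
#' (coefficients to full double precision).
#'
#' @param taxonomy A `facetax_taxonomy` object (see [build_taxonomy()]).
#' @param path JSON file path.
#' @return `read_taxonomy()` returns a `facetax_taxonomy`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  stopifnot(inherits(taxonomy, "facetax_taxonomy"))
  cl <- taxonomy$clusters
  obj <- list(
    format_version = TAXONOMY_FORMAT_VERSION,
    ethnic_code = taxonomy$ethnic_code,
    kind_code = taxonomy$kind_code,
    n_total = taxonomy$n_total,
    clusters = lapply(seq_len(nrow(cl)), function(i) list(
      code = cl$code[i],
      rank = cl$rank[i],
      size = cl$size[i],
      percentage = cl$percentage[i],
      representative_id = cl$representative_id[i],
      member_ids = cl$member_ids[[i]],
      centroid = cl$centroid[[i]],
      representative_coef = cl$representative_coef[[i]]
    )),
    removed_secs = lapply(seq_len(nrow(taxonomy$removed_secs)), function(i) list(
      member_ids = taxonomy$removed_secs$member_ids[[i]],
      reason = taxonomy$removed_secs$reason[i]
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) ftx_abort(paste("no such taxonomy file:", path), "format_error")
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) ftx_abort("cannot parse taxonomy JSON",
                                                "parse_error", parent = e))
  if (!identical(raw$format_version, TAXONOMY_FORMAT_VERSION)) {
    ftx_abort(sprintf("taxonomy format version mismatch: file has %s, expected %s",
                      raw$format_version %||% "<none>", TAXONOMY_FORMAT_VERSION),
              "version_error")
  }
  clusters <- tibble::tibble(
    code = map_chr(raw$clusters, "code"),
    rank = map_int(raw$clusters, ~ as.integer(.x$rank)),
    size = map_int(raw$clusters, ~ as.integer(.x$size)),
    percentage = map_dbl(raw$clusters, "percentage"),
    representative_id = map_chr(raw$clusters, "representative_id"),
    member_ids = map(raw$clusters, ~ as.character(unlist(.x$member_ids))),
    centroid = map(raw$clusters, ~ as.numeric(unlist(.x$centroid))),
    representative_coef = map(raw$clusters, ~ as.numeric(unlist(.x$representative_coef)))
  )
  removed <- tibble::tibble(
    member_ids = map(raw$removed_secs, ~ as.character(unlist(.x$member_ids))),
    reason = map_chr(raw$removed_secs, ~ as.character(.x$reason))
  )
  new_taxonomy(ethnic_code = raw$ethnic_code, kind_code = raw$kind_code,
               n_total = as.integer(raw$n_total), clusters = clusters,
               removed_secs = removed)
}

#' Write / read a coefficient table as CSV
#'
#' Rows are features, columns are id columns plus coefficients `e01`, `e02`,
#' ... (header = feature ids and coefficient names).
#'
#' @param coeffs A tibble as returned by [encode_features()].
#' @param path CSV path.
#' @export
write_coefficients <- function(coeffs, path) {
  write.csv(coeffs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) ftx_abort(paste("no such file:", path), "format_error")
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
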