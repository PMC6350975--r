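# From a selected cluster solution to a coded taxonomy: SEC outlier review,
# ranking by membership, four-character cluster codes, representative
# features, nearest-centroid classification, and face codes.

#' Review single-element clusters and eliminate outliers
#'
#' SECs are removed when their members look like preprocessing failures. In
#' automatic mode a member is an outlier when its landmark polygon is
#' oversized (area above `area_threshold` of its image canvas) or rotated
#' (principal axis more than `rotation_threshold` degrees off horizontal) —
#' the two failure causes the screens are designed to catch. In manual mode
#' an explicit list of cluster labels decides.
#'
#' @param solution A selected `facetax_kmeans` (from [select_k()]), or any
#'   `facetax_kmeans` plus `kind`/`pairing` to recompute its SECs.
#' @param features Feature table supplying polygons and canvas sizes;
#'   may be NULL (no geometry available — SECs are then all retained in
#'   automatic mode).
#' @param auto Automatic screening (default) or manual removal.
#' @param remove Manual mode: integer cluster labels to remove.
#' @param area_threshold Fraction of the canvas area above which a polygon
#'   is oversized. Default 0.6.
#' @param rotation_threshold Degrees of principal-axis rotation above which
#'   a polygon is rotated. Default 15.
#' @param kind,pairing Used to (re)compute SEC labels when the solution does
#'   not carry them.
#' @return A list: `kept_labels` (cluster labels retained) and
#'   `removed_secs`, a tibble with `cluster`, `member_ids`, `reason`.
#' @export
review_secs <- function(solution, features = NULL, auto = TRUE, remove = NULL,
                        area_threshold = 0.6, rotation_threshold = 15,
                        kind = NULL, pairing = NULL) {
  stopifnot(inherits(solution, "facetax_kmeans"))
  secs <- solution$sec_clusters %||% count_secs(solution, kind, pairing)
  all_labels <- sort(unique(solution$assignments))
  removed <- tibble(cluster = integer(), member_ids = list(), reason = character())
  for (s in secs) {
    ids <- names(solution$assignments)[solution$assignments == s]
    if (auto) {
      reasons <- character()
      if (!is.null(features) && "polygon" %in% names(features)) {
        rows <- features[features$feature_id %in% ids, ]
        for (i in seq_len(nrow(rows))) {
          poly <- rows$polygon[[i]]
          canvas <- prod(dim(rows$pixels[[i]]))
          if (polygon_area(poly) / canvas > area_threshold) {
            reasons <- c(reasons, "oversized")
          }
          if (abs(polygon_rotation(poly)) > rotation_threshold) {
            reasons <- c(reasons, "rotated")
          }
        }
      }
      if (length(reasons) > 0) {
        removed <- bind_rows(removed, tibble(
          cluster = s, member_ids = list(ids),
          reason = paste(unique(reasons), collapse = "+")))
      }
    } else if (s %in% remove) {
      removed <- bind_rows(removed, tibble(cluster = s, member_ids = list(ids),
                                           reason = "manual"))
    }
  }
  list(kept_labels = setdiff(all_labels, removed$cluster), removed_secs = removed)
}

new_taxonomy <- function(ethnic_code, kind_code, n_total, clusters, removed_secs) {
  structure(list(ethnic_code = ethnic_code, kind_code = kind_code,
                 n_total = n_total, clusters = clusters,
                 removed_secs = removed_secs),
            class = "facetax_taxonomy")
}

#' Build a coded taxonomy from a cluster solution
#'
#' Kept clusters are ranked by membership percentage (computed over the
#' pre-removal subset size, so percentages of kept plus removed members sum
#' to 100). Codes are ethnic letter + kind letter + two-digit rank, e.g.
#' `"AM01"` for the most populated cluster of Asian mouths. The
#' representative of a cluster is its member closest (Euclidean, in
#' coefficient space) to the centroid; ties break to the lexicographically
#' smallest feature id.
#'
#' @param solution A `facetax_kmeans` (ideally from [select_k()]).
#' @param coeffs Coefficient tibble/matrix the solution was fit on.
#' @param ethnic_code One uppercase letter (e.g. `"A"`, `"B"`, `"L"`,
#'   `"W"`).
#' @param kind_code `"M"`, `"N"` or `"E"`.
#' @param review Optional result of [review_secs()]; by default nothing is
#'   removed.
#' @return A `facetax_taxonomy`.
#' @export
build_taxonomy <- function(solution, coeffs, ethnic_code, kind_code,
                           review = NULL) {
  stopifnot(inherits(solution, "facetax_kmeans"))
  if (!grepl("^[A-Z]$", ethnic_code)) {
    ftx_abort("ethnic_code must be a single uppercase letter", "parameter_error")
  }
  if (!kind_code %in% c("M", "N", "E")) {
    ftx_abort("kind_code must be 'M', 'N' or 'E'", "parameter_error")
  }
  m <- as_coef_matrix(coeffs)
  ids <- rownames(m) %||% sprintf("feature%04d", seq_len(nrow(m)))
  labels <- solution$assignments
  n_total <- length(labels)
  kept <- if (is.null(review)) sort(unique(labels)) else review$kept_labels
  rows <- lapply(kept, function(lab) {
    member_idx <- which(labels == lab)
    member_ids <- ids[member_idx]
    cen <- solution$centroids[lab, ]
    d <- sqrt(colSums((t(m[member_idx, , drop = FALSE]) - cen)^2))
    ord <- order(d, member_ids)
    rep_id <- member_ids[ord[1]]
    tibble(label = lab, size = length(member_idx),
           percentage = 100 * length(member_idx) / n_total,
           representative_id = rep_id,
           member_ids = list(member_ids),
           centroid = list(unname(cen)),
           representative_coef = list(unname(m[member_idx[ord[1]], ])))
  })
  cl <- bind_rows(rows) |> arrange(desc(.data$percentage), .data$label)
  cl$rank <- seq_len(nrow(cl))
  cl$code <- sprintf("%s%s%02d", ethnic_code, kind_code, cl$rank)
  cl <- select(cl, "code", "rank", "size", "percentage", "representative_id",
               "member_ids", "centroid", "representative_coef")
  removed <- if (is.null(review)) {
    tibble(member_ids = list(), reason = character())
  } else {
    select(review$removed_secs, "member_ids", "reason")
  }
  new_taxonomy(ethnic_code, kind_code, n_total, cl, removed)
}

#' @export
print.facetax_taxonomy <- function(x, ...) {
  cat(sprintf("<facetax_taxonomy> %s/%s: %d clusters over %d features (%d SEC(s) removed)\n",
              x$ethnic_code, x$kind_code, nrow(x$clusters), x$n_total,
              nrow(x$removed_secs)))
  print(tidy(x))
  invisible(x)
}

#' @describeIn build_taxonomy `tidy()` returns one row per cluster: code,
#'   rank, size, percentage, representative id.
#' @param x A `facetax_taxonomy`.
#' @param ... Unused.
#' @method tidy facetax_taxonomy
#' @export
tidy.facetax_taxonomy <- function(x, ...) {
  select(x$clusters, "code", "rank", "size", "percentage", "representative_id")
}

#' @describeIn build_taxonomy `glance()` returns a one-row summary.
#' @method glance facetax_taxonomy
#' @export
glance.facetax_taxonomy <- function(x, ...) {
  tibble(ethnic_code = x$ethnic_code, kind_code = x$kind_code,
         n_clusters = nrow(x$clusters), n_total = x$n_total,
         n_removed_secs = nrow(x$removed_secs),
         coverage_pct = sum(x$clusters$percentage))
}

#' Membership bar chart of a taxonomy
#'
#' @param object A `facetax_taxonomy`.
#' @param ... Unused.
#' @return A ggplot of membership percentage by cluster code.
#' @method autoplot facetax_taxonomy
#' @export
autoplot.facetax_taxonomy <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = stats::reorder(.data$code, .data$rank),
                                   y = .data$percentage)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Membership (% of subset)") +
    ggplot2::theme_minimal()
}

#' Assign taxonomy membership to features
#'
#' `classify_feature()` encodes one feature image with the eigenface model
#' and assigns it to the nearest kept-cluster centroid; its cluster code is
#' returned. `classify_encoded()` does the same for already-encoded
#' coefficient rows.
#'
#' @param model An `eigen_model`.
#' @param taxonomy A `facetax_taxonomy`.
#' @param pixels Feature image matrix of the model's shape.
#' @param normalize Standardize the image before encoding (set to FALSE for
#'   images already on the model's standardized scale, e.g. [reconstruct()]
#'   outputs).
#' @return `classify_feature()`: a single cluster code.
#' @export
classify_feature <- function(model, taxonomy, pixels, normalize = TRUE) {
  co <- encode_vector(model, pixels, normalize)
  classify_coef(taxonomy, co)
}

classify_coef <- function(taxonomy, co) {
  cens <- do.call(rbind, taxonomy$clusters$centroid)
  d2 <- colSums((t(cens) - co)^2)
  taxonomy$clusters$code[which.min(d2)]
}

#' @rdname classify_feature
#' @param coeffs Coefficient tibble or matrix.
#' @return `classify_encoded()`: tibble with `feature_id` and `code`.
#' @export
classify_encoded <- function(taxonomy, coeffs) {
  m <- as_coef_matrix(coeffs)
  codes <- vapply(seq_len(nrow(m)), function(i) classify_coef(taxonomy, m[i, ]),
                  character(1))
  tibble(feature_id = rownames(m) %||% sprintf("feature%04d", seq_len(nrow(m))),
         code = codes)
}

#' Compose a whole-face code from per-feature cluster codes
#'
#' Faces are coded as ethnic letter, a hyphen, then the mouth, nose and eye
#' cluster codes, e.g. `"A-M01N01E01"`.
#'
#' @param ethnic One uppercase letter.
#' @param mouth_code,nose_code,eye_code Four-character cluster codes whose
#'   ethnic letters must all equal `ethnic`.
#' @return The face code string.
#' @export
face_code <- function(ethnic, mouth_code, nose_code, eye_code) {
  codes <- c(mouth = mouth_code, nose = nose_code, eye = eye_code)
  kinds <- c("M", "N", "E")
  for (i in seq_along(codes)) {
    if (!grepl(sprintf("^[A-Z]%s[0-9]{2}$", kinds[i]), codes[i])) {
      ftx_abort(sprintf("malformed %s cluster code: %s", names(codes)[i], codes[i]),
                "parameter_error")
    }
    if (substr(codes[i], 1, 1) != ethnic) {
      ftx_abort("component codes must share the face's ethnic letter", "parameter_error")
    }
  }
  sprintf("%s-%s%s%s", ethnic, substr(mouth_code, 2, 4),
          substr(nose_code, 2, 4), substr(eye_code, 2, 4))
}
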