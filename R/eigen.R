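# Eigenface encoding of feature images.
#
# Each image is vectorized, standardized to zero mean and unit variance
# (per image), and the principal components of the standardized set are
# computed by thin SVD of the n x p centered matrix (the snapshot method:
# n images, p pixels, n << p). A feature is then described by its first M
# projection coefficients.

normalize_image_matrix <- function(features) {
  shp <- dim(features$pixels[[1]])
  if (!all(map_lgl(features$pixels, ~ identical(dim(.x), shp)))) {
    ftx_abort("all feature images must have the same shape", "parameter_error")
  }
  X <- t(vapply(features$pixels, as.vector, numeric(prod(shp))))
  mu <- rowMeans(X)
  sg <- apply(X, 1, sd)
  if (any(sg == 0)) {
    ftx_abort("zero-variance image(s): cannot standardize", "parameter_error")
  }
  ids <- features[["feature_id"]] %||% features[["image_id"]] %||%
    sprintf("img%04d", seq_len(nrow(features)))
  list(Z = (X - mu) / sg, shape = shp,
       norm = tibble(feature_id = ids, mean = mu, sd = sg))
}

#' Fit an eigenface model to a set of feature images
#'
#' @param features A feature table of one kind with same-size images
#'   (see [extract_features()]), or any tibble with `feature_id` and `pixels`
#'   list-column.
#' @param m Number of eigenfaces (coefficients) to keep. Default 45.
#' @return An `eigen_model`: mean vector, `m` orthonormal components ordered
#'   by explained variance, component variances, total variance, and the
#'   per-image standardization parameters needed for de-normalization.
#' @export
fit_eigenmodel <- function(features, m = 45) {
  if (!"pixels" %in% names(features)) ftx_abort("features need a 'pixels' column", "parameter_error")
  n <- nrow(features)
  if (n <= m) {
    ftx_abort(sprintf(paste("m = %d eigenfaces require at least m + 1 = %d images",
                            "(have %d); lower m"), m, m + 1, n),
              "parameter_error")
  }
  nz <- normalize_image_matrix(features)
  mean_vector <- colMeans(nz$Z)
  C <- sweep(nz$Z, 2, mean_vector)
  sv <- svd(C)
  variances <- sv$d^2 / (n - 1)
  comps <- sv$v[, seq_len(m), drop = FALSE]
  # deterministic sign: largest-magnitude entry of each component is positive
  for (j in seq_len(m)) {
    i <- which.max(abs(comps[, j]))
    if (comps[i, j] < 0) comps[, j] <- -comps[, j]
  }
  total <- sum(variances)
  if (total <= 0) ftx_abort("image set has zero total variance", "parameter_error")
  structure(list(
    kind = if ("kind" %in% names(features)) features$kind[1] else NA_character_,
    image_shape = nz$shape,
    mean_vector = mean_vector,
    components = comps,
    component_variances = variances[seq_len(m)],
    all_variances = variances,
    total_variance = total,
    normalization = nz$norm,
    n_images = n, m = m
  ), class = "eigen_model")
}

#' @export
print.eigen_model <- function(x, ...) {
  cat(sprintf("<eigen_model> %d x %d px, %d images, M = %d, %.1f%% variance explained\n",
              x$image_shape[1], x$image_shape[2], x$n_images, x$m,
              100 * explained_variance(x, x$m)))
  invisible(x)
}

#' Fraction of variance explained by the first m eigenfaces
#'
#' @param model An `eigen_model`.
#' @param m Number of leading components, `1 <= m <= model$m`.
#' @return A fraction in \[0, 1\]; 1 at the full rank of the data.
#' @export
explained_variance <- function(model, m) {
  stopifnot(inherits(model, "eigen_model"))
  if (m < 1 || m > model$m) ftx_abort("m out of range", "parameter_error")
  sum(model$component_variances[seq_len(m)]) / model$total_variance
}

standardize_pixels <- function(pixels) {
  v <- as.vector(pixels)
  s <- sd(v)
  if (s == 0) ftx_abort("zero-variance image cannot be standardized", "parameter_error")
  (v - mean(v)) / s
}

encode_vector <- function(model, pixels, normalize = TRUE) {
  if (!identical(dim(pixels), model$image_shape)) {
    ftx_abort("image shape does not match the model", "parameter_error")
  }
  v <- if (normalize) standardize_pixels(pixels) else as.vector(pixels)
  drop(crossprod(model$components, v - model$mean_vector))
}

#' Encode feature images as eigenface coefficients
#'
#' Projects each standardized, mean-centered image onto the model's
#' components.
#'
#' @param features A feature table (or tibble with `feature_id` + `pixels`).
#' @param model An `eigen_model` of matching image shape.
#' @param normalize Standardize each image before projecting (the default;
#'   set to FALSE for images already in the model's standardized space, such
#'   as [reconstruct()] outputs).
#' @return A tibble with the feature table's id columns plus coefficient
#'   columns `e01` ... `eM`.
#' @export
encode_features <- function(features, model, normalize = TRUE) {
  stopifnot(inherits(model, "eigen_model"))
  co <- t(vapply(features$pixels, function(p) encode_vector(model, p, normalize),
                 numeric(model$m)))
  colnames(co) <- coef_colnames(model$m)
  ids <- intersect(names(features), .id_cols)
  dplyr::bind_cols(features[ids], as_tibble(co))
}

#' Reconstruct an image from eigenface coefficients
#'
#' Computes mean + sum(c_i * component_i) and reshapes to the model's image
#' shape. With `denormalize = TRUE` the stored standardization parameters of
#' a known training feature are inverted, returning the image on its
#' original intensity scale.
#'
#' @param model An `eigen_model`.
#' @param coefficients Numeric vector, length <= `model$m`.
#' @param denormalize Undo the per-image standardization (requires
#'   `feature_id`).
#' @param feature_id Training feature whose normalization to invert.
#' @return An image matrix (standardized scale unless `denormalize`).
#' @export
reconstruct <- function(model, coefficients, denormalize = FALSE,
                        feature_id = NULL) {
  stopifnot(inherits(model, "eigen_model"))
  k <- length(coefficients)
  if (k > model$m) ftx_abort("more coefficients than model components", "parameter_error")
  v <- model$mean_vector
  if (k > 0) v <- v + drop(model$components[, seq_len(k), drop = FALSE] %*% coefficients)
  if (denormalize) {
    if (is.null(feature_id) || !feature_id %in% model$normalization$feature_id) {
      ftx_abort("unknown feature id for de-normalization", "parameter_error")
    }
    i <- match(feature_id, model$normalization$feature_id)
    v <- v * model$normalization$sd[i] + model$normalization$mean[i]
  }
  matrix(v, model$image_shape[1], model$image_shape[2])
}

#' @describeIn fit_eigenmodel `tidy()` returns one row per component with its
#'   variance, proportion of variance, and cumulative proportion.
#' @param x An `eigen_model`.
#' @param ... Unused.
#' @method tidy eigen_model
#' @export
tidy.eigen_model <- function(x, ...) {
  tibble(component = seq_len(x$m),
         variance = x$component_variances,
         prop_variance = x$component_variances / x$total_variance,
         cum_variance = cumsum(x$component_variances) / x$total_variance)
}

#' @describeIn fit_eigenmodel `glance()` returns a one-row model summary.
#' @method glance eigen_model
#' @export
glance.eigen_model <- function(x, ...) {
  tibble(n_images = x$n_images, m = x$m,
         image_height = x$image_shape[1], image_width = x$image_shape[2],
         prop_variance = explained_variance(x, x$m))
}

#' Scree plot of an eigenface model
#'
#' @param object An `eigen_model`.
#' @param ... Unused.
#' @return A ggplot of cumulative explained variance against the number of
#'   components.
#' @method autoplot eigen_model
#' @export
autoplot.eigen_model <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$component, y = .data$cum_variance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Eigenfaces", y = "Cumulative explained variance") +
    ggplot2::theme_minimal()
}
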