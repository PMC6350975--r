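# Shared fixtures and independent oracles, built in code at test time.

# Independent point-in-polygon test (even-odd ray casting + on-boundary
# check), deliberately separate from the rasterizer used by the package.
point_in_poly_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    # on-segment check
    cross <- (px - xs[j]) * (ys[i] - ys[j]) - (py - ys[j]) * (xs[i] - xs[j])
    if (cross == 0 &&
        px >= min(xs[i], xs[j]) && px <= max(xs[i], xs[j]) &&
        py >= min(ys[i], ys[j]) && py <= max(ys[i], ys[j])) {
      return(TRUE)
    }
  }
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    if ((ys[i] > py) != (ys[j] > py)) {
      xint <- xs[j] + (py - ys[j]) * (xs[i] - xs[j]) / (ys[i] - ys[j])
      if (px < xint) inside <- !inside
    }
  }
  inside
}

# Brute-force Dunn's Index: explicit double loops, no dist().
dunn_oracle <- function(x, labels) {
  n <- nrow(x)
  inter <- Inf; intra <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((x[i, ] - x[j, ])^2))
    if (labels[i] == labels[j]) intra <- max(intra, d) else inter <- min(inter, d)
  }
  inter / intra
}

# Random small feature tables for eigen tests.
random_features <- function(n, shape = c(8, 8), seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    feature_id = sprintf("f%03d", seq_len(n)),
    kind = "nose",
    pixels = lapply(seq_len(n), function(i) matrix(runif(prod(shape)), shape[1], shape[2]))
  ))
}

# Rank-limited feature set: mean + random combination of `rank` fixed
# direction images (+ optional noise).
rank_limited_features <- function(n, rank, shape = c(8, 8), noise = 0,
                                  coef_sd = 0.02, seed = 1) {
  withr::with_seed(seed, {
    base <- matrix(runif(prod(shape), 0.4, 0.6), shape[1], shape[2])
    dirs <- lapply(seq_len(rank), function(i) matrix(rnorm(prod(shape)), shape[1], shape[2]))
    tibble::tibble(
      feature_id = sprintf("f%03d", seq_len(n)),
      kind = "nose",
      pixels = lapply(seq_len(n), function(i) {
        img <- base
        for (d in dirs) img <- img + rnorm(1, 0, coef_sd) * d
        img + matrix(rnorm(prod(shape), 0, noise), shape[1], shape[2])
      })
    )
  })
}

planted_coeffs <- function(g = 6, members = 12, noise_sd = 0.02, m = 15, seed = 1) {
  pop <- generate_planted_features(make_prototypes(g), members, noise_sd, seed = seed)
  model <- fit_eigenmodel(pop, m = m)
  list(pop = pop, model = model, coeffs = encode_features(pop, model))
}

# A small taxonomy over planted clusters, for survey tests.
planted_taxonomy <- function(g = 6, members = 12, noise_sd = 0.02, seed = 1) {
  pc <- planted_coeffs(g, members, noise_sd, seed = seed)
  sol <- run_kmeans(pc$coeffs, g, seed = seed + 1)
  tax <- build_taxonomy(sol, pc$coeffs, "W", "N")
  list(taxonomy = tax, coeffs = pc$coeffs, pop = pc$pop, solution = sol)
}
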