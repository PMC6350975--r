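# K-means clustering of eigenface coefficients and Dunn's-Index-guided
# selection of the number of clusters, subject to the single-element-cluster
# (SEC) rule.
#
# K-means is Lloyd's algorithm from k-means++ seeding, run to convergence
# (no assignment changes) or 300 iterations; clusters emptied during the
# iterations are re-seeded with the point currently farthest from its
# centroid.

sq_dists <- function(x, centers) {
  # n x k matrix of squared Euclidean distances
  outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  if (k > 1) {
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      i <- sample.int(n, 1, prob = p)
      centers[j, ] <- x[i, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
    }
  }
  centers
}

#' K-means clustering (Lloyd's algorithm, k-means++ seeding)
#'
#' @param x Coefficient matrix or tibble (rows = features; see
#'   [encode_features()]).
#' @param k Number of clusters, `1 <= k <= nrow(x)`.
#' @param seed Integer seed controlling initialization; identical inputs and
#'   seeds give identical results. `NULL` uses the current RNG state.
#' @param max_iter Iteration cap (default 300).
#' @return A `facetax_kmeans`: `k`, `assignments` (integer labels in 1..k,
#'   named by feature id when available), `centroids` (k x d), `inertia`
#'   (within-cluster sum of squares), `iterations`, `converged`.
#' @export
run_kmeans <- function(x, k, seed = NULL, max_iter = 300) {
  m <- as_coef_matrix(x)
  n <- nrow(m)
  if (k > n) ftx_abort("k cannot exceed the number of points", "parameter_error")
  if (k < 1) ftx_abort("k must be >= 1", "parameter_error")
  fit <- function() {
    centers <- kmeanspp_init(m, k)
    labels <- rep(0L, n)
    iter <- 0L; converged <- FALSE
    while (iter < max_iter) {
      iter <- iter + 1L
      d2 <- sq_dists(m, centers)
      new_labels <- max.col(-d2, ties.method = "first")
      # re-seed empty clusters with the globally farthest point
      repairs <- 0L
      repeat {
        sizes <- tabulate(new_labels, k)
        empty <- which(sizes == 0)
        if (length(empty) == 0) break
        repairs <- repairs + 1L
        if (repairs > 10L * k) {
          ftx_abort("k exceeds the number of distinct points", "parameter_error")
        }
        cur <- d2[cbind(seq_len(n), new_labels)]
        far <- which.max(cur)
        centers[empty[1], ] <- m[far, ]
        d2 <- sq_dists(m, centers)
        new_labels <- max.col(-d2, ties.method = "first")
      }
      if (identical(new_labels, labels)) { converged <- TRUE; break }
      labels <- new_labels
      for (j in seq_len(k)) {
        centers[j, ] <- colMeans(m[labels == j, , drop = FALSE])
      }
    }
    d2 <- sq_dists(m, centers)
    inertia <- sum(d2[cbind(seq_len(n), labels)])
    names(labels) <- rownames(m)
    structure(list(k = k, assignments = labels, centroids = centers,
                   inertia = inertia, iterations = iter, converged = converged),
              class = "facetax_kmeans")
  }
  if (is.null(seed)) fit() else withr::with_seed(seed, fit())
}

#' @export
print.facetax_kmeans <- function(x, ...) {
  cat(sprintf("<facetax_kmeans> k = %d, n = %d, inertia = %.4g (%d iterations)\n",
              x$k, length(x$assignments), x$inertia, x$iterations))
  invisible(x)
}

dunn_from_dist <- function(D, labels) {
  labs <- unique(labels)
  if (length(labs) < 2) ftx_abort("Dunn's Index needs >= 2 clusters", "parameter_error")
  same <- outer(labels, labels, "==")
  ut <- upper.tri(D)
  intra <- max(D[same & ut], 0)
  inter <- min(D[!same & ut])
  if (intra == 0) {
    rlang::warn("all within-cluster distances are zero; Dunn's Index is +Inf")
    return(Inf)
  }
  inter / intra
}

#' Dunn's Index of a clustering
#'
#' The ratio of the smallest between-cluster distance (single linkage: the
#' minimum distance between points of different clusters) to the largest
#' within-cluster diameter (complete diameter), in Euclidean metric. Higher
#' values indicate compact, well-separated clusters.
#'
#' @param x Coefficient matrix or tibble.
#' @param assignments Integer cluster labels, one per row of `x`.
#' @return A positive real; `+Inf` (with a warning) when every cluster has
#'   zero diameter.
#' @export
dunn_index <- function(x, assignments) {
  m <- as_coef_matrix(x)
  stopifnot(length(assignments) == nrow(m))
  dunn_from_dist(as.matrix(dist(m)), as.integer(assignments))
}

#' Flag single-element clusters (SECs)
#'
#' For mouths and noses a SEC is a cluster with a single member. For eyes,
#' any cluster with at most two members is a SEC — one individual eye, the
#' two eyes of the same person, or two eyes of different people.
#'
#' @param solution A `facetax_kmeans` (or an integer assignment vector).
#' @param kind `"mouth"`, `"nose"` or `"eye"`.
#' @param pairing For eyes: a named character vector mapping feature_id to
#'   face_id (or a data frame with those columns). Required so eye-pair SECs
#'   are auditable.
#' @return Integer labels of the flagged clusters.
#' @export
count_secs <- function(solution, kind, pairing = NULL) {
  labels <- if (inherits(solution, "facetax_kmeans")) solution$assignments else solution
  sizes <- table(labels)
  if (kind == "eye") {
    if (is.null(pairing)) {
      ftx_abort("eye SEC counting requires the feature-to-face pairing", "parameter_error")
    }
    flagged <- names(sizes)[sizes <= 2]
  } else {
    flagged <- names(sizes)[sizes == 1]
  }
  as.integer(flagged)
}

#' Sweep the number of clusters K
#'
#' Runs K-means `runs_per_k` times for every K in `k_min..k_max` and scores
#' each solution with Dunn's Index. K is swept from 5 to 30 with 10 runs per
#' K by default; the per-K best run is the one with the highest Dunn's
#' Index, and the spread of the index across runs measures the coherence of
#' the results.
#'
#' @param x Coefficient matrix or tibble.
#' @param k_min,k_max K range (defaults 5 and 30).
#' @param runs_per_k Independent K-means runs per K (default 10).
#' @param seed Master seed; per-run seeds are derived from it.
#' @return A `facetax_sweep` tibble: `k`, `run`, `dunn`, `inertia`,
#'   `converged`, `solution` (list of `facetax_kmeans`).
#' @export
sweep_k <- function(x, k_min = 5, k_max = 30, runs_per_k = 10, seed = NULL) {
  if (k_min > k_max) ftx_abort("k_min must be <= k_max", "parameter_error")
  m <- as_coef_matrix(x)
  if (k_max > nrow(m)) ftx_abort("k_max cannot exceed the number of points", "parameter_error")
  ks <- rep(k_min:k_max, each = runs_per_k)
  runs <- rep(seq_len(runs_per_k), times = k_max - k_min + 1)
  seeds <- withr::with_seed(seed %||% sample.int(1e6, 1),
                            sample.int(.Machine$integer.max - 1L, length(ks)))
  D <- as.matrix(dist(m))
  sols <- vector("list", length(ks))
  dunns <- numeric(length(ks))
  for (i in seq_along(ks)) {
    sols[[i]] <- run_kmeans(m, ks[i], seed = seeds[i])
    dunns[i] <- withCallingHandlers(
      dunn_from_dist(D, sols[[i]]$assignments),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  out <- tibble(k = ks, run = runs, dunn = dunns,
                inertia = map_dbl(sols, "inertia"),
                converged = map_lgl(sols, "converged"),
                solution = sols)
  class(out) <- c("facetax_sweep", class(out))
  out
}

#' Per-K summary of a sweep (best run, coherence, SECs)
#'
#' @param sweep A `facetax_sweep`.
#' @param kind,pairing Passed to [count_secs()]; when `kind` is NULL the SEC
#'   columns are omitted.
#' @return A tibble with one row per K: `k`, `dunn` (best run), `dunn_sd`
#'   (across runs), `n_sec`, `sec_per_k` and the best `solution`.
#' @export
summarize_sweep <- function(sweep, kind = NULL, pairing = NULL) {
  best <- sweep |>
    group_by(.data$k) |>
    mutate(dunn_sd = sd(.data$dunn)) |>
    arrange(desc(.data$dunn), .data$run, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$k)
  if (!is.null(kind)) {
    best$n_sec <- map_int(best$solution,
                          ~ length(count_secs(.x, kind, pairing)))
    best$sec_per_k <- best$n_sec / best$k
  }
  select(best, -"run", -"converged")
}

#' Select K by Dunn's Index under the SEC constraint
#'
#' Among the per-K best runs whose SEC count is at most `max_secs`, returns
#' the solution with the highest Dunn's Index; ties break toward smaller K
#' (parsimony).
#'
#' @param sweep A `facetax_sweep`.
#' @param kind,pairing See [count_secs()].
#' @param max_secs Largest admissible number of SECs (default 2).
#' @return The chosen `facetax_kmeans`, augmented with `dunn` and
#'   `sec_clusters`.
#' @export
select_k <- function(sweep, kind, pairing = NULL, max_secs = 2) {
  if (nrow(sweep) == 0) ftx_abort("empty sweep", "parameter_error")
  best <- summarize_sweep(sweep, kind, pairing)
  ok <- filter(best, .data$n_sec <= max_secs)
  if (nrow(ok) == 0) {
    ftx_abort(paste0("no K in ", min(best$k), "..", max(best$k),
                     " satisfies the SEC constraint (<= ", max_secs, ")"),
              "selection_error",
              diagnostics = select(best, "k", "dunn", "n_sec"))
  }
  pick <- ok |> arrange(desc(.data$dunn), .data$k) |> slice(1)
  sol <- pick$solution[[1]]
  sol$dunn <- pick$dunn
  sol$sec_clusters <- count_secs(sol, kind, pairing)
  sol
}

#' Dunn's Index and SEC ratio across K (plot)
#'
#' The classic K-selection diagnostic: the best Dunn's Index per K together
#' with the ratio of single-element clusters to K.
#'
#' @param object A `facetax_sweep`.
#' @param kind,pairing See [count_secs()].
#' @param ... Unused.
#' @return A ggplot faceted into the two diagnostics.
#' @method autoplot facetax_sweep
#' @export
autoplot.facetax_sweep <- function(object, kind = NULL, pairing = NULL, ...) {
  best <- summarize_sweep(object, kind, pairing)
  long <- if (is.null(kind)) {
    tidyr::pivot_longer(select(best, "k", "dunn"), -"k")
  } else {
    tidyr::pivot_longer(select(best, "k", "dunn", "sec_per_k"), -"k")
  }
  long$name <- factor(long$name, c("dunn", "sec_per_k"),
                      c("Best Dunn's Index", "SEC / K"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::facet_wrap(~name, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Number of clusters K", y = NULL) +
    ggplot2::theme_minimal()
}
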