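# Simulated multi-stage forced-choice survey and agreement analysis.
#
# The protocol mirrors a tournament: a target feature sits at the center of
# a form with four representative features at the corners; the evaluator
# picks the most similar representative; the pick carries over to the next
# stage together with three not-yet-shown representatives, until every
# representative has been shown at least once. The cluster of the final
# pick is the survey's answer for that target. Human participants are
# replaced by evaluator models operating on eigenface coefficients.

#' Evaluator models for the simulated survey
#'
#' `evaluator_nearest()` always picks the option closest (Euclidean, in
#' coefficient space) to the target, ties to the first shown.
#' `evaluator_softmax()` picks option i with probability proportional to
#' `exp(-d_i / temperature)`: small temperatures approach the nearest
#' evaluator, `temperature = Inf` is a uniformly random pick.
#'
#' @param temperature Positive scale of the choice noise (distance units).
#' @return A `facetax_evaluator` with a `choose(target, options)` function
#'   returning the index of the chosen option row.
#' @export
evaluator_nearest <- function() {
  structure(list(
    name = "nearest",
    choose = function(target, options) {
      which.min(sqrt(rowSums((options - matrix(target, nrow(options),
                                               length(target), byrow = TRUE))^2)))
    }
  ), class = "facetax_evaluator")
}

#' @rdname evaluator_nearest
#' @export
evaluator_softmax <- function(temperature) {
  if (!is.numeric(temperature) || temperature <= 0) {
    ftx_abort("temperature must be positive", "parameter_error")
  }
  structure(list(
    name = "softmax", temperature = temperature,
    choose = function(target, options) {
      d <- sqrt(rowSums((options - matrix(target, nrow(options),
                                          length(target), byrow = TRUE))^2))
      if (is.infinite(temperature)) {
        p <- rep(1 / length(d), length(d))
      } else {
        w <- exp(-(d - min(d)) / temperature)
        p <- w / sum(w)
      }
      sample.int(length(d), 1, prob = p)
    }
  ), class = "facetax_evaluator")
}

#' Distance ranking of clusters from each cluster
#'
#' Distances between clusters are measured between the eigenface
#' coefficients of their representative features. For each cluster, every
#' other cluster is ranked: the 1st closest is the nearest cluster, and so
#' on; ties break by cluster rank.
#'
#' @param taxonomy A `facetax_taxonomy` whose clusters carry representative
#'   coefficients.
#' @return A tibble: `code`, `closest_rank` (1..R-1), `other_code`,
#'   `distance`.
#' @export
cluster_distance_ranks <- function(taxonomy) {
  cl <- taxonomy$clusters
  if (nrow(cl) < 2) ftx_abort("need >= 2 clusters to rank distances", "parameter_error")
  if (any(map_int(cl$representative_coef, length) == 0)) {
    ftx_abort("clusters are missing representative coefficients", "parameter_error")
  }
  reps <- do.call(rbind, cl$representative_coef)
  D <- as.matrix(dist(reps))
  out <- lapply(seq_len(nrow(cl)), function(i) {
    others <- setdiff(seq_len(nrow(cl)), i)
    ord <- others[order(D[i, others], cl$rank[others])]
    tibble(code = cl$code[i], closest_rank = seq_along(ord),
           other_code = cl$code[ord], distance = D[i, ord])
  })
  bind_rows(out)
}

#' Run one forced-choice survey trial
#'
#' Stage 1 shows four representatives sampled uniformly without replacement;
#' each later stage keeps the previous pick and adds three not-yet-shown
#' representatives (when fewer than three remain, already-seen non-selected
#' representatives fill the free corners). The trial ends once every
#' representative has been shown.
#'
#' @param target Coefficient vector of the target feature.
#' @param representatives Tibble with `code` and `coef` (list of numeric
#'   vectors), one row per cluster representative (>= 4 rows).
#' @param evaluator A `facetax_evaluator`.
#' @return A `facetax_trial`: list with `stages` (each a list of `shown`
#'   codes and `selected` code), `final_code`, `shown_all`.
#' @export
run_trial <- function(target, representatives, evaluator) {
  R <- nrow(representatives)
  if (R < 4) ftx_abort("the survey needs at least 4 representatives", "parameter_error")
  codes <- representatives$code
  coefs <- do.call(rbind, representatives$coef)
  seen <- character(0)
  carried <- NULL
  stages <- list()
  repeat {
    if (is.null(carried)) {
      shown <- sample(codes, 4)
    } else {
      unseen <- setdiff(codes, seen)
      new <- if (length(unseen) >= 3) sample(unseen, 3) else unseen
      n_fill <- 3 - length(new)
      if (n_fill > 0) {
        pool <- setdiff(seen, c(carried, new))
        new <- c(new, sample(pool, n_fill))
      }
      shown <- c(carried, new)
    }
    seen <- union(seen, shown)
    pick <- evaluator$choose(target, coefs[match(shown, codes), , drop = FALSE])
    carried <- shown[pick]
    stages[[length(stages) + 1]] <- list(shown = shown, selected = carried)
    if (all(codes %in% seen)) break
  }
  structure(list(stages = stages, final_code = carried, shown_all = seen),
            class = "facetax_trial")
}

n_trial_stages <- function(R) 1L + as.integer(ceiling(max(0, R - 4) / 3))

new_agreement <- function(counts, n_trials, kind = NA_character_) {
  labels <- c("Expected", paste0(seq_len(length(counts) - 1),
                                 c("st", "nd", "rd", rep("th", max(0, length(counts) - 4)))[
                                   seq_len(length(counts) - 1)], " closest"))
  out <- tibble(outcome = factor(labels, levels = labels),
                count = as.integer(counts),
                percent = 100 * counts / n_trials,
                cum_percent = 100 * cumsum(counts) / n_trials)
  attr(out, "n_trials") <- n_trials
  attr(out, "kind") <- kind
  class(out) <- c("facetax_agreement", class(out))
  out
}

#' Agreement table arithmetic from raw counts
#'
#' Builds the survey agreement table (percentages and cumulative
#' percentages) from the counts of trials whose final cluster was the
#' expected cluster, the 1st-closest cluster to it, the 2nd closest, and so
#' on.
#'
#' @param counts Integer vector: expected first, then 1st closest, 2nd
#'   closest, ... Missing trailing ranks may be omitted.
#' @param n_trials Total trials (default `sum(counts)`).
#' @param kind Optional feature kind annotation.
#' @return A `facetax_agreement` tibble: `outcome`, `count`, `percent`,
#'   `cum_percent`.
#' @export
agreement_table <- function(counts, n_trials = sum(counts), kind = NA_character_) {
  counts <- as.integer(counts)
  if (any(counts < 0) || sum(counts) != n_trials) {
    ftx_abort("counts must be nonnegative and sum to n_trials", "parameter_error")
  }
  new_agreement(counts, n_trials, kind)
}

#' Cumulative agreement through a distance rank
#'
#' The percentage of trials whose final cluster was the expected cluster or
#' one of the `through_rank` clusters closest to it.
#'
#' @param table A `facetax_agreement`.
#' @param through_rank Closest-cluster rank to accumulate through (default
#'   3).
#' @return A percentage in \[0, 100\].
#' @export
agreement_summary <- function(table, through_rank = 3) {
  if (through_rank < 0 || through_rank > nrow(table) - 1) {
    ftx_abort("through_rank out of range", "parameter_error")
  }
  table$cum_percent[through_rank + 1]
}

#' Simulate the validation survey against a taxonomy
#'
#' Samples `n_targets` features at random from the encoded dataset
#' (excluding the representative features and any members removed during
#' SEC review), runs one forced-choice trial per target, and tabulates how
#' far — in cluster-distance rank — each trial's final cluster is from the
#' target's expected cluster.
#'
#' @param taxonomy A `facetax_taxonomy`.
#' @param coeffs Coefficient tibble/matrix of the full dataset the taxonomy
#'   was built on.
#' @param n_targets Number of targets (default 200).
#' @param evaluator A `facetax_evaluator` (default [evaluator_nearest()]).
#' @param seed Integer seed.
#' @return A `facetax_agreement` with attribute `trials` (list of
#'   `facetax_trial`).
#' @export
simulate_survey <- function(taxonomy, coeffs, n_targets = 200,
                            evaluator = evaluator_nearest(), seed = NULL) {
  m <- as_coef_matrix(coeffs)
  ids <- rownames(m) %||% sprintf("feature%04d", seq_len(nrow(m)))
  cl <- taxonomy$clusters
  membership <- setNames(rep(cl$code, map_int(cl$member_ids, length)),
                         unlist(cl$member_ids))
  eligible <- setdiff(intersect(ids, names(membership)), cl$representative_id)
  if (length(eligible) < n_targets) {
    ftx_abort(sprintf("only %d non-representative features available for %d targets",
                      length(eligible), n_targets), "parameter_error")
  }
  reps <- tibble(code = cl$code, coef = cl$representative_coef)
  ranks <- cluster_distance_ranks(taxonomy)
  R <- nrow(cl)
  run <- function() {
    targets <- sample(eligible, n_targets)
    trials <- vector("list", n_targets)
    outcome_rank <- integer(n_targets)
    for (i in seq_len(n_targets)) {
      tid <- targets[i]
      trial <- run_trial(m[match(tid, ids), ], reps, evaluator)
      trials[[i]] <- trial
      expected <- membership[[tid]]
      outcome_rank[i] <- if (trial$final_code == expected) 0L else {
        rr <- ranks[ranks$code == expected & ranks$other_code == trial$final_code, ]
        rr$closest_rank[1]
      }
    }
    counts <- tabulate(outcome_rank + 1L, R)
    out <- new_agreement(counts, n_targets, taxonomy$kind_code)
    attr(out, "trials") <- trials
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Selection probability by stage of first appearance
#'
#' The tournament design makes a representative's chance of being the final
#' pick depend on the stage in which it first appears. This Monte-Carlo
#' estimate stratifies the final-selection probability by first-appearance
#' stage.
#'
#' @param taxonomy A `facetax_taxonomy`.
#' @param coeffs Coefficients to draw targets from; NULL uses the
#'   representatives themselves as targets (adequate for distance-free
#'   evaluators).
#' @param evaluator A `facetax_evaluator`.
#' @param n_reps Number of simulated trials (default 1000).
#' @param seed Integer seed.
#' @return A tibble: `stage`, `n_first_shown`, `n_selected`, `p_selected`,
#'   `se`.
#' @export
stage_position_bias <- function(taxonomy, coeffs = NULL,
                                evaluator = evaluator_softmax(Inf),
                                n_reps = 1000, seed = NULL) {
  cl <- taxonomy$clusters
  reps <- tibble(code = cl$code, coef = cl$representative_coef)
  targets <- if (is.null(coeffs)) do.call(rbind, cl$representative_coef) else
    as_coef_matrix(coeffs)
  run <- function() {
    shown_n <- integer(0); sel_n <- integer(0)
    for (r in seq_len(n_reps)) {
      tg <- targets[sample.int(nrow(targets), 1), ]
      trial <- run_trial(tg, reps, evaluator)
      first_stage <- setNames(rep(NA_integer_, nrow(reps)), reps$code)
      for (s in seq_along(trial$stages)) {
        for (code in trial$stages[[s]]$shown) {
          if (is.na(first_stage[code])) first_stage[code] <- s
        }
      }
      n_stages <- length(trial$stages)
      if (length(shown_n) < n_stages) {
        shown_n <- c(shown_n, rep(0L, n_stages - length(shown_n)))
        sel_n <- c(sel_n, rep(0L, n_stages - length(sel_n)))
      }
      for (s in seq_len(n_stages)) {
        shown_n[s] <- shown_n[s] + sum(first_stage == s)
        sel_n[s] <- sel_n[s] + as.integer(first_stage[trial$final_code] == s)
      }
    }
    p <- ifelse(shown_n > 0, sel_n / shown_n, NA_real_)
    tibble(stage = seq_along(shown_n), n_first_shown = shown_n,
           n_selected = sel_n, p_selected = p,
           se = sqrt(p * (1 - p) / pmax(shown_n, 1)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Agreement table plot
#'
#' @param object A `facetax_agreement`.
#' @param ... Unused.
#' @return A ggplot: per-rank percentage bars with the cumulative percentage
#'   overlaid.
#' @method autoplot facetax_agreement
#' @export
autoplot.facetax_agreement <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$percent)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cum_percent, group = 1)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cum_percent)) +
    ggplot2::labs(x = NULL, y = "% of trials") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
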