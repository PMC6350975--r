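test_that("cluster distance ranks match a brute-force all-pairs sort", {
  pt <- planted_taxonomy(g = 5, members = 8, seed = 11)
  ranks <- cluster_distance_ranks(pt$taxonomy)
  cl <- pt$taxonomy$clusters
  reps <- do.call(rbind, cl$representative_coef)
  for (i in seq_len(nrow(cl))) {
    # oracle: explicit pairwise distances, sorted
    d <- vapply(seq_len(nrow(cl)), function(j) sqrt(sum((reps[i, ] - reps[j, ])^2)),
                numeric(1))
    ord <- setdiff(order(d), i)
    mine <- ranks[ranks$code == cl$code[i], ]
    expect_equal(mine$other_code, cl$code[ord])
    # rank lists are a permutation of all other codes
    expect_setequal(mine$other_code, setdiff(cl$code, cl$code[i]))
    expect_equal(mine$closest_rank, seq_len(nrow(cl) - 1))
  }

  # 2 clusters: each is the other's 1st closest
  two <- pt$taxonomy
  two$clusters <- two$clusters[1:2, ]
  r2 <- cluster_distance_ranks(two)
  expect_equal(nrow(r2), 2)
  expect_equal(r2$closest_rank, c(1L, 1L))
})

test_that("trial schedules cover every representative in the minimum stages", {
  mk_reps <- function(R) tibble::tibble(
    code = sprintf("WN%02d", seq_len(R)),
    coef = lapply(seq_len(R), function(i) c(i, 0)))

  # R = 4: a single stage shows everything
  withr::with_seed(5, {
    t4 <- run_trial(c(0, 0), mk_reps(4), evaluator_nearest())
    expect_length(t4$stages, 1)
    expect_setequal(t4$shown_all, mk_reps(4)$code)
  })

  # R = 9: exactly 3 stages (4 + 3 + 3 >= 9 distinct)
  withr::with_seed(6, {
    t9 <- run_trial(c(0, 0), mk_reps(9), evaluator_nearest())
    expect_length(t9$stages, 3)
    expect_setequal(t9$shown_all, mk_reps(9)$code)
    # the carried pick keeps its corner in every later stage
    for (s in 2:3) {
      expect_equal(t9$stages[[s]]$shown[1], t9$stages[[s - 1]]$selected)
    }
    # every stage shows exactly 4 corners
    expect_true(all(lengths(lapply(t9$stages, `[[`, "shown")) == 4))
  })

  # a zero-distance representative wins every stage it appears in
  withr::with_seed(7, {
    reps <- mk_reps(9)
    target <- reps$coef[[5]]
    tr <- run_trial(target, reps, evaluator_nearest())
    expect_equal(tr$final_code, "WN05")
  })
  expect_error(run_trial(c(0, 0), mk_reps(3), evaluator_nearest()),
               class = "facetax_parameter_error")
})

test_that("agreement arithmetic: counts to percentages and cumulatives", {
  tab <- agreement_table(c(82, 24, 23, 22, 17, 14, 6, 6, 6))
  expect_equal(attr(tab, "n_trials"), 200)
  expect_equal(tab$percent[1], 41.0)
  expect_equal(agreement_summary(tab, 3), 75.5)
  expect_equal(agreement_summary(tab, nrow(tab) - 1), 100)
  expect_true(all(diff(tab$cum_percent) >= 0))

  tab_n <- agreement_table(c(93, 36, 21, 12, 8, 14, 3, 5, 6, 1, 0, 1))
  expect_equal(tab_n$percent[1], 46.5)
  expect_equal(agreement_summary(tab_n, 3), 81.0)

  expect_error(agreement_summary(tab, 20), class = "facetax_parameter_error")
  expect_error(agreement_table(c(10, -1), 9), class = "facetax_parameter_error")
})

test_that("simulated surveys conserve counts and respect the evaluator", {
  pt <- planted_taxonomy(g = 6, members = 12, noise_sd = 0.02, seed = 13)
  ag <- simulate_survey(pt$taxonomy, pt$coeffs, n_targets = 40, seed = 21)
  expect_equal(sum(ag$count), 40)
  expect_equal(ag$cum_percent[nrow(ag)], 100)
  # protocol invariant: every trial showed every representative
  trials <- attr(ag, "trials")
  for (tr in trials) {
    expect_setequal(tr$shown_all, pt$taxonomy$clusters$code)
  }
  # a perfect evaluator on well-separated planted clusters agrees
  expect_gte(ag$percent[1], 95)

  # identical seeds give identical tables
  ag2 <- simulate_survey(pt$taxonomy, pt$coeffs, n_targets = 40, seed = 21)
  expect_equal(ag$count, ag2$count)

  # asking for more targets than non-representative features fails
  expect_error(simulate_survey(pt$taxonomy, pt$coeffs, n_targets = 1000),
               class = "facetax_parameter_error")
  p <- autoplot(ag)
  expect_s3_class(p, "ggplot")
})

test_that("agreement degrades as evaluator noise grows", {
  pt <- planted_taxonomy(g = 6, members = 12, noise_sd = 0.02, seed = 17)
  temps <- c(0.5, 5, 50)
  exp_pct <- vapply(temps, function(tm) {
    ag <- simulate_survey(pt$taxonomy, pt$coeffs, n_targets = 60,
                          evaluator = evaluator_softmax(tm), seed = 31)
    ag$percent[1]
  }, numeric(1))
  expect_true(all(diff(exp_pct) <= 0))
  expect_error(evaluator_softmax(-1), class = "facetax_parameter_error")
})

test_that("stage-position bias is flat for R = 4 and present for R = 9", {
  # R = 4: every representative first appears at stage 1; selection is 1/4
  pt4 <- planted_taxonomy(g = 4, members = 8, seed = 23)
  sb4 <- stage_position_bias(pt4$taxonomy, evaluator = evaluator_softmax(Inf),
                             n_reps = 400, seed = 3)
  expect_equal(nrow(sb4), 1)
  expect_equal(sb4$p_selected, 0.25, tolerance = 0.1)

  # R = 9 under a uniform evaluator: later first-appearance stages carry
  # different selection probability (the tournament bias)
  pt9 <- planted_taxonomy(g = 9, members = 8, seed = 29)
  sb9 <- stage_position_bias(pt9$taxonomy, evaluator = evaluator_softmax(Inf),
                             n_reps = 1500, seed = 4)
  expect_equal(nrow(sb9), 3)
  expect_gt(max(sb9$p_selected) - min(sb9$p_selected), 0.05)
})
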