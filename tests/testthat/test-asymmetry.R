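test_that("hemisphere split gives 45 + 45 columns that partition the table", {
  cohort <- generate_cohort(cohort_config(groups = c(HC = 8), seed = 27))
  tab <- cohort$tables$HC
  halves <- split_hemispheres(tab)
  expect_length(roi_columns(halves$left), 45)
  expect_length(roi_columns(halves$right), 45)
  expect_setequal(c(roi_columns(halves$left), roi_columns(halves$right)),
                  roi_columns(tab))
  # missing side label is named
  atlas <- aal90_atlas()
  expect_error(split_hemispheres(tab, atlas[-2, ]), atlas$abbrev[2])
})

test_that("a mirrored right hemisphere yields identical efficiencies and AI 0", {
  cohort <- generate_cohort(cohort_config(groups = c(HC = 15), seed = 28))
  halves <- split_hemispheres(cohort$tables$HC)
  mirrored <- halves$left
  names(mirrored) <- names(halves$right)
  eff <- hemispheric_efficiencies(halves$left, mirrored)
  expect_equal(eff$M_L, eff$M_R, tolerance = 1e-12)
  expect_equal(asymmetry_index(eff$M_R, eff$M_L), c(0, 0))
})

test_that("the AI formula has its exact algebraic properties", {
  expect_equal(asymmetry_index(0.5, 0.5), 0)
  # the control-group global efficiencies quoted at four decimals
  expect_equal(asymmetry_index(0.6253, 0.6247), 0.096, tolerance = 1e-3)
  set.seed(29)
  a <- runif(50, 0.1, 1)
  b <- runif(50, 0.1, 1)
  expect_equal(asymmetry_index(2 * a, 2 * b), asymmetry_index(a, b),
               tolerance = 1e-12)
  expect_true(all(asymmetry_index(a, b) >= 0))
  expect_equal(asymmetry_index(a, b) == 0, a == b)
  expect_error(asymmetry_index(0, 0), "positive")
  expect_error(asymmetry_index(-1, 2), "non-negative")
})

test_that("within-group test is deterministic under a seed and carries draws", {
  cohort <- generate_cohort(cohort_config(groups = c(HC = 12), seed = 30))
  tab <- cohort$tables$HC
  a <- within_group_test(tab, n_rep = 100, seed = 77)
  b <- within_group_test(tab, n_rep = 100, seed = 77)
  expect_identical(a$summary, b$summary)
  expect_identical(a$draws, b$draws)
  expect_equal(nrow(a$draws), 200) # 100 reps x 2 metrics
  expect_true(all(a$summary$p >= 1 / 101 & a$summary$p <= 1))
  expect_true(all(a$draws$AI >= 0))
  g <- glance(a)
  expect_equal(g$n_rep, 100)
  expect_named(tidy(a),
               c("group", "sparsity", "metric", "M_L", "M_R", "AI", "p",
                 "direction"))
})

test_that("planted leftward coupling gain is detected as rightward asymmetry", {
  st2 <- plant_asymmetry(light_structure(), 2, "L")
  cohort <- generate_cohort(cohort_config(groups = c(G = 200), structure = st2,
                                          hemisphere_gain = c(G = 1),
                                          seed = 314))
  res <- within_group_test(cohort$tables$G, n_rep = 200, seed = 315,
                           n_boot = 0)
  expect_equal(res$summary$direction[res$summary$metric == "global"],
               "rightward")
})

test_that("AI comparison between groups is a Welch t-test with its symmetries", {
  cohort <- generate_cohort(cohort_config(groups = c(HC = 12, DLB = 12),
                                          seed = 32))
  r1 <- within_group_test(cohort$tables$HC, n_rep = 100, seed = 1)
  r2 <- within_group_test(cohort$tables$DLB, n_rep = 100, seed = 2)
  cmp <- compare_ai_between_groups(r1, r2)
  expect_equal(cmp$metric, c("global", "local"))
  self <- compare_ai_between_groups(r1, r1)
  expect_equal(self$t, c(0, 0))
  expect_equal(self$p, c(1, 1))
  rev <- compare_ai_between_groups(r2, r1)
  expect_equal(rev$t, -cmp$t, tolerance = 1e-12)
  expect_equal(rev$p, cmp$p, tolerance = 1e-12)
  # oracle: direct Welch t-test on the draw vectors
  a <- r1$draws$AI[r1$draws$metric == "global"]
  b <- r2$draws$AI[r2$draws$metric == "global"]
  tt <- t.test(a, b)
  expect_equal(cmp$t[1], unname(tt$statistic))
  expect_equal(cmp$p[1], tt$p.value)
})
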