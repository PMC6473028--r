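test_that("partial correlation with no covariates is plain Pearson", {
  cohort <- generate_cohort(tiny_cohort(n = 15, seed = 6))
  tab <- cohort$tables$G
  pc <- partial_correlation(tab, covariates = character(0))
  expect_equal(unclass(pc), unname(cor(as.matrix(tab[, roi_columns(tab)]))),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("duplicated ROI gives a unit entry and symmetry is exact", {
  cohort <- generate_cohort(tiny_cohort(n = 15, seed = 7))
  tab <- cohort$tables$G
  tab$ROI01.R <- tab$ROI01.L
  pc <- partial_correlation(tab, covariates = "age")
  m <- unclass(pc)
  expect_equal(m["ROI01.L", "ROI01.R"], 1, tolerance = 1e-12)
  expect_identical(m, t(m))
  expect_true(all(abs(m[upper.tri(m)]) <= 1 + 1e-12))
  expect_equal(unname(diag(m)), rep(1, ncol(m)))
})

test_that("partial correlation matches the explicit residualization oracle", {
  # 6 subjects, 3 ROIs, fixed values, age covariate
  tab <- tibble::tibble(
    subject_id = paste0("s", 1:6), group = "G",
    age = c(61, 72, 58, 66, 70, 63), sex = c(0, 1, 0, 1, 1, 0),
    A = c(1.2, 2.1, 0.7, 1.9, 2.4, 1.1),
    B = c(0.8, 1.6, 0.9, 1.2, 2.0, 0.7),
    C = c(2.2, 0.9, 2.5, 1.4, 1.0, 2.1)
  )
  pc <- partial_correlation(tab, covariates = "age")
  Z <- matrix(tab$age)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    expect_equal(unclass(pc)[pair[1], pair[2]],
                 oracle_partial_cor(tab[[pair[1]]], tab[[pair[2]]], Z),
                 tolerance = 1e-12)
  }
  # second oracle: normalized sign-flipped inverse covariance of (i, j, age)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    S <- cov(cbind(tab[[pair[1]]], tab[[pair[2]]], tab$age))
    P <- solve(S)
    expect_equal(unclass(pc)[pair[1], pair[2]],
                 -P[1, 2] / sqrt(P[1, 1] * P[2, 2]), tolerance = 1e-10)
  }
})

test_that("rank-deficient covariates and tiny groups are rejected", {
  cohort <- generate_cohort(tiny_cohort(n = 10, seed = 8))
  tab <- cohort$tables$G
  tab$age2 <- tab$age
  expect_error(partial_correlation(tab[, setdiff(names(tab), "age2")][1:4, ]),
               "subjects")
  tab2 <- tab
  expect_error(partial_correlation(tab2, covariates = c("age", "age2")),
               "rank deficient")
})

test_that("binarization keeps exactly round(s * P) top pairs", {
  set.seed(31)
  m <- matrix(rnorm(90 * 90), 90)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  adj <- binarize_at_sparsity(m, 0.28)
  expect_equal(sum(adj) / 2, 1121) # 28% of 4005 pairs
  expect_equal(sum(adj) / 2 / 4005, 0.28, tolerance = 1e-3)
  expect_identical(adj, t(adj))
  expect_equal(unname(diag(adj)), rep(0L, 90))
})

test_that("binarization matches a full-sort oracle and breaks ties lexicographically", {
  set.seed(32)
  for (rep in 1:20) {
    n <- sample(8:12, 1)
    m <- matrix(rnorm(n * n), n)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    s <- runif(1, 0.1, 0.4)
    adj <- binarize_at_sparsity(m, s)
    # oracle: sort all pairs by value, take the top k
    ut <- which(upper.tri(m), arr.ind = TRUE)
    vals <- m[upper.tri(m)]
    k <- round(s * nrow(ut))
    top <- order(-vals)[seq_len(k)]
    oracle <- matrix(0L, n, n)
    oracle[ut[top, , drop = FALSE]] <- 1L
    oracle <- oracle + t(oracle)
    expect_equal(unname(adj), oracle)
  }
  # degenerate ties: all equal entries -> lexicographic pair order, exact count
  m <- matrix(0.5, 6, 6)
  diag(m) <- 1
  adj <- binarize_at_sparsity(m, 0.3) # round(0.3 * 15) = 4 edges
  expect_equal(sum(adj) / 2, 4)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  ord <- order(ut[, 1], ut[, 2])
  expected_pairs <- ut[ord[1:4], , drop = FALSE]
  expect_true(all(adj[expected_pairs] == 1))
})

test_that("sparsity sweeps are nested and consistent with direct binarization", {
  cohort <- generate_cohort(tiny_cohort(n = 20, n_rois = 14, seed = 9))
  pc <- partial_correlation(cohort$tables$G)
  stack <- sparsity_sweep(pc)
  expect_length(stack$adjacency, 35)
  lo <- stack$adjacency[[1]]
  hi <- stack$adjacency[[35]]
  expect_true(all(hi[lo == 1] == 1)) # edges at 6% subset of edges at 40%
  expect_identical(stack$adjacency[[which(stack$sparsities == 0.28)]],
                   binarize_at_sparsity(pc, 0.28))
  expect_error(sparsity_sweep(pc, c(0.2, 0.1)), "increasing")
})
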