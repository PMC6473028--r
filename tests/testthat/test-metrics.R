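complete_graph <- function(n) {
  adj <- matrix(1L, n, n)
  diag(adj) <- 0L
  adj
}

star_graph <- function(n_leaves) {
  adj <- matrix(0L, n_leaves + 1, n_leaves + 1)
  adj[1, -1] <- adj[-1, 1] <- 1L
  adj
}

path_graph <- function(n) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1L
  adj
}

test_that("closed-form graphs give their textbook metric values", {
  k5 <- complete_graph(5)
  expect_equal(clustering_coefficient(k5)$mean, 1)
  expect_equal(characteristic_path_length(k5)$L, 1)
  expect_equal(efficiencies(k5), list(global = 1, local = 1))

  star <- star_graph(5)
  expect_equal(clustering_coefficient(star)$mean, 0)
  expect_equal(efficiencies(star)$local, 0)

  p4 <- path_graph(4)
  expect_equal(characteristic_path_length(p4)$L, 10 / 6)

  # two disjoint triangles: L = 1 over connected pairs, 9 disconnected pairs
  tri2 <- matrix(0L, 6, 6)
  tri2[1:3, 1:3] <- 1L
  tri2[4:6, 4:6] <- 1L
  diag(tri2) <- 0L
  cpl <- characteristic_path_length(tri2)
  expect_equal(cpl$L, 1)
  expect_equal(cpl$n_disconnected_pairs, 9)
})

test_that("star centre is the only hub with bi equal to the node count", {
  star <- star_graph(5)
  bt <- betweenness_table(star)
  # centre carries all shortest paths: BC = choose(5, 2) = 10; leaves 0
  expect_equal(bt$BC, c(10, rep(0, 5)))
  expect_equal(bt$bi[1], 6) # BC / mean(BC) = 10 / (10/6)
  expect_identical(bt$hub, c(TRUE, rep(FALSE, 5)))
})

test_that("cycle graph has uniform bi = 1 and no hubs; complete graph warns", {
  cyc <- matrix(0L, 8, 8)
  for (i in 1:8) {
    j <- i %% 8 + 1
    cyc[i, j] <- cyc[j, i] <- 1L
  }
  bt <- betweenness_table(cyc)
  expect_equal(bt$bi, rep(1, 8))
  expect_false(any(bt$hub))
  expect_warning(bt2 <- betweenness_table(complete_graph(4)), "zero")
  expect_true(all(is.na(bt2$bi)))
})

test_that("metrics match brute-force oracles on random graphs", {
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(5:12, 1)
    adj <- random_adjacency(n, runif(1, 0.2, 0.8))
    cc <- clustering_coefficient(adj)
    expect_equal(unname(cc$node), oracle_clustering(adj), tolerance = 1e-12)
    if (sum(adj) > 0) {
      expect_equal(characteristic_path_length(adj)$L,
                   oracle_path_length(adj)$L, tolerance = 1e-12)
    }
    eff <- efficiencies(adj)
    expect_equal(eff$global, oracle_global_efficiency(adj), tolerance = 1e-12)
    expect_equal(eff$local, oracle_local_efficiency(adj), tolerance = 1e-12)
    bt <- suppressWarnings(betweenness_table(adj))
    expect_equal(bt$BC, oracle_betweenness(adj), tolerance = 1e-9)
  }
})

test_that("rewiring preserves degrees and graphs with no swaps pass through", {
  set.seed(42)
  adj <- random_adjacency(20, 0.3)
  rw <- rewire_degree_preserving(adj, n_swaps = 100)
  expect_gt(rw$accepted, 0)
  expect_equal(colSums(rw$adjacency), colSums(adj))
  expect_identical(rw$adjacency, t(rw$adjacency))
  expect_equal(unname(diag(rw$adjacency)), rep(0L, 20))
  # complete graph admits no swaps
  k5 <- complete_graph(5)
  rw2 <- rewire_degree_preserving(k5, n_swaps = 10)
  expect_equal(rw2$accepted, 0)
  expect_identical(rw2$adjacency, k5)
})

test_that("small-world indices are seeded, exact ratios, and 1 on complete graphs", {
  set.seed(43)
  adj <- random_adjacency(25, 0.25)
  a <- small_world_indices(adj, n_null = 10, seed = 99)
  b <- small_world_indices(adj, n_null = 10, seed = 99)
  expect_identical(a, b)
  expect_identical(a$sigma, a$gamma / a$lambda)
  expect_warning(sw <- small_world_indices(complete_graph(6), n_null = 5,
                                           seed = 1),
                 "rewiring")
  expect_equal(c(sw$gamma, sw$lambda, sw$sigma), c(1, 1, 1))
})

test_that("metric curves are tidy and include small-world rows when asked", {
  cohort <- generate_cohort(tiny_cohort(n = 20, n_rois = 16, seed = 10))
  pc <- partial_correlation(cohort$tables$G)
  stack <- sparsity_sweep(pc, c(0.2, 0.3))
  cur <- metric_curve(stack, n_null = 5, seed = 7, group = "G")
  expect_named(cur, c("group", "sparsity", "metric", "value"))
  expect_setequal(unique(cur$metric),
                  c("C", "L", "Eglob", "Eloc", "gamma", "lambda", "sigma"))
  sig <- cur$value[cur$metric == "sigma"]
  expect_identical(sig, cur$value[cur$metric == "gamma"] /
                          cur$value[cur$metric == "lambda"])
  cur2 <- metric_curve(stack, n_null = 0)
  expect_setequal(unique(cur2$metric), c("C", "L", "Eglob", "Eloc"))
})
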