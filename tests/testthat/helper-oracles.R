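# Independent brute-force oracles used to cross-check the graph machinery.
# All are explicit-loop implementations, deliberately naive.

random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  adj
}

# Per-node clustering by explicit triple loop over neighbour pairs.
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) { ci[v] <- 0; next }
    tri <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] == 1) tri <- tri + 1
      }
    }
    ci[v] <- tri / (k * (k - 1) / 2)
  }
  ci
}

# All-pairs shortest paths by Floyd-Warshall.
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_path_length <- function(adj) {
  d <- oracle_distances(adj)
  ut <- d[upper.tri(d)]
  list(L = mean(ut[is.finite(ut)]), n_disconnected_pairs = sum(!is.finite(ut)))
}

oracle_global_efficiency <- function(adj) {
  if (nrow(adj) < 2) return(0)
  d <- oracle_distances(adj)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  le <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    le[v] <- if (length(nb) < 2) 0 else {
      oracle_global_efficiency(adj[nb, nb, drop = FALSE])
    }
  }
  mean(le)
}

# Betweenness by explicit shortest-path counting (distance-layered DP),
# independent of Brandes' algorithm.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  # npaths[s, t] = number of shortest s-t paths
  npaths <- matrix(0, n, n)
  for (s in seq_len(n)) {
    npaths[s, s] <- 1
    for (dist in seq_len(n)) {
      for (t in which(d[s, ] == dist)) {
        preds <- which(adj[, t] == 1 & d[s, ] == dist - 1)
        npaths[s, t] <- sum(npaths[s, preds])
      }
    }
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          bc[v] <- bc[v] + npaths[s, v] * npaths[v, t] / npaths[s, t]
        }
      }
    }
  }
  bc
}

# Partial correlation of columns i, j of X given covariate matrix Z, by
# explicit least squares on (intercept, Z) and correlating the residuals.
oracle_partial_cor <- function(x, y, Z) {
  Zi <- cbind(1, Z)
  rx <- stats::residuals(stats::lm.fit(Zi, x))
  ry <- stats::residuals(stats::lm.fit(Zi, y))
  stats::cor(rx, ry)
}

# Benjamini-Hochberg step-up by explicit sort and scan.
oracle_bh_flags <- function(p, q_level) {
  m <- length(p)
  ord <- order(p)
  flags <- logical(m)
  max_k <- 0
  for (k in seq_len(m)) {
    if (p[ord[k]] <= k / m * q_level) max_k <- k
  }
  if (max_k > 0) flags[ord[seq_len(max_k)]] <- TRUE
  flags
}

# The light planted structure used for asymmetry power fixtures: enough
# positive-definiteness headroom to double one hemisphere's coupling.
light_structure <- function() {
  planted_structure(within_weight = 0.03, homotopic_weight = 0.10,
                    hub_weight = 0.025, hub_span = 0.8)
}

# A small cohort config for fast mechanics tests.
tiny_cohort <- function(n = 12, n_rois = 10, seed = 1, ...) {
  cohort_config(groups = c(G = n),
                structure = planted_structure(n_rois = n_rois,
                                              n_communities = 2,
                                              hub_positions = 2,
                                              hub_span = 0.5),
                hemisphere_gain = c(G = 1), seed = seed, ...)
}
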