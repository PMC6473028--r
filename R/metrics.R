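as_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                      diag = FALSE)
}

check_adjacency <- function(adj) {
  adj <- unclass(adj)
  if (nrow(adj) != ncol(adj)) abort("Adjacency must be square.")
  if (any(adj != 0 & adj != 1)) abort("Adjacency must be 0/1.")
  if (any(diag(adj) != 0)) abort("Adjacency diagonal must be zero.")
  if (!isSymmetric(unname(adj))) abort("Adjacency must be symmetric.")
  adj
}

#' Clustering coefficient
#'
#' Per-node clustering coefficient: the number of triangles through the node
#' divided by the `k(k-1)/2` pairs of its `k` neighbours, defined as 0 for
#' nodes of degree < 2, plus the mean over all nodes.
#'
#' @param adj Symmetric 0/1 adjacency matrix, zero diagonal.
#' @return List with `mean` (scalar) and `node` (named numeric vector).
#' @export
clustering_coefficient <- function(adj) {
  adj <- check_adjacency(adj)
  g <- as_graph(adj)
  ci <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(ci) <- colnames(adj)
  list(mean = mean(ci), node = ci)
}

#' Characteristic path length
#'
#' Mean shortest-path length over connected node pairs; the number of
#' disconnected (unordered) pairs is reported alongside.
#'
#' @inheritParams clustering_coefficient
#' @return List with `L` and `n_disconnected_pairs`.
#' @export
characteristic_path_length <- function(adj) {
  adj <- check_adjacency(adj)
  if (sum(adj) == 0) abort("Graph has no edges; path length undefined.")
  d <- igraph::distances(as_graph(adj))
  ut <- d[upper.tri(d)]
  finite <- is.finite(ut)
  list(L = mean(ut[finite]), n_disconnected_pairs = sum(!finite))
}

# Global efficiency of a small 0/1 adjacency matrix by breadth-first
# reachability through boolean matrix products; disconnected pairs count 0.
adj_global_efficiency <- function(a) {
  n <- nrow(a)
  if (n < 2) return(0)
  inv_sum <- 0
  reach <- a != 0
  found <- reach
  diag(found) <- TRUE
  k <- 1
  repeat {
    inv_sum <- inv_sum + sum(reach[upper.tri(reach)]) / k
    if (all(found) || k >= n - 1) break
    nxt <- ((reach %*% a) != 0) & !found
    if (!any(nxt)) break
    reach <- nxt
    found <- found | nxt
    k <- k + 1
  }
  inv_sum / (n * (n - 1) / 2)
}

# Mean local efficiency: global efficiency of each node's neighbour-induced
# subgraph, 0 for degree < 2.
adj_local_efficiency <- function(adj) {
  per_node <- vapply(seq_len(nrow(adj)), function(v) {
    nb <- which(adj[v, ] != 0)
    if (length(nb) < 2) return(0)
    adj_global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(per_node)
}

#' Global and local efficiency
#'
#' Global efficiency is the mean over node pairs of the inverse shortest-path
#' length, counting disconnected pairs as 0. Local efficiency is the mean over
#' nodes of the global efficiency of the subgraph induced by each node's
#' neighbours (node excluded; 0 for degree < 2).
#'
#' @inheritParams clustering_coefficient
#' @return List with `global` and `local`.
#' @export
efficiencies <- function(adj) {
  adj <- check_adjacency(adj)
  g <- as_graph(adj)
  eg <- igraph::global_efficiency(g)
  if (is.nan(eg)) eg <- 0
  list(global = eg, local = adj_local_efficiency(adj))
}

#' Node betweenness centrality and hub flags
#'
#' Shortest-path betweenness (equal-length paths split evenly), normalized
#' per node as `bi = BC / mean(BC)`; nodes with `bi` above the threshold
#' (default 1.5) are flagged as candidate hubs.
#'
#' @inheritParams clustering_coefficient
#' @param bi_threshold Hub threshold on normalized betweenness.
#' @return Tibble with columns `roi`, `degree`, `BC`, `bi`, `hub`.
#' @export
betweenness_table <- function(adj, bi_threshold = 1.5) {
  adj <- check_adjacency(adj)
  g <- as_graph(adj)
  bc <- igraph::betweenness(g, directed = FALSE)
  rois <- colnames(adj) %||% as.character(seq_len(ncol(adj)))
  mean_bc <- mean(bc)
  if (mean_bc == 0) {
    warn("Mean betweenness is zero; bi undefined and no hubs flagged.")
    bi <- rep(NA_real_, length(bc))
    hub <- rep(FALSE, length(bc))
  } else {
    bi <- bc / mean_bc
    hub <- bi > bi_threshold
  }
  tibble(roi = rois, degree = as.integer(colSums(adj)), BC = unname(bc),
         bi = unname(bi), hub = unname(hub))
}

#' Degree-preserving rewiring (double-edge swaps)
#'
#' Randomizes a binary graph while preserving every node's degree by repeated
#' double-edge swaps: two edges (a,b) and (c,d) are replaced by (a,d) and
#' (c,b) when this creates neither self-loops nor multi-edges. Runs until
#' `n_swaps` swaps are accepted (or a proposal budget is exhausted, e.g. on a
#' complete graph where no swap is possible). Uses R's RNG.
#'
#' @inheritParams clustering_coefficient
#' @param n_swaps Number of accepted swaps to perform.
#' @param max_tries Proposal budget (default `20 * n_swaps`).
#' @return List with `adjacency` (rewired matrix) and `accepted` (swap count).
#' @export
rewire_degree_preserving <- function(adj, n_swaps, max_tries = 20 * n_swaps) {
  adj <- check_adjacency(adj)
  n <- nrow(adj)
  link <- adj != 0
  ut <- which(upper.tri(adj) & link, arr.ind = TRUE)
  n_e <- nrow(ut)
  if (n_e < 2) return(list(adjacency = adj, accepted = 0L))
  ea <- ut[, 1]
  eb <- ut[, 2]
  accepted <- 0L
  tries <- 0L
  while (accepted < n_swaps && tries < max_tries) {
    tries <- tries + 1L
    idx <- sample.int(n_e, 2L)
    a <- ea[idx[1]]; b <- eb[idx[1]]
    c <- ea[idx[2]]; d <- eb[idx[2]]
    if (runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
    # proposed new edges: (a,d) and (c,b)
    if (a == d || c == b) next
    if (link[a, d] || link[c, b]) next
    link[a, b] <- link[b, a] <- FALSE
    link[c, d] <- link[d, c] <- FALSE
    link[a, d] <- link[d, a] <- TRUE
    link[c, b] <- link[b, c] <- TRUE
    ea[idx[1]] <- min(a, d); eb[idx[1]] <- max(a, d)
    ea[idx[2]] <- min(c, b); eb[idx[2]] <- max(c, b)
    accepted <- accepted + 1L
  }
  out <- matrix(0L, n, n, dimnames = dimnames(adj))
  out[link] <- 1L
  list(adjacency = out, accepted = accepted)
}

#' Small-world indices against degree-preserving surrogates
#'
#' Computes `gamma = C / C_null`, `lambda = L / L_null` and
#' `sigma = gamma / lambda`, where `C_null` and `L_null` are means over
#' `n_null` degree-preserving rewired surrogates (`swaps_per_edge * |E|`
#' accepted swaps each). A small-world network satisfies `gamma >> 1`,
#' `lambda ~ 1`, `sigma > 1`.
#'
#' @inheritParams clustering_coefficient
#' @param n_null Number of surrogate networks.
#' @param swaps_per_edge Accepted swaps per edge in each surrogate.
#' @param seed Optional seed for reproducible surrogates.
#' @return List with `C`, `L`, `C_null`, `L_null`, `gamma`, `lambda`,
#'   `sigma`.
#' @export
small_world_indices <- function(adj, n_null = 100, swaps_per_edge = 10,
                                seed = NULL) {
  adj <- check_adjacency(adj)
  if (n_null < 1) abort("n_null must be at least 1.")
  C <- clustering_coefficient(adj)$mean
  L <- characteristic_path_length(adj)$L
  n_e <- sum(adj) / 2
  n_swaps <- ceiling(swaps_per_edge * n_e)
  with_seed(seed, {
    c_null <- numeric(n_null)
    l_null <- numeric(n_null)
    total_accepted <- 0L
    for (k in seq_len(n_null)) {
      rw <- rewire_degree_preserving(adj, n_swaps)
      total_accepted <- total_accepted + rw$accepted
      c_null[k] <- clustering_coefficient(rw$adjacency)$mean
      l_null[k] <- characteristic_path_length(rw$adjacency)$L
    }
    if (total_accepted == 0L) {
      warn("Degree sequence admits no rewiring (e.g. complete graph); gamma = lambda = sigma = 1.")
      return(list(C = C, L = L, C_null = C, L_null = L,
                  gamma = 1, lambda = 1, sigma = 1))
    }
    gamma <- C / mean(c_null)
    lambda <- L / mean(l_null)
    list(C = C, L = L, C_null = mean(c_null), L_null = mean(l_null),
         gamma = gamma, lambda = lambda, sigma = gamma / lambda)
  })
}

# Single scalar metric of a binary network; used by sweeps and permutation
# tests. Small-world metrics need a null-model configuration.
graph_metric_value <- function(adj, metric, n_null = 100, swaps_per_edge = 10,
                               seed = NULL) {
  switch(metric,
    C = clustering_coefficient(adj)$mean,
    L = characteristic_path_length(adj)$L,
    Eglob = {
      e <- igraph::global_efficiency(as_graph(check_adjacency(adj)))
      if (is.nan(e)) 0 else e
    },
    Eloc = adj_local_efficiency(check_adjacency(adj)),
    gamma = ,
    lambda = ,
    sigma = small_world_indices(adj, n_null, swaps_per_edge, seed)[[metric]],
    abort(sprintf("Unknown metric '%s'.", metric))
  )
}

#' Graph-metric curves over a sparsity sweep
#'
#' Computes C, L, global and local efficiency — and, when `n_null > 0`, the
#' small-world indices gamma, lambda, sigma — at every sparsity of a binarized
#' network stack, as a tidy table.
#'
#' @param stack A `network_stack` from [sparsity_sweep()].
#' @param n_null Surrogates per sparsity for the small-world indices; 0 skips
#'   them.
#' @param swaps_per_edge Accepted swaps per edge per surrogate.
#' @param seed Optional master seed (one sub-seed per sparsity level).
#' @param group Optional group label recorded in the output.
#' @return Tidy tibble: `group`, `sparsity`, `metric`, `value`.
#' @export
metric_curve <- function(stack, n_null = 100, swaps_per_edge = 10,
                         seed = NULL, group = NA_character_) {
  stopifnot(inherits(stack, "network_stack"))
  seeds <- if (is.null(seed)) {
    rep(list(NULL), length(stack$sparsities))
  } else {
    as.list(derive_seeds(seed, length(stack$sparsities)))
  }
  rows <- purrr::map2(seq_along(stack$sparsities), seeds, function(i, s_i) {
    adj <- stack$adjacency[[i]]
    vals <- c(
      C = clustering_coefficient(adj)$mean,
      L = characteristic_path_length(adj)$L,
      Eglob = efficiencies(adj)$global,
      Eloc = efficiencies(adj)$local
    )
    if (n_null > 0) {
      sw <- small_world_indices(adj, n_null, swaps_per_edge, seed = s_i)
      vals <- c(vals, gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma)
    }
    tibble(group = group, sparsity = stack$sparsities[i],
           metric = names(vals), value = unname(vals))
  })
  dplyr::bind_rows(rows)
}

#' Hub table at a fixed sparsity
#'
#' Binarizes an association matrix at one sparsity (default the 28% used for
#' hub detection, at which whole-brain networks are typically fully
#' connected) and flags hubs by normalized betweenness. Warns when the
#' network is not fully connected at that sparsity.
#'
#' @param m `pcor_matrix` or plain symmetric matrix.
#' @param sparsity Sparsity threshold (default 0.28).
#' @param bi_threshold Hub threshold (default 1.5).
#' @inheritParams binarize_at_sparsity
#' @return Tibble `roi`, `degree`, `BC`, `bi`, `hub` with attributes
#'   `sparsity` and `connected`.
#' @export
hub_table <- function(m, sparsity = 0.28, bi_threshold = 1.5,
                      ranking = c("signed", "absolute")) {
  adj <- binarize_at_sparsity(m, sparsity, match.arg(ranking))
  connected <- igraph::is_connected(as_graph(adj))
  if (!connected) {
    warn(sprintf("Network is not fully connected at sparsity %g%%.",
                 100 * sparsity))
  }
  out <- betweenness_table(adj, bi_threshold)
  attr(out, "sparsity") <- sparsity
  attr(out, "connected") <- connected
  out
}
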