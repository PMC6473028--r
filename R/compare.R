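#' Permutation test for between-group differences in a network metric
#'
#' Tests, at every sparsity of the grid, the difference in a group-level
#' network metric between two groups (group A minus group B). The null
#' distribution is built by randomly reassigning subjects to two pseudo-groups
#' of the original sizes and rebuilding both partial-correlation networks and
#' the metric for each permutation; covariates travel with the subjects. The
#' two-tailed p-value uses the add-one convention
#' `p = (1 + #\{|null| >= |obs|\}) / (1 + n_perm)`, so p is never 0.
#'
#' @param table_a,table_b Subject x ROI tibbles for the two groups (same ROI
#'   columns).
#' @param metric One of `"C"`, `"L"`, `"Eglob"`, `"Eloc"`, `"gamma"`,
#'   `"lambda"`, `"sigma"`. Small-world metrics re-run the null model inside
#'   every permutation and are costly.
#' @param grid Sparsity grid (default 6-40% in 1% steps).
#' @param n_perm Number of permutations (>= 100; the study convention is
#'   1000).
#' @param alpha Significance level for range reporting.
#' @param seed Seed for the permutation stream.
#' @param covariates Covariates removed before correlation.
#' @param n_null,swaps_per_edge Null-model settings, used only for
#'   small-world metrics.
#' @inheritParams binarize_at_sparsity
#' @return Object of class `permutation_result`: tibble with `sparsity`,
#'   `obs_diff`, `p`, `significant`, plus attributes `metric`, `n_perm`,
#'   `alpha`, `seed`, `groups`, `ranges`.
#' @export
permutation_test <- function(table_a, table_b, metric = "Eglob",
                             grid = default_sparsity_grid(),
                             n_perm = 1000, alpha = 0.05, seed = NULL,
                             covariates = c("age", "sex"),
                             ranking = c("signed", "absolute"),
                             n_null = 100, swaps_per_edge = 10) {
  ranking <- match.arg(ranking)
  if (n_perm < 100) abort("n_perm must be at least 100.")
  rois <- roi_columns(table_a)
  if (!identical(rois, roi_columns(table_b))) {
    abort("The two tables must share the same ROI columns.")
  }
  n_a <- nrow(table_a)
  n_b <- nrow(table_b)
  if (min(n_a, n_b) <= length(covariates) + 2) {
    abort("Groups too small for partial correlation after relabelling.")
  }
  # subjects pooled for relabelling; the group column is dropped so permuted
  # pseudo-groups are valid single-group tables. Rows are put in a canonical
  # order so results do not depend on input row order.
  combined <- dplyr::bind_rows(
    dplyr::mutate(table_a, group = NULL, .in_a = TRUE),
    dplyr::mutate(table_b, group = NULL, .in_a = FALSE)
  )
  if ("subject_id" %in% names(combined)) {
    combined <- combined[order(combined$subject_id), ]
  }
  in_a <- which(combined$.in_a)
  combined$.in_a <- NULL

  curve_fun <- function(tab, seed_i) {
    pc <- partial_correlation(tab, covariates)
    stack <- sparsity_sweep(pc, grid, ranking)
    vapply(seq_along(grid), function(i) {
      graph_metric_value(stack$adjacency[[i]], metric, n_null,
                         swaps_per_edge, seed_i)
    }, numeric(1))
  }

  seeds <- if (is.null(seed)) NULL else derive_seeds(seed, n_perm + 3)
  obs <- curve_fun(combined[in_a, ],
                   if (is.null(seeds)) NULL else seeds[1]) -
         curve_fun(combined[-in_a, ],
                   if (is.null(seeds)) NULL else seeds[2])

  n_tot <- n_a + n_b
  count_ge <- rep(0L, length(grid))
  with_seed(if (is.null(seeds)) NULL else seeds[3], {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n_tot, n_a)
      d <- curve_fun(combined[idx, ],
                     if (is.null(seeds)) NULL else seeds[3 + b]) -
           curve_fun(combined[-idx, ],
                     if (is.null(seeds)) NULL else seeds[3 + b])
      count_ge <- count_ge + (abs(d) >= abs(obs))
    }
  })
  p <- (1 + count_ge) / (1 + n_perm)
  out <- tibble(sparsity = grid, obs_diff = obs, p = p,
                significant = p < alpha)
  ranges <- significant_ranges(p, grid, alpha)
  structure(out,
            class = c("permutation_result", class(out)),
            metric = metric, n_perm = n_perm, alpha = alpha, seed = seed,
            groups = c(unique(table_a$group) %||% "A",
                       unique(table_b$group) %||% "B"),
            ranges = ranges)
}

#' Maximal contiguous sparsity ranges of significance
#'
#' Collapses per-sparsity p-values into the maximal contiguous runs with
#' `p < alpha`, reported as closed percent intervals (the form in which
#' significant sparsity ranges such as 18-33% are quoted).
#'
#' @param p P-values on an ordered sparsity grid.
#' @param grid The sparsity grid (fractions).
#' @param alpha Significance level.
#' @return Tibble with `start_pct`, `end_pct`, one row per run; zero rows if
#'   nothing is significant.
#' @export
significant_ranges <- function(p, grid, alpha = 0.05) {
  stopifnot(length(p) == length(grid))
  sig <- p < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  tibble(start_pct = 100 * grid[starts[keep]],
         end_pct = 100 * grid[ends[keep]])
}

#' @export
tidy.permutation_result <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.permutation_result <- function(x, ...) {
  rng <- attr(x, "ranges")
  tibble(metric = attr(x, "metric"),
         group_a = attr(x, "groups")[1],
         group_b = attr(x, "groups")[2],
         n_perm = attr(x, "n_perm"),
         alpha = attr(x, "alpha"),
         n_significant = sum(x$significant),
         ranges = paste(sprintf("%g-%g%%", rng$start_pct, rng$end_pct),
                        collapse = ", "))
}
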