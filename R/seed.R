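#' Fisher r-to-z transformation
#'
#' `z = 0.5 * ln((1 + r) / (1 - r))` (natural log), the variance-stabilizing
#' transform that makes correlation coefficients approximately Gaussian.
#'
#' @param r Correlation value(s), strictly inside (-1, 1).
#' @return z value(s).
#' @examples
#' fisher_z(0.5)
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    abort("fisher_z requires |r| < 1.")
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Seed-based correlation map
#'
#' Pearson correlation of one seed ROI's signal with every other ROI's signal
#' across the subjects of a group, optionally after residualizing on
#' covariates (off by default: the seed analysis uses plain Pearson
#' correlation). Targets perfectly correlated with the seed (|r| = 1, e.g. a
#' duplicated column) are reported but get `z = NA` with a warning.
#'
#' @param table Subject x ROI tibble (one group).
#' @param seed_roi Seed ROI column name (default `"MTG.R"`, the right middle
#'   temporal gyrus).
#' @param covariates Optional covariates to residualize on (default none).
#' @return Tibble `target`, `r`, `z` with attributes `seed_roi`,
#'   `n_subjects`.
#' @export
seed_map <- function(table, seed_roi = "MTG.R", covariates = character(0)) {
  rois <- roi_columns(table)
  if (!(seed_roi %in% rois)) {
    abort(sprintf("Seed ROI '%s' is not a column of the table.", seed_roi))
  }
  if (nrow(table) < 5) abort("Need at least 5 subjects for a seed map.")
  X <- signal_matrix(table)
  if (length(covariates) > 0) {
    Z <- cbind(1, as.matrix(as.data.frame(table)[, covariates, drop = FALSE]))
    storage.mode(Z) <- "double"
    X <- qr.resid(qr(Z), X)
  }
  if (stats::var(X[, seed_roi]) == 0) {
    abort(sprintf("Seed ROI '%s' has zero variance.", seed_roi))
  }
  targets <- setdiff(rois, seed_roi)
  r <- as.vector(stats::cor(X[, seed_roi], X[, targets]))
  boundary <- abs(r) >= 1 - 1e-15
  z <- rep(NA_real_, length(r))
  z[!boundary] <- fisher_z(r[!boundary])
  if (any(boundary)) {
    warn(paste0("Target(s) perfectly correlated with the seed (|r| = 1): ",
                paste(targets[boundary], collapse = ", "),
                "; excluded from z."))
  }
  out <- tibble(target = targets, r = r, z = z)
  attr(out, "seed_roi") <- seed_roi
  attr(out, "n_subjects") <- nrow(table)
  out
}

#' Compare two groups' seed maps with Fisher-z statistics
#'
#' For each target ROI, `Z = (z1 - z2) / sqrt(1/(n1 - 3) + 1/(n2 - 3))` with a
#' two-tailed p-value from the standard normal. Z is antisymmetric under
#' swapping the groups.
#'
#' @param map1,map2 Seed maps from [seed_map()] sharing targets.
#' @param n1,n2 Group sizes (each > 3); defaults read from the maps.
#' @return Tibble `target`, `z1`, `z2`, `Z`, `p`.
#' @export
compare_seed_maps <- function(map1, map2,
                              n1 = attr(map1, "n_subjects"),
                              n2 = attr(map2, "n_subjects")) {
  if (is.null(n1) || is.null(n2) || n1 <= 3 || n2 <= 3) {
    abort("Both group sizes must exceed 3.")
  }
  if (!identical(map1$target, map2$target)) {
    abort("Seed maps do not share the same targets.")
  }
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  Z <- (map1$z - map2$z) / se
  tibble(target = map1$target, z1 = map1$z, z2 = map2$z, Z = Z,
         p = 2 * stats::pnorm(-abs(Z)))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment; discoveries are targets with adjusted q at or
#' below `q_level`.
#'
#' @param p P-values in \[0, 1\].
#' @param q_level FDR level (default 0.05).
#' @return Tibble `p`, `q`, `significant`.
#' @export
fdr_correct <- function(p, q_level = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  q <- stats::p.adjust(p, method = "BH")
  tibble(p = p, q = q, significant = !is.na(q) & q <= q_level)
}

#' Full seed-based group comparison
#'
#' Seed maps for two groups, Fisher-z group statistic per target, FDR
#' correction, and a direction flag (connection strengthened or weakened in
#' group 1 relative to group 2).
#'
#' @param table1,table2 Subject x ROI tibbles for the two groups.
#' @inheritParams seed_map
#' @param q_level FDR level.
#' @return Object of class `seed_comparison`: tibble `target`, `r1`, `r2`,
#'   `z1`, `z2`, `Z`, `p`, `q`, `significant`, `direction`.
#' @export
seed_comparison <- function(table1, table2, seed_roi = "MTG.R",
                            covariates = character(0), q_level = 0.05) {
  m1 <- seed_map(table1, seed_roi, covariates)
  m2 <- seed_map(table2, seed_roi, covariates)
  cmp <- compare_seed_maps(m1, m2)
  fdr <- fdr_correct(cmp$p, q_level)
  out <- tibble(target = cmp$target, r1 = m1$r, r2 = m2$r,
                z1 = cmp$z1, z2 = cmp$z2, Z = cmp$Z,
                p = cmp$p, q = fdr$q, significant = fdr$significant,
                direction = dplyr::case_when(
                  !fdr$significant ~ "none",
                  cmp$Z > 0 ~ "strengthened",
                  TRUE ~ "weakened"
                ))
  structure(out, class = c("seed_comparison", class(out)),
            seed_roi = seed_roi, q_level = q_level,
            groups = c(unique(table1$group) %||% "1",
                       unique(table2$group) %||% "2"),
            n = c(attr(m1, "n_subjects"), attr(m2, "n_subjects")))
}

#' @export
glance.seed_comparison <- function(x, ...) {
  tibble(seed_roi = attr(x, "seed_roi"),
         group_1 = attr(x, "groups")[1], group_2 = attr(x, "groups")[2],
         n1 = attr(x, "n")[1], n2 = attr(x, "n")[2],
         q_level = attr(x, "q_level"),
         n_strengthened = sum(x$direction == "strengthened"),
         n_weakened = sum(x$direction == "weakened"))
}
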