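#' Group-level partial-correlation matrix
#'
#' Builds the metabolic covariance network for one group: the entry (i, j) is
#' the Pearson correlation between ROI i and ROI j signals across subjects
#' after each ROI has been residualized on the covariates (with intercept).
#' With `covariates = character(0)` this reduces to the plain Pearson
#' correlation matrix. Residualizing on linear covariates is the textbook
#' partial correlation controlling for those covariates, used here to exclude
#' age and sex interference from the between-region covariance.
#'
#' @param table Subject x ROI tibble for a single group.
#' @param covariates Character vector of covariate column names (default age
#'   and sex).
#' @return An object of class `pcor_matrix`: the ROI x ROI correlation matrix
#'   with attributes `group`, `n_subjects`, `covariates`.
#' @examples
#' cohort <- generate_cohort(cohort_config(groups = c(HC = 12),
#'                                         structure = planted_structure(n_rois = 8),
#'                                         seed = 7))
#' pc <- partial_correlation(cohort$tables$HC)
#' range(pc[upper.tri(pc)])
#' @export
partial_correlation <- function(table, covariates = c("age", "sex")) {
  if ("group" %in% names(table) && length(unique(table$group)) > 1) {
    abort("Table mixes several groups; build one network per group.")
  }
  X <- signal_matrix(table)
  n <- nrow(X)
  if (n <= length(covariates) + 2) {
    abort(sprintf("Need more than %d subjects to control %d covariate(s); got %d.",
                  length(covariates) + 2, length(covariates), n))
  }
  if (length(covariates) > 0) {
    missing <- setdiff(covariates, names(table))
    if (length(missing) > 0) {
      abort(paste0("Covariate column(s) not in table: ",
                   paste(missing, collapse = ", ")))
    }
    Zc <- as.matrix(as.data.frame(table)[, covariates, drop = FALSE])
    storage.mode(Zc) <- "double"
    # constant covariates are absorbed by the intercept: residualizing on
    # them is a no-op, so drop them (routine for binary sex in small groups)
    keep <- apply(Zc, 2, function(z) stats::var(z) > 0)
    Z <- cbind(1, Zc[, keep, drop = FALSE])
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) {
      abort("Covariate design is rank deficient (collinear covariates).")
    }
    X <- qr.resid(qz, X)
  } else {
    X <- sweep(X, 2, colMeans(X))
  }
  v <- colSums(X^2)
  zero_var <- colnames(X)[v <= .Machine$double.eps * n]
  if (length(zero_var) > 0) {
    warn(paste0("Zero-variance residual for ROI(s): ",
                paste(zero_var, collapse = ", "),
                "; their correlations are undefined (NA)."))
    X[, zero_var] <- NA_real_
  }
  R <- stats::cor(X)
  R[is.nan(R)] <- NA_real_
  diag(R) <- 1
  R <- (R + t(R)) / 2 # enforce exact symmetry
  group <- if ("group" %in% names(table)) unique(table$group) else NA_character_
  structure(R, class = c("pcor_matrix", "matrix", "array"),
            group = group, n_subjects = n, covariates = covariates)
}

#' Binarize an association matrix at a sparsity threshold
#'
#' Keeps exactly `round(sparsity * P)` of the `P = R(R-1)/2` unordered node
#' pairs — those with the strongest connections — as edges (1), all others 0.
#' Pairs are ranked by signed correlation by default (strongest positive
#' first); an absolute-value ranking is available. Ties at the threshold
#' boundary are broken deterministically in lexicographic (i, j) order. Edge
#' counts use R's `round()` (round-half-to-even).
#'
#' @param m `pcor_matrix` or plain symmetric matrix.
#' @param sparsity Fraction of pairs kept, in (0, 1).
#' @param ranking `"signed"` (default) or `"absolute"`.
#' @return Symmetric 0/1 integer adjacency matrix with zero diagonal.
#' @export
binarize_at_sparsity <- function(m, sparsity, ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  m <- unclass(m)
  R <- nrow(m)
  if (R != ncol(m)) abort("Matrix must be square.")
  if (sparsity <= 0 || sparsity >= 1) abort("sparsity must be in (0, 1).")
  P <- R * (R - 1) / 2
  n_edges <- round(sparsity * P)
  if (n_edges < 1) {
    abort(sprintf("sparsity %.4f keeps zero of %d pairs.", sparsity, P))
  }
  ut <- which(upper.tri(m), arr.ind = TRUE)
  vals <- m[upper.tri(m)]
  if (anyNA(vals)) {
    abort("Association matrix has undefined (NA) entries; cannot rank pairs.")
  }
  key <- if (ranking == "absolute") abs(vals) else vals
  ord <- order(-key, ut[, 1], ut[, 2])
  keep <- ord[seq_len(n_edges)]
  adj <- matrix(0L, R, R, dimnames = dimnames(m))
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj[cbind(ut[keep, 2], ut[keep, 1])] <- 1L
  adj
}

#' Binarize across a sparsity sweep
#'
#' Applies [binarize_at_sparsity()] over an increasing grid of sparsities
#' (default 6-40% in 1% steps, 35 levels). Because every level ranks the same
#' pairs, the edge sets are nested: edges at a lower sparsity are a subset of
#' edges at any higher one.
#'
#' @param m `pcor_matrix` or plain symmetric matrix.
#' @param grid Strictly increasing sparsity grid within (0, 1).
#' @inheritParams binarize_at_sparsity
#' @return Object of class `network_stack`: list with `sparsities` and
#'   `adjacency` (list of 0/1 matrices).
#' @export
sparsity_sweep <- function(m, grid = default_sparsity_grid(),
                           ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("Sparsity grid must be strictly increasing.")
  }
  adjacency <- lapply(grid, function(s) binarize_at_sparsity(m, s, ranking))
  names(adjacency) <- format_sparsity(grid)
  out <- list(sparsities = grid, adjacency = adjacency)
  class(out) <- "network_stack"
  out
}

#' Default sparsity grid: 6\% to 40\% in 1\% steps
#' @return Numeric vector of length 35.
#' @export
default_sparsity_grid <- function() {
  seq(6L, 40L) / 100
}

format_sparsity <- function(s) sprintf("%g%%", 100 * s)

#' @export
print.pcor_matrix <- function(x, ...) {
  cat(sprintf("Partial-correlation network: %d ROIs, group '%s', n = %d, covariates: %s\n",
              nrow(x), attr(x, "group"), attr(x, "n_subjects"),
              if (length(attr(x, "covariates"))) {
                paste(attr(x, "covariates"), collapse = ", ")
              } else "none"))
  invisible(x)
}

#' @export
tidy.pcor_matrix <- function(x, ...) {
  m <- unclass(x)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  rois <- colnames(m) %||% as.character(seq_len(ncol(m)))
  tibble(roi_i = rois[ut[, 1]], roi_j = rois[ut[, 2]],
         pcor = m[upper.tri(m)])
}

#' Write an association matrix as delimited text
#' @param m Matrix (ROI names as dimnames become the header).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = FALSE)
  invisible(path)
}
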