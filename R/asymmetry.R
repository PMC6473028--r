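#' Split a subject table by hemisphere
#'
#' Partitions the ROI columns into left- and right-hemisphere tables (45
#' regions each on the default atlas), subjects unchanged.
#'
#' @param table Subject x ROI tibble.
#' @param atlas Atlas definition with a `hemisphere` column covering every
#'   ROI column of the table.
#' @return List with `left` and `right` tibbles.
#' @export
split_hemispheres <- function(table, atlas = aal90_atlas()) {
  rois <- roi_columns(table)
  missing <- setdiff(rois, atlas$abbrev)
  if (length(missing) > 0) {
    abort(paste0("ROI(s) without an atlas hemisphere label: ",
                 paste(missing, collapse = ", ")))
  }
  hemi <- atlas$hemisphere[match(rois, atlas$abbrev)]
  left <- rois[hemi == "L"]
  right <- rois[hemi == "R"]
  if (length(left) != length(right)) {
    abort(sprintf("Unbalanced hemispheres: %d left vs %d right ROIs.",
                  length(left), length(right)))
  }
  meta <- intersect(META_COLS, names(table))
  list(left = table[, c(meta, left)], right = table[, c(meta, right)])
}

#' Hemispheric network efficiencies
#'
#' Builds each hemisphere's partial-correlation network independently from
#' the same subjects, binarizes both at the same sparsity, and returns global
#' and local efficiency per side.
#'
#' @param left,right Hemispheric subject tables from [split_hemispheres()].
#' @param covariates Covariates removed before correlation.
#' @param sparsity Sparsity threshold applied to both hemispheres.
#' @inheritParams binarize_at_sparsity
#' @return Tibble with `metric` (`"global"`, `"local"`), `M_L`, `M_R`.
#' @export
hemispheric_efficiencies <- function(left, right, covariates = c("age", "sex"),
                                     sparsity = 0.28,
                                     ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  eff_side <- function(tab) {
    pc <- partial_correlation(tab, covariates)
    adj <- binarize_at_sparsity(pc, sparsity, ranking)
    efficiencies(adj)
  }
  el <- eff_side(left)
  er <- eff_side(right)
  tibble(metric = c("global", "local"),
         M_L = c(el$global, el$local),
         M_R = c(er$global, er$local))
}

#' Hemispheric asymmetry index
#'
#' `AI = 200 * |M_R - M_L| / (M_R + M_L)`: a percent-scaled, non-negative
#' measure of left-right imbalance of a hemispheric network measure, zero iff
#' the two sides are equal and invariant to common rescaling.
#'
#' @param m_r,m_l Non-negative right- and left-hemisphere measures (not both
#'   zero); vectorized.
#' @return AI value(s).
#' @examples
#' asymmetry_index(0.6253, 0.6247)
#' @export
asymmetry_index <- function(m_r, m_l) {
  if (any(m_r < 0 | m_l < 0)) abort("Efficiencies must be non-negative.")
  if (any(m_r + m_l == 0)) abort("M_R + M_L must be positive.")
  200 * abs(m_r - m_l) / (m_r + m_l)
}

#' Within-group test of hemispheric asymmetry
#'
#' Two resampling schemes are run: subject-level hemisphere sign-flips and a
#' subject bootstrap.
#'
#' The within-group p-value for left vs right (default
#' `method = "signflip"`) comes from a paired permutation: each subject's
#' left and right hemispheric blocks are swapped independently with
#' probability 1/2 (homotopic regions aligned), both pseudo-hemisphere
#' networks rebuilt, and the null distribution of `M_R - M_L` accumulated
#' over `n_rep` replicates; under the mirror-symmetry null the subject-wise
#' (left, right) pair is exchangeable, so the test is calibrated. The
#' two-tailed p uses the add-one convention.
#'
#' `method = "bootstrap"` instead resamples subjects with replacement and
#' takes the two-tailed add-one fraction of the resampled `M_R - M_L`
#' distribution crossing zero. Bootstrapping correlation-matrix functionals
#' at cohort-scale n inflates the spread of the resampled difference
#' (duplicated subjects), making this variant conservative; it is retained
#' because its replicates provide the sampling (not null) distributions.
#'
#' Bootstrap draws of `M_L`, `M_R` and AI are returned in `draws` — they are
#' the resampling distributions used by [compare_ai_between_groups()]. Set
#' `n_boot = 0` to skip them when only the within-group p is needed. When
#' `p < alpha` the direction is `rightward` or `leftward` per the sign of the
#' observed difference.
#'
#' @param table Subject x ROI tibble for one group.
#' @param covariates Covariates removed before correlation.
#' @param sparsity Sparsity threshold for both hemispheric networks.
#' @param n_rep Number of resampling replicates (>= 100; study convention
#'   1000).
#' @param seed Seed for the resampling stream.
#' @param alpha Level at which a direction is declared.
#' @param atlas Atlas with hemisphere labels.
#' @param method `"signflip"` (default) or `"bootstrap"`; see Details.
#' @param n_boot Number of bootstrap draws for the AI distributions (default
#'   `n_rep`; 0 skips them — then `method` must be `"signflip"`).
#' @inheritParams binarize_at_sparsity
#' @return Object of class `asymmetry_result`: list with `group`, `sparsity`,
#'   `summary` (tibble: `metric`, `M_L`, `M_R`, `AI`, `p`, `direction`),
#'   `draws` (tibble: `rep`, `metric`, `M_L`, `M_R`, `AI`), `n_redrawn`.
#' @export
within_group_test <- function(table, covariates = c("age", "sex"),
                              sparsity = 0.28, n_rep = 1000, seed = NULL,
                              alpha = 0.05, atlas = aal90_atlas(),
                              method = c("signflip", "bootstrap"),
                              ranking = c("signed", "absolute"),
                              n_boot = n_rep) {
  method <- match.arg(method)
  ranking <- match.arg(ranking)
  if (n_rep < 100) abort("n_rep must be at least 100.")
  if (n_boot == 0 && method == "bootstrap") {
    abort("n_boot = 0 requires method = 'signflip'.")
  }
  halves <- split_hemispheres(table, atlas)
  obs <- hemispheric_efficiencies(halves$left, halves$right, covariates,
                                  sparsity, ranking)
  n <- nrow(table)
  L <- signal_matrix(halves$left)
  R <- signal_matrix(halves$right)
  meta <- halves$left[, intersect(META_COLS, names(halves$left))]

  rebuild <- function(Lm, Rm) {
    hemispheric_efficiencies(dplyr::bind_cols(meta, as_tibble(Lm)),
                             dplyr::bind_cols(meta, as_tibble(Rm)),
                             covariates, sparsity, ranking)
  }
  col_ok <- function(m) {
    cm <- colMeans(m)
    all(colSums((m - rep(cm, each = nrow(m)))^2) > 0)
  }

  n_redrawn <- 0L
  boot <- NULL
  flips <- NULL
  with_seed(seed, {
    boot <- purrr::map(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (col_ok(L[idx, , drop = FALSE]) && col_ok(R[idx, , drop = FALSE])) break
        n_redrawn <<- n_redrawn + 1L
      }
      eff <- rebuild(L[idx, , drop = FALSE], R[idx, , drop = FALSE])
      dplyr::mutate(eff, rep = b, AI = asymmetry_index(.data$M_R, .data$M_L))
    })
    if (method == "signflip") {
      flips <- purrr::map(seq_len(n_rep), function(b) {
        repeat {
          swap <- runif(n) < 0.5
          Lf <- L; Rf <- R
          Lf[swap, ] <- R[swap, ]
          Rf[swap, ] <- L[swap, ]
          if (col_ok(Lf) && col_ok(Rf)) break
          n_redrawn <<- n_redrawn + 1L
        }
        eff <- rebuild(Lf, Rf)
        eff$M_R - eff$M_L # per metric, null difference
      })
    }
  })
  draws <- if (n_boot > 0) {
    dplyr::bind_rows(boot)[, c("rep", "metric", "M_L", "M_R", "AI")]
  } else {
    tibble(rep = integer(0), metric = character(0), M_L = numeric(0),
           M_R = numeric(0), AI = numeric(0))
  }

  summary <- purrr::map_dfr(c("global", "local"), function(met) {
    k <- which(obs$metric == met)
    o <- obs[k, ]
    obs_diff <- o$M_R - o$M_L
    if (method == "signflip") {
      null_diffs <- vapply(flips, `[`, numeric(1), k)
      p <- (1 + sum(abs(null_diffs) >= abs(obs_diff))) / (1 + n_rep)
    } else {
      d <- draws[draws$metric == met, ]
      diff_draws <- d$M_R - d$M_L
      p_lo <- (1 + sum(diff_draws <= 0)) / (1 + n_rep)
      p_hi <- (1 + sum(diff_draws >= 0)) / (1 + n_rep)
      p <- min(1, 2 * min(p_lo, p_hi))
    }
    tibble(metric = met, M_L = o$M_L, M_R = o$M_R,
           AI = asymmetry_index(o$M_R, o$M_L), p = p,
           direction = if (p < alpha) {
             if (obs_diff > 0) "rightward" else "leftward"
           } else "none")
  })

  out <- list(group = unique(table$group) %||% NA_character_,
              sparsity = sparsity, method = method, n_rep = n_rep,
              seed = seed, alpha = alpha,
              summary = summary, draws = draws, n_redrawn = n_redrawn)
  class(out) <- "asymmetry_result"
  out
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf("Hemispheric asymmetry, group '%s' (sparsity %g%%, %d %s replicates)\n",
              x$group, 100 * x$sparsity, x$n_rep, x$method))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.asymmetry_result <- function(x, ...) {
  dplyr::mutate(x$summary, group = x$group, sparsity = x$sparsity,
                .before = 1)
}

#' @export
glance.asymmetry_result <- function(x, ...) {
  tibble(group = x$group, sparsity = x$sparsity, method = x$method,
         n_rep = x$n_rep, n_redrawn = x$n_redrawn,
         AI_global = x$summary$AI[x$summary$metric == "global"],
         AI_local = x$summary$AI[x$summary$metric == "local"])
}

#' Compare asymmetry indices between two groups
#'
#' Welch two-sample t-test on the resampled AI distributions of two groups
#' (e.g. a disease group against controls), per efficiency metric.
#'
#' @param result_1,result_2 `asymmetry_result` objects carrying resampling
#'   draws.
#' @param metric `"global"`, `"local"`, or both (default).
#' @return Tibble `metric`, `mean_AI_1`, `mean_AI_2`, `t`, `df`, `p`.
#' @export
compare_ai_between_groups <- function(result_1, result_2,
                                      metric = c("global", "local")) {
  purrr::map_dfr(metric, function(met) {
    a <- result_1$draws$AI[result_1$draws$metric == met]
    b <- result_2$draws$AI[result_2$draws$metric == met]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) {
        return(tibble(metric = met, mean_AI_1 = mean(a), mean_AI_2 = mean(b),
                      t = 0, df = NA_real_, p = 1))
      }
      abort("Degenerate (zero-variance) AI distributions differ in mean; t-test undefined.")
    }
    tt <- stats::t.test(a, b)
    tibble(metric = met, mean_AI_1 = mean(a), mean_AI_2 = mean(b),
           t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value)
  })
}
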