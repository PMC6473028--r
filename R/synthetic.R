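#' Planted association structure for synthetic cohorts
#'
#' Defines the ground-truth partial-correlation pattern from which synthetic
#' subject x ROI signals are drawn. The layout mirrors an AAL-style
#' parcellation: homotopic left/right pairs interleaved (left on odd columns),
#' each hemisphere divided into contiguous communities with positive
#' within-community partial correlations, homotopic pairs coupled across
#' hemispheres, and designated bilateral hub nodes wired to many regions in
#' their own hemisphere so that they carry high betweenness in the binarized
#' network. A `hemisphere_gain` multiplier on one hemisphere's
#' within-hemisphere weights plants an efficiency asymmetry (see
#' [plant_asymmetry()] for the direction of the effect).
#'
#' The weight matrix `W` holds planted partial correlations; the implied
#' precision matrix is `I - W_offdiag` and the population covariance its
#' inverse, which must be positive definite.
#'
#' @param n_rois Even number of regions (default 90).
#' @param n_communities Communities per hemisphere (default 5).
#' @param within_weight Partial correlation planted between same-community,
#'   same-hemisphere pairs.
#' @param homotopic_weight Partial correlation planted between left/right
#'   homotopic pairs.
#' @param hub_positions Base-pair positions (1..n_rois/2) planted as bilateral
#'   hubs.
#' @param hub_weight Partial correlation between a hub and each of its planted
#'   partners.
#' @param hub_span Fraction of same-hemisphere nodes each hub is wired to.
#' @param hemisphere_gain Multiplier applied to within-hemisphere weights of
#'   `gain_hemisphere` (1 = symmetric).
#' @param gain_hemisphere `"L"` or `"R"`.
#' @return An object of class `planted_structure`: list with `weights`
#'   (n_rois x n_rois symmetric matrix, unit diagonal), `hub_nodes` (ROI
#'   indices), `hemisphere` (per-ROI `"L"`/`"R"`), `community` (per-ROI
#'   integer), `hemisphere_gain`, `gain_hemisphere`.
#' @export
planted_structure <- function(n_rois = 90,
                              n_communities = 5,
                              within_weight = 0.05,
                              homotopic_weight = 0.15,
                              hub_positions = c(2, 11, 22, 38),
                              hub_weight = 0.045,
                              hub_span = 0.8,
                              hemisphere_gain = 1,
                              gain_hemisphere = "R") {
  if (n_rois %% 2 != 0) abort("n_rois must be even (hemisphere split).")
  half <- n_rois / 2L
  if (n_communities > half) abort("More communities than base positions.")
  if (any(hub_positions < 1 | hub_positions > half)) {
    abort("hub_positions must lie in 1..n_rois/2.")
  }
  hemisphere <- rep(c("L", "R"), half)
  base_pos <- rep(seq_len(half), each = 2) # homotopic pair index per ROI
  comm_of_pos <- as.integer(cut(seq_len(half), breaks = n_communities,
                                labels = FALSE))
  community <- comm_of_pos[base_pos]

  W <- matrix(0, n_rois, n_rois)
  # same hemisphere, same community
  for (i in seq_len(n_rois - 1)) {
    for (j in (i + 1):n_rois) {
      if (hemisphere[i] == hemisphere[j] && community[i] == community[j]) {
        W[i, j] <- W[j, i] <- within_weight
      }
    }
  }
  # homotopic coupling
  for (p in seq_len(half)) {
    i <- 2L * p - 1L
    j <- 2L * p
    W[i, j] <- W[j, i] <- homotopic_weight
  }
  # bilateral hubs: each hub wired to the first hub_span fraction of base
  # positions in its own hemisphere (mirrored on the other side)
  n_span <- max(1L, floor(hub_span * (half - 1)))
  hub_nodes <- integer(0)
  for (p in hub_positions) {
    partners_pos <- setdiff(seq_len(half), p)[seq_len(n_span)]
    for (side in 0:1) { # 0 = left (odd), 1 = right (even)
      h <- 2L * p - 1L + side
      partners <- 2L * partners_pos - 1L + side
      W[h, partners] <- pmax(W[h, partners], hub_weight)
      W[partners, h] <- W[h, partners]
      hub_nodes <- c(hub_nodes, h)
    }
  }
  diag(W) <- 1
  structure_obj <- new_planted_structure(W, sort(hub_nodes), hemisphere,
                                         community, 1, gain_hemisphere)
  if (hemisphere_gain != 1) {
    structure_obj <- plant_asymmetry(structure_obj, hemisphere_gain,
                                     gain_hemisphere)
  }
  structure_obj
}

new_planted_structure <- function(weights, hub_nodes, hemisphere, community,
                                  hemisphere_gain, gain_hemisphere) {
  out <- list(weights = weights, hub_nodes = hub_nodes,
              hemisphere = hemisphere, community = community,
              hemisphere_gain = hemisphere_gain,
              gain_hemisphere = gain_hemisphere)
  class(out) <- "planted_structure"
  check_positive_definite(out)
  out
}

#' Wrap an explicit weight matrix as a planted structure
#'
#' For tests and custom simulations: supply the planted partial-correlation
#' matrix directly (symmetric, unit diagonal). Hemisphere labels follow the
#' interleaved convention (left on odd columns).
#'
#' @param weights Symmetric matrix with unit diagonal.
#' @param hub_nodes Optional ROI indices regarded as planted hubs.
#' @return A `planted_structure`.
#' @export
as_planted_structure <- function(weights, hub_nodes = integer(0)) {
  n <- nrow(weights)
  if (n %% 2 != 0) abort("weights must have an even dimension.")
  if (!isSymmetric(unname(weights))) abort("weights must be symmetric.")
  if (any(diag(weights) != 1)) abort("weights must have unit diagonal.")
  new_planted_structure(unname(weights), hub_nodes,
                        rep(c("L", "R"), n / 2),
                        rep(1L, n), 1, "R")
}

# Precision implied by the planted weights: unit diagonal, -w off-diagonal.
planted_precision <- function(structure) {
  W <- structure$weights
  P <- -W
  diag(P) <- 1
  P
}

check_positive_definite <- function(structure) {
  ev <- eigen(planted_precision(structure), symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    abort(sprintf(
      "Implied precision matrix is not positive definite (smallest eigenvalue %.3g).",
      min(ev)))
  }
  invisible(structure)
}

#' Population correlation matrix implied by a planted structure
#'
#' Inverts the implied precision matrix and standardizes to correlation
#' scale. This is the noiseless population correlation the sample correlation
#' converges to (up to measurement-noise attenuation).
#'
#' @param structure A `planted_structure`.
#' @return Correlation matrix.
#' @export
structure_correlation <- function(structure) {
  stats::cov2cor(solve(planted_precision(structure)))
}

#' Scale one hemisphere's internal coupling
#'
#' Multiplies all within-hemisphere planted weights of the designated
#' hemisphere by `gain`, re-verifying positive definiteness.
#'
#' Because binarization keeps a fixed fraction of the strongest pairs,
#' uniformly strengthening one hemisphere's internal coupling concentrates
#' that hemisphere's retained edges inside its communities (correlations
#' saturate within communities and second-order within-community pairs
#' outrank long-range ones). The gained hemisphere therefore becomes more
#' segregated and *less* globally efficient at a fixed sparsity: `gain > 1`
#' on the left hemisphere plants rightward global-efficiency asymmetry
#' (M_R > M_L), and vice versa. This direction is a property of
#' fixed-sparsity thresholding, verified on the noiseless population
#' correlation matrix.
#'
#' @param structure A `planted_structure`.
#' @param gain Positive multiplier; 1 leaves the structure unchanged.
#' @param hemisphere `"L"` or `"R"` (default the structure's
#'   `gain_hemisphere`).
#' @return The modified `planted_structure`.
#' @export
plant_asymmetry <- function(structure, gain,
                            hemisphere = structure$gain_hemisphere) {
  if (gain <= 0) abort("gain must be positive.")
  if (!(hemisphere %in% c("L", "R"))) abort("hemisphere must be 'L' or 'R'.")
  W <- structure$weights
  idx <- which(structure$hemisphere == hemisphere)
  W[idx, idx] <- W[idx, idx] * gain
  diag(W) <- 1
  new_planted_structure(W, structure$hub_nodes, structure$hemisphere,
                        structure$community,
                        structure$hemisphere_gain * gain, hemisphere)
}

#' Configuration for a synthetic multi-group cohort
#'
#' Defaults emulate a four-group FDG-PET study: HC/AD/PDD/DLB with 22/22/18/22
#' subjects, 90 ROIs, age uniform on 55-75 years, sex Bernoulli(0.5), a mild
#' common age/sex effect on ROI means confounding raw correlations, and
#' group-specific hemispheric gains planting efficiency asymmetries
#' (symmetric controls; rightward efficiency asymmetry in AD and DLB via a
#' left-hemisphere coupling gain, leftward in PDD via a right-hemisphere
#' gain; see [plant_asymmetry()]).
#'
#' @param groups Named integer vector of group sizes.
#' @param structure Base `planted_structure` shared by all groups.
#' @param hemisphere_gain Named numeric vector, per-group gain.
#' @param gain_hemisphere Named character vector, per-group side.
#' @param seed Integer seed; fixed seed gives byte-identical cohorts.
#' @param age_range Uniform age range in years.
#' @param sex_prob Probability of sex = 1.
#' @param age_coef Effect of (age - mean age) on every ROI mean, signal units
#'   per year (scalar or per-ROI vector).
#' @param sex_coef Effect of sex = 1 on every ROI mean (scalar or vector).
#' @param noise_sd Independent measurement noise SD, signal units.
#' @param baseline Mean uptake added to all ROIs (arbitrary normalized units).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(groups = c(HC = 22, AD = 22, PDD = 18, DLB = 22),
                          structure = planted_structure(),
                          hemisphere_gain = c(HC = 1, AD = 1.05,
                                              PDD = 1.05, DLB = 1.08),
                          gain_hemisphere = c(HC = "L", AD = "L",
                                              PDD = "R", DLB = "L"),
                          seed = 1L,
                          age_range = c(55, 75),
                          sex_prob = 0.5,
                          age_coef = -0.03,
                          sex_coef = 0.2,
                          noise_sd = 0.5,
                          baseline = 10) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("groups must be a named vector of group sizes.")
  }
  if (any(groups < 5)) abort("Each group needs at least 5 subjects.")
  hemisphere_gain <- hemisphere_gain[names(groups)]
  gain_hemisphere <- gain_hemisphere[names(groups)]
  hemisphere_gain[is.na(hemisphere_gain)] <- 1
  gain_hemisphere[is.na(gain_hemisphere)] <- "R"
  names(hemisphere_gain) <- names(groups)
  names(gain_hemisphere) <- names(groups)
  cfg <- list(groups = groups, structure = structure,
              hemisphere_gain = hemisphere_gain,
              gain_hemisphere = gain_hemisphere,
              seed = as.integer(seed), age_range = age_range,
              sex_prob = sex_prob, age_coef = age_coef, sex_coef = sex_coef,
              noise_sd = noise_sd, baseline = baseline)
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic multi-group cohort
#'
#' Draws, for each group, `n` subjects whose ROI signals are multivariate
#' normal with the group's planted covariance (base structure plus the
#' group's hemispheric gain), plus linear age/sex effects and independent
#' measurement noise. The ground-truth structures are returned alongside the
#' tables so tests never re-derive them.
#'
#' @param config A [cohort_config()].
#' @return An object of class `metabnet_cohort`: list with `tables` (named
#'   list of subject x ROI tibbles), `truth` (named list of per-group
#'   `planted_structure`s) and `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(groups = c(HC = 8, AD = 8),
#'                                         structure = planted_structure(n_rois = 10),
#'                                         seed = 42))
#' names(cohort$tables)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("config must be built with cohort_config().")
  }
  st <- config$structure
  n_rois <- nrow(st$weights)
  half <- n_rois / 2L
  roi_names <- if (n_rois == 90) {
    aal90_atlas()$abbrev
  } else {
    paste0("ROI", sprintf("%02d", rep(seq_len(half), each = 2)),
           c(".L", ".R"))
  }
  age_coef <- rep_len(config$age_coef, n_rois)
  sex_coef <- rep_len(config$sex_coef, n_rois)
  mid_age <- mean(config$age_range)

  with_seed(config$seed, {
    tables <- list()
    truth <- list()
    for (g in names(config$groups)) {
      n <- config$groups[[g]]
      st_g <- if (config$hemisphere_gain[[g]] == 1) st else {
        plant_asymmetry(st, config$hemisphere_gain[[g]],
                        config$gain_hemisphere[[g]])
      }
      R <- structure_correlation(st_g)
      ch <- chol(R)
      age <- runif(n, config$age_range[1], config$age_range[2])
      sex <- rbinom(n, 1, config$sex_prob)
      signal <- matrix(rnorm(n * n_rois), n, n_rois) %*% ch
      noise <- matrix(rnorm(n * n_rois, sd = config$noise_sd), n, n_rois)
      X <- config$baseline + signal + noise +
        outer(age - mid_age, age_coef) + outer(sex, sex_coef)
      colnames(X) <- roi_names
      tab <- tibble(
        subject_id = sprintf("%s_%03d", g, seq_len(n)),
        group = g, age = age, sex = sex
      )
      tables[[g]] <- dplyr::bind_cols(tab, as_tibble(X))
      truth[[g]] <- st_g
    }
    out <- list(tables = tables, truth = truth, config = config)
    class(out) <- "metabnet_cohort"
    out
  })
}

#' Bind a cohort's group tables into one tibble
#'
#' @param cohort A `metabnet_cohort`.
#' @return A single subject x ROI tibble with all groups stacked.
#' @export
cohort_table <- function(cohort) {
  dplyr::bind_rows(cohort$tables)
}

#' Write a cohort to disk as plain text
#'
#' One CSV per group plus, per group, the ground-truth planted weight matrix
#' and a JSON sidecar with hub nodes and gains.
#'
#' @param cohort A `metabnet_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(cohort$tables)) {
    write_roi_table(cohort$tables[[g]], file.path(dir, paste0(g, ".csv")))
    st <- cohort$truth[[g]]
    utils::write.table(st$weights,
                       file.path(dir, paste0(g, "_truth_weights.txt")),
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(
      list(group = g, hub_nodes = st$hub_nodes,
           hemisphere_gain = st$hemisphere_gain,
           gain_hemisphere = st$gain_hemisphere,
           seed = cohort$config$seed),
      file.path(dir, paste0(g, "_truth.json")), auto_unbox = TRUE)
  }
  invisible(dir)
}
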