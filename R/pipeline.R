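#' Validate a pipeline configuration
#'
#' Accepts a path to a YAML/JSON file or a list, fills defaults, and collects
#' every problem at once rather than stopping at the first.
#'
#' Recognized keys: `tables` (named map group -> CSV path) or `simulate`
#' (logical, use the synthetic cohort generator), `covariates`,
#' `sparsity: {min, max, step}`, `ranking`, `null_model: {n, swaps_per_edge}`,
#' `permutation: {n, alpha, metric}`, `seed_roi`, `fdr`,
#' `asymmetry: {sparsity, reps}`, `hub: {sparsity, bi_threshold}`,
#' `control_group`, `seed`, `out_dir`.
#'
#' @param config Path or list.
#' @return List with `config` (completed configuration) and `errors`
#'   (character vector; empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    # keep single-letter keys like "n" as strings (YAML 1.1 would read them
    # as booleans) while still parsing true/false values
    config <- yaml::read_yaml(config, handlers = list(
      "bool#yes" = function(x) if (tolower(x) %in% c("true", "yes", "on")) TRUE else x,
      "bool#no" = function(x) if (tolower(x) %in% c("false", "no", "off")) FALSE else x
    ))
  }
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  defaults <- list(
    simulate = is.null(config$tables),
    covariates = c("age", "sex"),
    sparsity = list(min = 0.06, max = 0.40, step = 0.01),
    ranking = "signed",
    null_model = list(n = 100, swaps_per_edge = 10),
    permutation = list(n = 1000, alpha = 0.05, metric = "Eglob"),
    seed_roi = "MTG.R",
    fdr = 0.05,
    asymmetry = list(sparsity = 0.28, reps = 1000),
    hub = list(sparsity = 0.28, bi_threshold = 1.5),
    control_group = "HC",
    seed = 1L,
    out_dir = "metabnet_output"
  )
  config <- utils::modifyList(defaults, config)

  if (!is.null(config$tables)) {
    if (is.null(names(config$tables)) || any(names(config$tables) == "")) {
      note("'tables' must be a named map of group -> file path.")
    }
    for (p in unlist(config$tables)) {
      if (!file.exists(p)) note(sprintf("Input file not found: %s", p))
    }
  } else if (!isTRUE(config$simulate)) {
    note("Either 'tables' or 'simulate: true' must be given.")
  }
  sp <- config$sparsity
  if (sp$min > sp$max) note("sparsity.min exceeds sparsity.max.")
  if (sp$min <= 0 || sp$max >= 1) note("sparsity bounds must lie in (0, 1).")
  if (sp$step <= 0) note("sparsity.step must be positive.")
  if (!(config$ranking %in% c("signed", "absolute"))) {
    note("ranking must be 'signed' or 'absolute'.")
  }
  if (config$permutation$n < 100) note("permutation.n must be >= 100.")
  if (config$permutation$alpha <= 0 || config$permutation$alpha >= 1) {
    note("permutation.alpha must be in (0, 1).")
  }
  if (!(config$permutation$metric %in%
        c("C", "L", "Eglob", "Eloc", "gamma", "lambda", "sigma"))) {
    note("permutation.metric is not a recognized network metric.")
  }
  if (config$fdr <= 0 || config$fdr > 1) note("fdr must be in (0, 1].")
  if (config$asymmetry$reps < 100) note("asymmetry.reps must be >= 100.")
  if (config$hub$sparsity <= 0 || config$hub$sparsity >= 1) {
    note("hub.sparsity must be in (0, 1).")
  }
  list(config = config, errors = errors)
}

#' Run the full metabolic-network analysis pipeline
#'
#' Stage order: load or simulate group tables; per-group partial-correlation
#' network, sparsity sweep, metric curves and hub table; per disease-vs-control
#' pair, permutation comparison and seed-based correlation analysis; per
#' group, hemispheric asymmetry; everything written as plain-text tables plus
#' a JSON manifest. The master seed deterministically derives each stage's
#' seed, so a rerun with the same configuration is byte-identical.
#'
#' @param config Path, list, or validated configuration.
#' @param out_dir Output directory (overrides the configuration's).
#' @return Invisible list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  v <- validate_config(config)
  if (length(v$errors) > 0) {
    abort(paste0("Invalid configuration:\n",
                 paste0("- ", v$errors, collapse = "\n")))
  }
  cfg <- v$config
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- seq(cfg$sparsity$min, cfg$sparsity$max, by = cfg$sparsity$step)
  stage_seeds <- derive_seeds(cfg$seed, 4)

  log_stage <- function(fmt, ...) {
    message(sprintf("[metabnet] %s", sprintf(fmt, ...)))
  }

  # --- input stage ---------------------------------------------------------
  if (!is.null(cfg$tables)) {
    log_stage("loading %d group table(s)", length(cfg$tables))
    tables <- purrr::imap(cfg$tables, function(p, g) {
      tab <- read_roi_table(p)
      tab$group <- g
      tab
    })
  } else {
    log_stage("simulating synthetic cohort (seed %d)", stage_seeds[1])
    cohort <- generate_cohort(cohort_config(seed = stage_seeds[1]))
    write_cohort(cohort, file.path(cfg$out_dir, "cohort"))
    tables <- cohort$tables
  }
  groups <- names(tables)

  # --- per-group networks, curves, hubs ------------------------------------
  log_stage("building networks for groups: %s", paste(groups, collapse = ", "))
  networks <- purrr::map(tables, partial_correlation,
                         covariates = cfg$covariates)
  curves <- purrr::imap_dfr(networks, function(pc, g) {
    stack <- sparsity_sweep(pc, grid, cfg$ranking)
    metric_curve(stack, n_null = cfg$null_model$n,
                 swaps_per_edge = cfg$null_model$swaps_per_edge,
                 seed = stage_seeds[2], group = g)
  })
  hubs <- purrr::imap_dfr(networks, function(pc, g) {
    dplyr::mutate(hub_table(pc, cfg$hub$sparsity, cfg$hub$bi_threshold,
                            cfg$ranking),
                  group = g, .before = 1)
  })
  for (g in groups) {
    write_matrix(networks[[g]],
                 file.path(cfg$out_dir, sprintf("pcor_%s.csv", g)))
  }
  utils::write.csv(curves, file.path(cfg$out_dir, "metric_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(hubs, file.path(cfg$out_dir, "hub_tables.csv"),
                   row.names = FALSE)

  # --- group comparisons ---------------------------------------------------
  ctrl <- cfg$control_group
  pairs <- setdiff(groups, ctrl)
  comparisons <- list()
  seed_results <- list()
  if (ctrl %in% groups) {
    for (g in pairs) {
      log_stage("permutation test %s vs %s (%d permutations)", g, ctrl,
                cfg$permutation$n)
      comparisons[[g]] <- permutation_test(
        tables[[g]], tables[[ctrl]], metric = cfg$permutation$metric,
        grid = grid, n_perm = cfg$permutation$n,
        alpha = cfg$permutation$alpha, seed = stage_seeds[3],
        covariates = cfg$covariates, ranking = cfg$ranking,
        n_null = cfg$null_model$n,
        swaps_per_edge = cfg$null_model$swaps_per_edge)
      seed_results[[g]] <- seed_comparison(tables[[g]], tables[[ctrl]],
                                           seed_roi = cfg$seed_roi,
                                           q_level = cfg$fdr)
    }
    perm_out <- purrr::imap_dfr(comparisons, function(x, g) {
      dplyr::mutate(tidy(x), group = g, control = ctrl,
                    metric = attr(x, "metric"), .before = 1)
    })
    utils::write.csv(perm_out,
                     file.path(cfg$out_dir, "permutation_results.csv"),
                     row.names = FALSE)
    seed_out <- purrr::imap_dfr(seed_results, function(x, g) {
      dplyr::mutate(as_tibble(x), group = g, control = ctrl, .before = 1)
    })
    utils::write.csv(seed_out, file.path(cfg$out_dir, "seed_results.csv"),
                     row.names = FALSE)
  }

  # --- hemispheric asymmetry ----------------------------------------------
  log_stage("asymmetry analysis (%d replicates per group)",
            cfg$asymmetry$reps)
  asymmetry <- purrr::map(tables, within_group_test,
                          covariates = cfg$covariates,
                          sparsity = cfg$asymmetry$sparsity,
                          n_rep = cfg$asymmetry$reps,
                          seed = stage_seeds[4],
                          ranking = cfg$ranking)
  asym_out <- purrr::map_dfr(asymmetry, tidy)
  utils::write.csv(asym_out, file.path(cfg$out_dir, "asymmetry_results.csv"),
                   row.names = FALSE)

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package = "metabnet",
    version = as.character(utils::packageVersion("metabnet")),
    seed = cfg$seed,
    stage_seeds = stage_seeds,
    groups = groups,
    config = cfg[setdiff(names(cfg), "tables")],
    outputs = list.files(cfg$out_dir, recursive = TRUE)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(tables = tables, networks = networks, curves = curves,
                 hubs = hubs, comparisons = comparisons,
                 seed_results = seed_results, asymmetry = asymmetry,
                 manifest = manifest))
}
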