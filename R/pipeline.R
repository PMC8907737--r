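#' Configure an end-to-end risk-grading run
#'
#' A run takes either four input files (sampling, consumption, limits,
#' toxicology) or a synthetic [scenario_config()], never both. All
#' clustering randomness flows from `seed`; a scenario's generators use the
#' scenario's own seed.
#'
#' @param sampling,consumption,limits,tox Input file paths (CSV; `tox` may be
#'   YAML or CSV).
#' @param scenario A [scenario_config()] used instead of file inputs.
#' @param lod_scope Scope of the GEMS/FOOD substitution rule, `"global"` or
#'   `"per_combination"`.
#' @param quantile_type Quantile estimator for P50/P95 (default 7).
#' @param parameters Kernel width grid (default `1:10`).
#' @param ks Cluster count grid (default `3:7`; values below 2 are invalid
#'   because the CH index is undefined there).
#' @param seed Root seed for the clustering stage.
#' @param mode Eigendecomposition mode, see [spectral_cluster()].
#' @param moe_cap Margin-of-exposure sentinel cap.
#' @param output_dir Optional directory for all output files.
#' @return A `run_config` object (named list).
#' @export
run_config <- function(sampling = NULL, consumption = NULL, limits = NULL,
                       tox = NULL, scenario = NULL,
                       lod_scope = "global", quantile_type = 7,
                       parameters = 1:10, ks = 3:7, seed = 0L,
                       mode = "njw", moe_cap = 1e6, output_dir = NULL) {
  cfg <- structure(
    list(sampling = sampling, consumption = consumption, limits = limits,
         tox = tox, scenario = scenario, lod_scope = lod_scope,
         quantile_type = quantile_type, parameters = parameters, ks = ks,
         seed = as.integer(seed), mode = mode, moe_cap = moe_cap,
         output_dir = output_dir),
    class = "run_config"
  )
  cfg
}

#' Validate a run configuration
#'
#' Returns problems instead of throwing, so configurations can be checked
#' interactively. An empty character vector means the configuration is
#' runnable.
#'
#' @param config A [run_config()].
#' @return Character vector of problems, each naming the offending field.
#' @export
validate_run_config <- function(config) {
  problems <- character(0)
  has_files <- !is.null(config$sampling) || !is.null(config$consumption) ||
    !is.null(config$limits) || !is.null(config$tox)
  has_scenario <- !is.null(config$scenario)
  if (has_files && has_scenario) {
    problems <- c(problems, "inputs: supply either file paths or a scenario, not both")
  }
  if (!has_files && !has_scenario) {
    problems <- c(problems, "inputs: no file paths and no scenario supplied")
  }
  if (has_files) {
    for (field in c("sampling", "consumption", "limits", "tox")) {
      if (is.null(config[[field]])) {
        problems <- c(problems, sprintf("%s: file path missing", field))
      } else if (!file.exists(config[[field]])) {
        problems <- c(problems, sprintf("%s: file does not exist: %s",
                                        field, config[[field]]))
      }
    }
  }
  if (has_scenario && !inherits(config$scenario, "scenario_config")) {
    problems <- c(problems, "scenario: not a scenario_config object")
  }
  if (length(config$parameters) < 1) {
    problems <- c(problems, "parameters: kernel width grid is empty")
  } else if (any(config$parameters <= 0)) {
    problems <- c(problems, "parameters: kernel widths must be > 0")
  }
  if (length(config$ks) < 1) {
    problems <- c(problems, "ks: cluster count grid is empty")
  } else if (any(config$ks < 2)) {
    problems <- c(problems, "ks: cluster counts below 2 are invalid (CH index undefined)")
  }
  if (!config$lod_scope %in% c("global", "per_combination")) {
    problems <- c(problems, "lod_scope: must be 'global' or 'per_combination'")
  }
  if (!config$mode %in% c("njw", "unnormalized", "affinity")) {
    problems <- c(problems, "mode: must be 'njw', 'unnormalized' or 'affinity'")
  }
  problems
}

#' Run the full risk-grading pipeline
#'
#' Executes ingest (or synthetic generation), non-detect substitution,
#' per-combination summaries, the three risk indexes, the CH-scored spectral
#' clustering grid search, and risk-level assignment. When
#' `config$output_dir` is set, writes `indices.csv`, `ch_scores.csv`,
#' `clusters.csv`, `levels.csv` (region-by-category level matrix),
#' `high_risk.csv` and `summary.json` there. Deterministic under a fixed
#' configuration.
#'
#' @param config A [run_config()]; validated before running.
#' @return A `lead_risk_run` object: list with `config`, `features`, `stats`,
#'   `grid` (the [ch_grid_search()] fit), `level_map`, `levels` (tibble with
#'   per-combination `risk_level` and `composite_score`), `proportions`,
#'   `high_risk`, and `report` (stage record counts, selected parameter and
#'   k, package version, seed). Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
run_pipeline <- function(config) {
  problems <- validate_run_config(config)
  if (length(problems) > 0) {
    abort(paste0("invalid run configuration:\n", paste("-", problems, collapse = "\n")),
          class = "leadrisk_config_error")
  }

  if (!is.null(config$scenario)) {
    sampling <- generate_sampling_table(config$scenario)
    consumption <- generate_consumption_table(config$scenario)
    limits <- generate_limit_table(config$scenario)
    tox <- config$scenario$tox
  } else {
    sampling <- read_sampling_csv(config$sampling)
    consumption <- read_consumption_csv(config$consumption)
    limits <- read_limits_csv(config$limits)
    tox <- read_tox_config(config$tox)
  }

  substituted <- substitute_nondetects(sampling, scope = config$lod_scope)
  stats <- summarize_combinations(substituted, quantile_type = config$quantile_type)
  features <- build_feature_matrix(stats, consumption, limits, tox,
                                   moe_cap = config$moe_cap)
  grid <- ch_grid_search(features, parameters = config$parameters,
                         ks = config$ks, seed = config$seed,
                         mode = config$mode)

  level_map <- order_clusters_by_risk(grid$Z, grid$labels)
  assignment <- dplyr::mutate(features[c("region", "category")],
                              cluster = grid$labels)
  composite <- grid$Z[, 1] + grid$Z[, 2] - grid$Z[, 3]
  levels_tbl <- assign_levels(assignment, level_map) |>
    dplyr::left_join(
      dplyr::mutate(features[c("region", "category")], composite_score = composite),
      by = c("region", "category")
    )
  proportions <- level_proportions(levels_tbl)
  high_risk <- rank_high_risk(levels_tbl) |>
    dplyr::left_join(
      dplyr::left_join(stats[c("region", "category", "max")], limits,
                       by = "category"),
      by = c("region", "category")
    ) |>
    dplyr::mutate(exceedance = exceedance_factor(.data$max, .data$limit_mg_per_kg)) |>
    dplyr::select("region", "category", "risk_level", "composite_score",
                  "max", "exceedance")

  report <- list(
    config = config,
    n_samples = nrow(sampling),
    n_nondetects = sum(sampling$detected == 0L),
    n_combinations = nrow(features),
    selected_parameter = grid$best_parameter,
    selected_k = grid$best_k,
    best_ch_score = grid$best_score,
    package_version = as.character(utils::packageVersion("leadrisk")),
    seed = config$seed
  )

  run <- structure(
    list(config = config, stats = stats, features = features, grid = grid,
         level_map = level_map, levels = levels_tbl, proportions = proportions,
         high_risk = high_risk, report = report),
    class = "lead_risk_run"
  )
  if (!is.null(config$output_dir)) write_run_outputs(run, config$output_dir)
  run
}

write_run_outputs <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_indices_csv(run$features, file.path(dir, "indices.csv"))
  readr::write_csv(run$grid$scores, file.path(dir, "ch_scores.csv"))
  readr::write_csv(
    dplyr::mutate(run$features[c("region", "category")],
                  cluster_id = run$grid$labels),
    file.path(dir, "clusters.csv")
  )
  run$levels |>
    dplyr::select("region", "category", "risk_level") |>
    tidyr::pivot_wider(names_from = "category", values_from = "risk_level") |>
    readr::write_csv(file.path(dir, "levels.csv"))
  readr::write_csv(run$high_risk, file.path(dir, "high_risk.csv"))
  jsonlite::write_json(
    list(
      selected_parameter = run$report$selected_parameter,
      selected_k = run$report$selected_k,
      best_ch_score = run$report$best_ch_score,
      per_level = run$proportions$per_level,
      grouped = run$proportions$grouped,
      ch_scores_file = "ch_scores.csv",
      seed = run$report$seed
    ),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @export
print.lead_risk_run <- function(x, ...) {
  cat(sprintf(
    "<lead_risk_run> %d combinations from %d samples; selected parameter %g, k = %d (CH %.4g)\n",
    x$report$n_combinations, x$report$n_samples,
    x$report$selected_parameter, x$report$selected_k, x$report$best_ch_score
  ))
  g <- x$proportions$grouped
  cat(sprintf("  %s: %.2f%%   %s: %.2f%%   %s: %.2f%%\n",
              g$group[1], g$percent[1], g$group[2], g$percent[2],
              g$group[3], g$percent[3]))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x,object A `lead_risk_run` object.
#' @param ... Unused.
#' @method tidy lead_risk_run
#' @export
tidy.lead_risk_run <- function(x, ...) {
  dplyr::left_join(x$features, x$levels, by = c("region", "category"))
}

#' @rdname run_pipeline
#' @method glance lead_risk_run
#' @export
glance.lead_risk_run <- function(x, ...) {
  tibble::tibble(
    n_samples = x$report$n_samples,
    n_combinations = x$report$n_combinations,
    selected_parameter = x$report$selected_parameter,
    selected_k = x$report$selected_k,
    best_ch_score = x$report$best_ch_score,
    pct_levels_1_2 = x$proportions$grouped$percent[1],
    pct_levels_4_5 = x$proportions$grouped$percent[3]
  )
}

#' @rdname run_pipeline
#' @method autoplot lead_risk_run
#' @export
autoplot.lead_risk_run <- function(object, ...) {
  ggplot2::ggplot(object$levels,
                  ggplot2::aes(x = .data$category, y = .data$region,
                               fill = factor(.data$risk_level))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_brewer(palette = "YlOrRd", name = "risk level") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Risk level by region and vegetable category") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
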