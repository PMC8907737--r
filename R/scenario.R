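#' The nine vegetable categories used by the national monitoring scheme
#'
#' Category names matching the Chinese national food-safety limit standard for
#' lead: Brassica and leafy vegetables are limited at 0.3 mg/kg, legume
#' vegetables at 0.2 mg/kg, and all other categories at 0.1 mg/kg.
#'
#' @format Character vector of length 9.
#' @export
vegetable_categories <- c(
  "leafy", "root and potato", "melon", "brassica", "solanaceous",
  "legume", "bean sprouts", "fresh edible fungus", "bulb"
)

default_tier_params <- function(n_tiers) {
  # Tier medians step arithmetically across the 0.1 mg/kg limit (pollution
  # ratios 0.2..2.0) and the per-tier log-sd shrinks where the corresponding
  # index is large, so every planted tier has comparable within-tier spread
  # after standardisation; consumption means are back-solved so the tier
  # median margins of exposure step evenly from ~7 down to 1. Adjacent tier
  # log-means are separated by >= 3 of the larger adjacent log-sd.
  medians <- c(0.02, 0.065, 0.11, 0.155, 0.20)
  log_sd <- c(0.04, 0.08, 0.10, 0.06, 0.04)
  moe_target <- c(7, 5.5, 4, 2.5, 1)
  if (n_tiers > 5L) abort("default tier parameters cover at most 5 tiers; supply `tier_params`")
  i <- seq_len(n_tiers)
  tibble::tibble(
    tier = i,
    log_mean = log(medians[i]),
    log_sd = log_sd[i],
    # fc such that BMDL01 / (fc * median / W * 1000) = moe_target
    fc_mean_kg_per_day = 0.6 * 60 / 1000 / (moe_target[i] * medians[i])
  )
}

#' Define a synthetic monitoring scenario with planted risk tiers
#'
#' Describes a complete synthetic study: a grid of regions and vegetable
#' categories, a planted risk tier for every region-category combination,
#' lognormal concentration parameters and a gamma consumption mean per tier,
#' a single limit of detection, per-category regulatory limits, and the
#' toxicological reference values. The generators
#' ([generate_sampling_table()], [generate_consumption_table()],
#' [generate_limit_table()]) are deterministic given `seed`.
#'
#' @param n_regions Number of regions (>= 2).
#' @param n_categories Number of vegetable categories (>= 1).
#' @param categories Category names: `NULL` (generic `category_01`, ...,
#'   sharing the 0.1 mg/kg "other vegetables" limit so a planted
#'   concentration tier is also a coherent pollution tier), `"national"`
#'   (the nine [vegetable_categories] with the 0.3/0.2/0.1 limit preset),
#'   or an explicit character vector.
#' @param samples_per_combination Samples drawn per region-category
#'   combination (>= 2).
#' @param n_tiers Number of planted risk tiers (used when `tier_assignment`
#'   is `NULL`).
#' @param tier_assignment Optional tibble with columns `region`, `category`,
#'   `tier` giving the planted tier of every combination. Default: tiers
#'   assigned round-robin over the region-major combination grid.
#' @param tier_params Optional tibble with columns `tier`, `log_mean`,
#'   `log_sd` (lognormal concentration parameters, mg/kg scale) and
#'   `fc_mean_kg_per_day` (mean daily consumption). Default: tier
#'   concentration medians 0.02, 0.065, 0.11, 0.155, 0.20 mg/kg with
#'   per-tier log-sd 0.04 to 0.10, and consumption means back-solved so the
#'   tier median margins of exposure step evenly from about 7 down to 1.
#' @param lod Limit of detection in mg/kg (default 0.03, which censors the
#'   lowest default tier entirely, a 20% non-detect fraction overall); draws
#'   below it are recorded as non-detects. Use 0 for no censoring.
#' @param limits Optional tibble `category`, `limit_mg_per_kg`. Default: the
#'   national limit preset (0.3 mg/kg Brassica/leafy, 0.2 legume, 0.1 other).
#' @param fc_scale Multiplier applied to all consumption means.
#' @param fc_shape Gamma shape of the consumption draws (default 2500, a 2%
#'   coefficient of variation around the tier mean).
#' @param tox Named list with `rfd_ug_per_kg_day`, `bmdl01_ug_per_kg_day`,
#'   `body_weight_kg`. Defaults to the lead reference values 3.5, 0.6, 60.
#' @param seed Integer root seed for all generators.
#' @return An object of class `scenario_config` (a named list).
#' @examples
#' cfg <- scenario_config(n_regions = 4, samples_per_combination = 5)
#' generate_sampling_table(cfg)
#' @export
scenario_config <- function(n_regions = 20,
                            n_categories = 9,
                            categories = NULL,
                            samples_per_combination = 30,
                            n_tiers = 5,
                            tier_assignment = NULL,
                            tier_params = NULL,
                            lod = 0.03,
                            limits = NULL,
                            fc_scale = 1,
                            fc_shape = 2500,
                            tox = list(rfd_ug_per_kg_day = 3.5,
                                       bmdl01_ug_per_kg_day = 0.6,
                                       body_weight_kg = 60),
                            seed = 1L) {
  if (n_regions < 2) abort("`n_regions` must be >= 2", class = "leadrisk_config_error")
  if (n_categories < 1) abort("`n_categories` must be >= 1", class = "leadrisk_config_error")
  if (samples_per_combination < 2) {
    abort("`samples_per_combination` must be >= 2", class = "leadrisk_config_error")
  }
  if (lod < 0) abort("`lod` must be >= 0", class = "leadrisk_config_error")
  if (fc_scale <= 0) abort("`fc_scale` must be > 0", class = "leadrisk_config_error")
  if (fc_shape <= 0) abort("`fc_shape` must be > 0", class = "leadrisk_config_error")

  regions <- sprintf("region_%02d", seq_len(n_regions))
  if (is.null(categories)) {
    categories <- sprintf("category_%02d", seq_len(n_categories))
  } else if (identical(categories, "national")) {
    categories <- vegetable_categories
  }
  if (length(categories) != n_categories) {
    abort("`categories` length must equal `n_categories`",
          class = "leadrisk_config_error")
  }

  if (is.null(tier_params)) tier_params <- default_tier_params(n_tiers)
  tier_params <- tibble::as_tibble(tier_params)
  stopifnot(all(c("tier", "log_mean", "log_sd", "fc_mean_kg_per_day") %in% names(tier_params)))
  if (any(tier_params$log_sd <= 0) || any(tier_params$fc_mean_kg_per_day <= 0)) {
    abort("tier log-sd and consumption means must be strictly positive",
          class = "leadrisk_config_error")
  }

  if (is.null(tier_assignment)) {
    grid <- tidyr::expand_grid(region = regions, category = categories)
    tier_assignment <- dplyr::mutate(
      grid, tier = ((dplyr::row_number() - 1L) %% nrow(tier_params)) + 1L
    )
  }
  tier_assignment <- tibble::as_tibble(tier_assignment)
  stopifnot(all(c("region", "category", "tier") %in% names(tier_assignment)))
  full <- tidyr::expand_grid(region = regions, category = categories)
  if (nrow(dplyr::anti_join(full, tier_assignment, by = c("region", "category"))) > 0 ||
      anyDuplicated(tier_assignment[c("region", "category")]) > 0) {
    abort("`tier_assignment` must cover every combination exactly once",
          class = "leadrisk_config_error")
  }
  if (!all(tier_assignment$tier %in% tier_params$tier)) {
    abort("every assigned tier needs a row in `tier_params`",
          class = "leadrisk_config_error")
  }

  if (is.null(limits)) {
    lims <- if (all(categories %in% vegetable_categories)) {
      limit_preset(categories)
    } else {
      rep(0.1, length(categories))   # generic categories: the "other" limit
    }
    limits <- tibble::tibble(category = categories, limit_mg_per_kg = lims)
  }
  limits <- tibble::as_tibble(limits)
  if (any(limits$limit_mg_per_kg <= 0)) {
    abort("regulatory limits must be strictly positive", class = "leadrisk_config_error")
  }
  if (any(vapply(tox, function(v) !is.numeric(v) || v <= 0, logical(1)))) {
    abort("toxicological reference values must be strictly positive",
          class = "leadrisk_config_error")
  }

  structure(
    list(
      regions = regions, categories = categories,
      samples_per_combination = as.integer(samples_per_combination),
      tier_assignment = tier_assignment, tier_params = tier_params,
      lod = lod, limits = limits, fc_scale = fc_scale, fc_shape = fc_shape,
      tox = tox,
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %d regions x %d categories, %d samples/combination, %d tiers, LOD %g mg/kg, seed %d\n",
    length(x$regions), length(x$categories), x$samples_per_combination,
    nrow(x$tier_params), x$lod, x$seed
  ))
  invisible(x)
}

#' Planted tier labels of a scenario
#'
#' @param config A [scenario_config()].
#' @return Tibble with columns `region`, `category`, `tier`, one row per
#'   combination, region-major order.
#' @export
planted_tiers <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  dplyr::arrange(config$tier_assignment, .data$region, .data$category)
}

#' National regulatory lead limit for a vegetable category
#'
#' Applies the national limit scheme: 0.3 mg/kg for Brassica and leafy
#' vegetables, 0.2 mg/kg for legume vegetables, 0.1 mg/kg for all other
#' monitored categories.
#'
#' @param category Character vector of category names (see
#'   [vegetable_categories]).
#' @return Numeric vector of limits in mg/kg.
#' @export
limit_preset <- function(category) {
  unknown <- setdiff(category, vegetable_categories)
  if (length(unknown) > 0) {
    abort(paste0("unknown vegetable categories for the limit preset: ",
                 paste(unknown, collapse = ", ")),
          class = "leadrisk_config_error")
  }
  dplyr::case_when(
    category %in% c("brassica", "leafy") ~ 0.3,
    category == "legume" ~ 0.2,
    .default = 0.1
  )
}

#' Simulate a censored lead sampling table
#'
#' Draws `samples_per_combination` lognormal concentrations for every
#' region-category combination using its planted tier's parameters. Draws
#' below the scenario LOD are recorded as non-detects with the concentration
#' blanked, emulating left-censored monitoring data.
#'
#' @param config A [scenario_config()].
#' @return Tibble with columns `region`, `category`, `concentration_mg_per_kg`
#'   (`NA` for non-detects), `detected` (0/1), `lod_mg_per_kg`.
#' @export
generate_sampling_table <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  combos <- planted_tiers(config) |>
    dplyr::left_join(config$tier_params, by = "tier")
  m <- config$samples_per_combination
  withr::with_seed(config$seed, {
    tab <- combos |>
      dplyr::mutate(
        draw = purrr::map2(.data$log_mean, .data$log_sd,
                           ~ rlnorm(m, meanlog = .x, sdlog = .y))
      ) |>
      tidyr::unnest("draw")
  })
  tab |>
    dplyr::mutate(
      detected = as.integer(.data$draw >= config$lod),
      concentration_mg_per_kg = dplyr::if_else(.data$detected == 1L, .data$draw, NA_real_),
      lod_mg_per_kg = config$lod
    ) |>
    dplyr::select("region", "category", "concentration_mg_per_kg",
                  "detected", "lod_mg_per_kg")
}

#' Simulate a mean daily consumption table
#'
#' One mean daily consumption (kg/day) per region-category combination, drawn
#' from a gamma distribution (shape 4) whose mean is the planted tier's
#' consumption mean times `fc_scale`. Strictly positive by construction.
#'
#' @param config A [scenario_config()].
#' @return Tibble with columns `region`, `category`, `fc_kg_per_day`.
#' @export
generate_consumption_table <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  combos <- planted_tiers(config) |>
    dplyr::left_join(config$tier_params, by = "tier")
  shape <- config$fc_shape
  withr::with_seed(config$seed + 1L, {
    fc <- rgamma(nrow(combos), shape = shape,
                 scale = combos$fc_mean_kg_per_day * config$fc_scale / shape)
  })
  combos |>
    dplyr::mutate(fc_kg_per_day = pmax(fc, .Machine$double.eps)) |>
    dplyr::select("region", "category", "fc_kg_per_day")
}

#' Regulatory limit table of a scenario
#'
#' @param config A [scenario_config()].
#' @return Tibble with columns `category`, `limit_mg_per_kg`.
#' @export
generate_limit_table <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  config$limits
}

#' Write all scenario inputs as CSV/YAML files
#'
#' Writes `sampling.csv`, `consumption.csv`, `limits.csv`, `tox.yaml` in the
#' schemas read by [read_sampling_csv()] and friends, plus
#' `planted_tiers.csv`, a sidecar with the planted tier of every combination
#' for validation harnesses.
#'
#' @param config A [scenario_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_scenario <- function(config, dir) {
  stopifnot(inherits(config, "scenario_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    sampling = file.path(dir, "sampling.csv"),
    consumption = file.path(dir, "consumption.csv"),
    limits = file.path(dir, "limits.csv"),
    tox = file.path(dir, "tox.yaml"),
    tiers = file.path(dir, "planted_tiers.csv")
  )
  readr::write_csv(generate_sampling_table(config), paths$sampling, na = "")
  readr::write_csv(generate_consumption_table(config), paths$consumption)
  readr::write_csv(generate_limit_table(config), paths$limits)
  yaml::write_yaml(config$tox, paths$tox)
  readr::write_csv(planted_tiers(config), paths$tiers)
  invisible(paths)
}
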