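check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "leadrisk_schema_error")
  }
  extra <- setdiff(names(df), required)
  if (length(extra) > 0) {
    warn(sprintf("%s: ignoring unknown column(s): %s", path,
                 paste(extra, collapse = ", ")))
  }
  df[required]
}

check_numeric <- function(df, cols, path) {
  for (col in cols) {
    bad <- which(!is.na(df[[col]]) & is.na(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad) > 0) {
      abort(sprintf("%s: non-numeric value in column '%s', row %d",
                    path, col, bad[1]),
            class = "leadrisk_schema_error")
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Read a lead sampling table
#'
#' Expects columns `region`, `category`, `concentration_mg_per_kg` (empty for
#' non-detects), `detected` (0/1), `lod_mg_per_kg`. Unknown columns are
#' dropped with a warning.
#'
#' @param path CSV file path.
#' @return Tibble of sampling records.
#' @export
read_sampling_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  df <- check_columns(df, c("region", "category", "concentration_mg_per_kg",
                            "detected", "lod_mg_per_kg"), path)
  df <- check_numeric(df, c("concentration_mg_per_kg", "detected", "lod_mg_per_kg"), path)
  df$detected <- as.integer(df$detected)
  bad <- which(df$lod_mg_per_kg <= 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: non-positive LOD in row %d", path, bad[1]),
          class = "leadrisk_schema_error")
  }
  bad <- which(df$detected == 1L & (is.na(df$concentration_mg_per_kg) |
                                      df$concentration_mg_per_kg < 0))
  if (length(bad) > 0) {
    abort(sprintf("%s: detected record without a valid concentration in row %d",
                  path, bad[1]),
          class = "leadrisk_schema_error")
  }
  tibble::as_tibble(df)
}

#' Read a mean daily consumption table
#'
#' Expects columns `region`, `category`, `fc_kg_per_day` (all entries > 0).
#'
#' @param path CSV file path.
#' @return Tibble mapping region and category to mean daily consumption.
#' @export
read_consumption_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  df <- check_columns(df, c("region", "category", "fc_kg_per_day"), path)
  df <- check_numeric(df, "fc_kg_per_day", path)
  bad <- which(is.na(df$fc_kg_per_day) | df$fc_kg_per_day <= 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: non-positive consumption in row %d, column 'fc_kg_per_day'",
                  path, bad[1]),
          class = "leadrisk_schema_error")
  }
  tibble::as_tibble(df)
}

#' Read a regulatory limit table
#'
#' Expects columns `category`, `limit_mg_per_kg` (all limits > 0).
#'
#' @param path CSV file path.
#' @return Tibble mapping category to its lead limit in mg/kg.
#' @export
read_limits_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  df <- check_columns(df, c("category", "limit_mg_per_kg"), path)
  df <- check_numeric(df, "limit_mg_per_kg", path)
  bad <- which(is.na(df$limit_mg_per_kg) | df$limit_mg_per_kg <= 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: non-positive limit in row %d, column 'limit_mg_per_kg'",
                  path, bad[1]),
          class = "leadrisk_schema_error")
  }
  tibble::as_tibble(df)
}

#' Read toxicological reference values
#'
#' Accepts a YAML file (keys `rfd_ug_per_kg_day`, `bmdl01_ug_per_kg_day`,
#' `body_weight_kg`) or a two-column CSV (`key`, `value`) with the same keys.
#' For lead the reference values are RfD 3.5 ug/(kg day), BMDL01
#' 0.6 ug/(kg day), body weight 60 kg.
#'
#' @param path YAML or CSV file path.
#' @return Named list with elements `rfd_ug_per_kg_day`,
#'   `bmdl01_ug_per_kg_day`, `body_weight_kg`.
#' @export
read_tox_config <- function(path) {
  keys <- c("rfd_ug_per_kg_day", "bmdl01_ug_per_kg_day", "body_weight_kg")
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    df <- check_columns(df, c("key", "value"), path)
    raw <- as.list(setNames(as.numeric(df$value), df$key))
  }
  missing <- setdiff(keys, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing toxicology key(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "leadrisk_schema_error")
  }
  out <- lapply(raw[keys], as.numeric)
  if (any(vapply(out, function(v) is.na(v) || v <= 0, logical(1)))) {
    abort(sprintf("%s: toxicology values must be strictly positive", path),
          class = "leadrisk_schema_error")
  }
  out
}

#' Substitute non-detect concentrations by the GEMS/FOOD rule
#'
#' Implements the WHO GEMS/FOOD low-level substitution rule for left-censored
#' residue data: when the proportion of non-detects over the chosen scope is
#' below 60%, every non-detect is replaced by LOD/2; at or above 60%, by the
#' LOD itself. Detected records are unchanged; the returned table has a
#' concentration for every record, so downstream summaries are well defined.
#'
#' @param sampling Sampling tibble as returned by [read_sampling_csv()] or
#'   [generate_sampling_table()].
#' @param scope `"global"` (one proportion over the whole table, the default)
#'   or `"per_combination"` (proportion computed within each region-category
#'   group).
#' @return The sampling tibble with `concentration_mg_per_kg` filled in for
#'   all records.
#' @export
substitute_nondetects <- function(sampling, scope = c("global", "per_combination")) {
  scope <- match.arg(scope)
  bad <- which(sampling$detected == 0L & (is.na(sampling$lod_mg_per_kg) |
                                            sampling$lod_mg_per_kg <= 0))
  if (length(bad) > 0) {
    abort(sprintf("non-detect record without a positive LOD in row %d", bad[1]),
          class = "leadrisk_data_error")
  }
  fill <- function(df) {
    nd <- df$detected == 0L
    if (!any(nd)) return(df)
    factor <- if (mean(nd) < 0.6) 0.5 else 1
    df$concentration_mg_per_kg[nd] <- df$lod_mg_per_kg[nd] * factor
    df
  }
  if (scope == "global") {
    fill(sampling)
  } else {
    sampling |>
      dplyr::group_by(.data$region, .data$category) |>
      dplyr::group_modify(~ fill(.x)) |>
      dplyr::ungroup() |>
      dplyr::select(dplyr::all_of(names(sampling)))
  }
}

#' Summarise lead content per region-category combination
#'
#' Computes sample count, mean, median (P50), 95th percentile (P95), maximum
#' and non-detect fraction for every region-category combination. Quantiles
#' use linear interpolation between order statistics at rank `p * (n - 1)`
#' (quantile type 7). Substitution must already have been applied so that
#' every record carries a concentration.
#'
#' @param sampling Substituted sampling tibble (no missing concentrations).
#' @param quantile_type Quantile estimator passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return Tibble with columns `region`, `category`, `n`, `mean`, `p50`,
#'   `p95`, `max`, `nd_fraction`, one row per combination.
#' @export
summarize_combinations <- function(sampling, quantile_type = 7) {
  if (anyNA(sampling$concentration_mg_per_kg)) {
    abort("missing concentrations: apply substitute_nondetects() first",
          class = "leadrisk_data_error")
  }
  sampling |>
    dplyr::group_by(.data$region, .data$category) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$concentration_mg_per_kg),
      p50 = quantile(.data$concentration_mg_per_kg, 0.5, type = quantile_type,
                     names = FALSE),
      p95 = quantile(.data$concentration_mg_per_kg, 0.95, type = quantile_type,
                     names = FALSE),
      max = max(.data$concentration_mg_per_kg),
      nd_fraction = mean(.data$detected == 0L),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$region, .data$category)
}
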