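#' Order clusters from lowest to highest risk
#'
#' Each cluster receives a composite risk score: the mean over its members of
#' `z(pc) + z(hi) - z(moe)` on the standardised feature matrix. Higher
#' pollution index and hazard index mean more risk; a higher margin of
#' exposure is protective, hence the negation. Clusters sorted ascending by
#' composite score receive levels 1 (lowest risk) to k (highest). Ties are
#' broken by larger cluster size first, then smaller cluster id.
#'
#' @param Z Standardised feature matrix with columns ordered (pc, hi, moe),
#'   as produced by [standardize_features()] on the feature tibble.
#' @param labels Integer cluster labels (1..k) over the rows of `Z`.
#' @return Tibble with columns `cluster`, `composite_score`, `size`, `level`.
#' @export
order_clusters_by_risk <- function(Z, labels) {
  Z <- feature_values(Z)
  stopifnot(ncol(Z) == 3, nrow(Z) == length(labels))
  composite <- Z[, 1] + Z[, 2] - Z[, 3]
  tibble::tibble(cluster = labels, composite = composite) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(composite_score = mean(.data$composite),
                     size = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$composite_score, dplyr::desc(.data$size), .data$cluster) |>
    dplyr::mutate(level = dplyr::row_number()) |>
    dplyr::arrange(.data$cluster)
}

#' Assign ordered risk levels to combinations
#'
#' @param assignment Tibble with columns `region`, `category`, `cluster`.
#' @param level_map Tibble from [order_clusters_by_risk()] (columns `cluster`,
#'   `level`; extra columns carried along).
#' @return Tibble `region`, `category`, `risk_level`, sorted region-major.
#' @export
assign_levels <- function(assignment, level_map) {
  uncovered <- setdiff(assignment$cluster, level_map$cluster)
  if (length(uncovered) > 0) {
    abort(sprintf("level map does not cover cluster id(s): %s",
                  paste(uncovered, collapse = ", ")),
          class = "leadrisk_internal_error")
  }
  assignment |>
    dplyr::left_join(level_map[c("cluster", "level")], by = "cluster") |>
    dplyr::rename(risk_level = "level") |>
    dplyr::select("region", "category", "risk_level") |>
    dplyr::arrange(.data$region, .data$category)
}

#' Per-level and grouped level proportions
#'
#' Counts and percentages (2 decimals) of combinations at each risk level,
#' plus the conventional groupings: low risk (levels 1-2) and high risk
#' (levels 4-5).
#'
#' @param level_table Tibble with a `risk_level` column.
#' @return List with `per_level` (tibble `risk_level`, `count`, `percent`)
#'   and `grouped` (tibble `group`, `count`, `percent`).
#' @export
level_proportions <- function(level_table) {
  if (nrow(level_table) == 0) abort("empty level table",
                                    class = "leadrisk_domain_error")
  n <- nrow(level_table)
  per_level <- level_table |>
    dplyr::count(.data$risk_level, name = "count") |>
    dplyr::mutate(percent = round(100 * .data$count / n, 2))
  grouped <- tibble::tibble(
    group = c("levels 1-2", "level 3", "levels 4-5"),
    count = c(sum(level_table$risk_level <= 2),
              sum(level_table$risk_level == 3),
              sum(level_table$risk_level >= 4))
  ) |>
    dplyr::mutate(percent = round(100 * .data$count / n, 2))
  list(per_level = per_level, grouped = grouped)
}

#' Rank combinations at or above a risk-level threshold
#'
#' Filters combinations with `risk_level >= threshold_level` and sorts them
#' by level descending, breaking ties by composite risk score descending
#' when scores are supplied.
#'
#' @param level_table Tibble `region`, `category`, `risk_level`, optionally
#'   with a `composite_score` column for tie order.
#' @param threshold_level Minimum level retained (default 3).
#' @return Filtered, sorted tibble.
#' @export
rank_high_risk <- function(level_table, threshold_level = 3) {
  out <- dplyr::filter(level_table, .data$risk_level >= threshold_level)
  if ("composite_score" %in% names(out)) {
    dplyr::arrange(out, dplyr::desc(.data$risk_level),
                   dplyr::desc(.data$composite_score))
  } else {
    dplyr::arrange(out, dplyr::desc(.data$risk_level))
  }
}

#' Exceedance factor of a sample over the regulatory limit
#'
#' How many times the maximum measured concentration exceeds the category's
#' national limit (e.g. 0.42 mg/kg over a 0.1 mg/kg limit is 4.2-fold).
#'
#' @param x_max Maximum concentration, mg/kg.
#' @param s Regulatory limit, mg/kg (> 0).
#' @return Dimensionless fold-exceedance.
#' @export
exceedance_factor <- function(x_max, s) {
  if (any(s <= 0)) abort("limit `s` must be > 0", class = "leadrisk_domain_error")
  x_max / s
}
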