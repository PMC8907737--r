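#' Single-factor pollution index
#'
#' Ratio of a measured lead concentration to the category's regulatory limit:
#' values above 1 exceed the national standard.
#'
#' @param x Concentration in mg/kg (>= 0).
#' @param s Regulatory limit in mg/kg (> 0).
#' @return Dimensionless pollution index `x / s`.
#' @export
pollution_index <- function(x, s) {
  if (any(s <= 0)) abort("limit `s` must be > 0", class = "leadrisk_domain_error")
  if (any(x < 0)) abort("concentration `x` must be >= 0", class = "leadrisk_domain_error")
  x / s
}

#' Nemerow integrated pollution index
#'
#' Combines the worst-case and average single-factor pollution indexes of a
#' combination: `sqrt((p_max^2 + p_ave^2) / 2)`. The result always lies in
#' `[p_max / sqrt(2), p_max]`, so a single hot sample dominates but the
#' average tempers it.
#'
#' @param p_max Maximum pollution index over the combination's samples.
#' @param p_ave Mean pollution index (equivalently, mean concentration over
#'   the limit).
#' @return Dimensionless integrated index.
#' @export
nemerow_index <- function(p_max, p_ave) {
  if (any(p_ave < 0)) abort("`p_ave` must be >= 0", class = "leadrisk_domain_error")
  if (any(p_ave > p_max)) {
    abort("`p_ave` exceeds `p_max`: inconsistent summary statistics",
          class = "leadrisk_domain_error")
  }
  sqrt((p_max^2 + p_ave^2) / 2)
}

#' Estimated daily intake of lead per kg body weight
#'
#' `EDI = FC * X / W`, with the mg-to-ug conversion applied so the result is
#' directly comparable to the reference dose and benchmark dose, which are
#' quoted in ug/(kg day).
#'
#' @param fc Mean daily consumption in kg/day (> 0).
#' @param x Lead concentration in mg/kg (>= 0).
#' @param w Body weight in kg (> 0).
#' @return Intake in ug per kg body weight per day.
#' @export
estimated_daily_intake <- function(fc, x, w) {
  if (any(w <= 0)) abort("body weight `w` must be > 0", class = "leadrisk_domain_error")
  if (any(fc <= 0)) abort("consumption `fc` must be > 0", class = "leadrisk_domain_error")
  if (any(x < 0)) abort("concentration `x` must be >= 0", class = "leadrisk_domain_error")
  fc * x / w * 1000
}

#' Hazard index for non-carcinogenic risk
#'
#' Estimated daily intake at high (P95) exposure divided by the oral
#' reference dose; values below 1 are conventionally acceptable.
#'
#' @param edi95 Intake at P95 concentration, ug/(kg day).
#' @param rfd Oral reference dose, ug/(kg day) (> 0); 3.5 for lead.
#' @return Dimensionless hazard index.
#' @export
hazard_index <- function(edi95, rfd) {
  if (any(rfd <= 0)) abort("`rfd` must be > 0", class = "leadrisk_domain_error")
  edi95 / rfd
}

#' Margin of exposure for chronic dietary risk
#'
#' Benchmark-dose lower bound divided by the estimated daily intake at median
#' (P50) exposure; larger margins are safer.
#'
#' @param bmdl01 Lower 95% bound on the 1% benchmark dose, ug/(kg day);
#'   0.6 for lead.
#' @param edi50 Intake at median concentration, ug/(kg day) (> 0).
#' @param cap Upper sentinel for the margin when `edi50` underflows toward 0
#'   (default `1e6`); a warning is raised when the cap binds.
#' @return Dimensionless margin of exposure.
#' @export
margin_of_exposure <- function(bmdl01, edi50, cap = 1e6) {
  if (any(edi50 < 0)) abort("`edi50` must be >= 0", class = "leadrisk_domain_error")
  out <- bmdl01 / edi50
  hit <- !is.finite(out) | out > cap
  if (any(hit)) {
    warn(sprintf("margin of exposure capped at %g for %d combination(s) with ~zero median exposure",
                 cap, sum(hit)))
    out[hit] <- cap
  }
  out
}

#' Assemble the clustering feature matrix of risk indexes
#'
#' For every region-category combination, computes the three model indexes:
#' the Nemerow integrated pollution index from the combination's maximum and
#' mean concentration over the category limit, the hazard index from the
#' intake at P95 concentration against the reference dose, and the margin of
#' exposure from the benchmark dose against the intake at P50 concentration.
#' Rows are ordered region-major (region, then category, lexicographic).
#'
#' @param stats Combination summaries from [summarize_combinations()].
#' @param consumption Consumption tibble (`region`, `category`,
#'   `fc_kg_per_day`).
#' @param limits Limit tibble (`category`, `limit_mg_per_kg`).
#' @param tox Toxicological references from [read_tox_config()] or
#'   [scenario_config()]`$tox`.
#' @param moe_cap Sentinel cap forwarded to [margin_of_exposure()].
#' @return Tibble with columns `region`, `category`, `pc`, `hi`, `moe`.
#' @export
build_feature_matrix <- function(stats, consumption, limits, tox, moe_cap = 1e6) {
  joined <- stats |>
    dplyr::left_join(consumption, by = c("region", "category")) |>
    dplyr::left_join(limits, by = "category")
  offenders <- joined |>
    dplyr::filter(is.na(.data$fc_kg_per_day) | is.na(.data$limit_mg_per_kg))
  if (nrow(offenders) > 0) {
    abort(paste0(
      "combinations lacking a consumption entry or a category limit: ",
      paste(paste(offenders$region, offenders$category, sep = "/"), collapse = "; ")
    ), class = "leadrisk_aggregation_error")
  }
  joined |>
    dplyr::mutate(
      pc = nemerow_index(pollution_index(.data$max, .data$limit_mg_per_kg),
                         pollution_index(.data$mean, .data$limit_mg_per_kg)),
      hi = hazard_index(
        estimated_daily_intake(.data$fc_kg_per_day, .data$p95, tox$body_weight_kg),
        tox$rfd_ug_per_kg_day
      ),
      moe = margin_of_exposure(
        tox$bmdl01_ug_per_kg_day,
        estimated_daily_intake(.data$fc_kg_per_day, .data$p50, tox$body_weight_kg),
        cap = moe_cap
      )
    ) |>
    dplyr::arrange(.data$region, .data$category) |>
    dplyr::select("region", "category", "pc", "hi", "moe")
}

#' Write the index table as CSV
#'
#' Emits full-precision `pc`, `hi`, `moe` plus rounded 3-decimal presentation
#' columns (`pc_3dp`, `hi_3dp`, `moe_3dp`) for report-style display.
#'
#' @param features Feature tibble from [build_feature_matrix()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_indices_csv <- function(features, path) {
  features |>
    dplyr::mutate(dplyr::across(c("pc", "hi", "moe"), ~ round(.x, 3),
                                .names = "{.col}_3dp")) |>
    readr::write_csv(path)
  invisible(path)
}
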