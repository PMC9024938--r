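# Soil-to-grain transfer factors and estimated daily intake (EDI).

#' Soil-to-plant transfer factor
#'
#' TF = grain concentration / soil concentration, both in the same unit
#' (mg/kg dry weight), a dimensionless bioavailability/mobility index.
#' Undefined for zero soil concentration.
#'
#' @param grain_mc Grain concentration(s), mg/kg.
#' @param soil_mc Soil concentration(s), mg/kg (> 0).
#' @return Numeric vector of transfer factors.
#' @export
transfer_factor <- function(grain_mc, soil_mc) {
  if (any(grain_mc < 0, na.rm = TRUE) || any(soil_mc < 0, na.rm = TRUE)) {
    abort("concentrations must be non-negative", class = "metalrisk_validation_error")
  }
  if (any(soil_mc == 0, na.rm = TRUE)) {
    abort("transfer factor undefined for zero soil concentration",
          class = "metalrisk_validation_error")
  }
  grain_mc / soil_mc
}

#' Transfer-factor table from a concentration table
#'
#' Computes per-(system, element) transfer factors from group mean
#' concentrations of the grain and soil media.
#'
#' @param table A [concentration_table()].
#' @param grain_medium Medium treated as the plant compartment, default
#'   `"rice_grain"`.
#' @param soil_medium Default `"soil"`.
#' @return Tibble with columns `system`, `element`, `grain_mean`,
#'   `soil_mean`, `tf`.
#' @export
transfer_factors <- function(table, grain_medium = "rice_grain",
                             soil_medium = "soil") {
  means <- summarize_concentrations(table) |>
    dplyr::filter(.data$medium %in% c(grain_medium, soil_medium)) |>
    dplyr::select("system", "medium", "element", "mean") |>
    tidyr::pivot_wider(names_from = "medium", values_from = "mean")
  if (!all(c(grain_medium, soil_medium) %in% names(means))) {
    abort("table must contain both grain and soil records",
          class = "metalrisk_validation_error")
  }
  means |>
    dplyr::rename(grain_mean = dplyr::all_of(grain_medium),
                  soil_mean = dplyr::all_of(soil_medium)) |>
    dplyr::filter(!is.na(.data$grain_mean), !is.na(.data$soil_mean)) |>
    dplyr::mutate(tf = transfer_factor(.data$grain_mean, .data$soil_mean)) |>
    dplyr::arrange(.data$system, .data$element)
}

#' Estimated daily intake
#'
#' The chronic dietary exposure model
#' \deqn{EDI = \frac{EF \times ED \times VI \times MC}{BW \times AT} \times 1000}
#' with MC the element concentration in the food (mg/kg dry weight), VI the
#' ingestion rate (kg/day), BW body weight (kg), EF exposure frequency
#' (days/year), ED exposure duration (years) and AT averaging time (days).
#' The factor 1000 converts mg to ug, so EDI is reported in ug/kg/day.
#' This is the single place in the package where the mg -> ug conversion
#' happens. Under the default convention EF = 365 and AT = ED x 365, the
#' formula collapses to EDI = VI x MC / BW x 1000.
#'
#' @param mc Concentration(s) in the food, mg/kg dry weight (>= 0).
#' @param vi Ingestion rate, kg/day.
#' @param bw Body weight, kg.
#' @param ef Exposure frequency, days/year. Default 365.
#' @param ed Exposure duration, years. Default 1 (cancels with default `at`).
#' @param at Averaging time, days. Default `ed * 365`.
#' @return EDI in ug/kg/day; linear and homogeneous in `mc`.
#' @export
compute_edi <- function(mc, vi, bw, ef = 365, ed = 1, at = ed * 365) {
  if (any(mc < 0, na.rm = TRUE)) {
    abort("concentration must be non-negative", class = "metalrisk_validation_error")
  }
  if (any(c(vi, bw, ef, ed, at) <= 0, na.rm = TRUE)) {
    abort("vi, bw, ef, ed, at must all be positive",
          class = "metalrisk_config_error")
  }
  (ef * ed * vi * mc) / (bw * at) * 1000
}

#' EDI table per element, food, population and system
#'
#' Applies [compute_edi()] to group mean concentrations of the food media
#' (rice grain -> rice, crayfish muscle -> crayfish) for every exposure
#' scenario, and optionally flags intakes exceeding the maximum tolerable
#' daily intake registry.
#'
#' @param table A [concentration_table()].
#' @param scenarios Scenario tibble, default [default_scenarios()].
#' @param mtdi Optional MTDI registry (see [default_mtdi()]); `NULL` skips
#'   the screen.
#' @return Tibble with columns `system`, `food`, `population`, `element`,
#'   `mc`, `edi` (ug/kg/day) and, when `mtdi` is given, `mtdi`,
#'   `exceeds_mtdi`.
#' @export
edi_table <- function(table, scenarios = default_scenarios(),
                      mtdi = default_mtdi()) {
  foods <- summarize_concentrations(table) |>
    dplyr::filter(.data$medium %in% names(.MEDIUM_FOOD)) |>
    dplyr::mutate(food = unname(.MEDIUM_FOOD[.data$medium])) |>
    dplyr::select("system", "food", "element", mc = "mean")
  if (nrow(foods) == 0) {
    return(tibble::tibble(system = character(), food = character(),
                          population = character(), element = character(),
                          mc = numeric(), edi = numeric()))
  }
  missing_food <- setdiff(unique(foods$food), unique(scenarios$food))
  if (length(missing_food) > 0) {
    abort(paste0("no ingestion rate configured for food(s): ",
                 paste(missing_food, collapse = ", ")),
          class = "metalrisk_config_error")
  }
  out <- dplyr::inner_join(foods, scenarios, by = "food",
                           relationship = "many-to-many") |>
    dplyr::mutate(edi = compute_edi(.data$mc, .data$vi, .data$bw,
                                    .data$ef, .data$ed, .data$at)) |>
    dplyr::select("system", "food", "population", "element", "mc", "edi")
  if (!is.null(mtdi)) {
    out <- out |>
      dplyr::left_join(mtdi, by = "element") |>
      dplyr::mutate(exceeds_mtdi = .data$edi > .data$mtdi)
  }
  dplyr::arrange(out, .data$system, .data$food, .data$population, .data$element)
}
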