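# Deterministic non-carcinogenic (THQ, HI) and carcinogenic (CR, TCR) risk.

#' Target hazard quotients
#'
#' THQ = EDI / RfD, both in ug/kg/day, per element. A THQ (or a hazard
#' index summed over elements) above 1 indicates potential non-carcinogenic
#' risk.
#'
#' @param edi EDI tibble from [edi_table()] (columns `element`, `edi`, plus
#'   grouping keys `food`, `population`, `system`).
#' @param toxicity Toxicity registry, default [default_toxicity()].
#' @return `edi` with `rfd` and `thq` columns added.
#' @export
compute_thq <- function(edi, toxicity = default_toxicity()) {
  out <- dplyr::left_join(tibble::as_tibble(edi),
                          dplyr::select(toxicity, "element", "rfd"),
                          by = "element")
  bad <- is.na(out$rfd) | out$rfd <= 0
  if (any(bad)) {
    abort(paste0("no reference dose available for element(s): ",
                 paste(unique(out$element[bad]), collapse = ", ")),
          class = "metalrisk_config_error")
  }
  dplyr::mutate(out, thq = .data$edi / .data$rfd)
}

#' Hazard indices
#'
#' HI is the arithmetic sum of the element THQs within each
#' (food, population, system) group. Per-element contribution shares
#' (THQ / HI, summing to 1 when HI > 0) are returned as a list-column of
#' named vectors. `tolerable` is `FALSE` when HI exceeds 1, the conventional
#' interpretation threshold for potential non-carcinogenic risk.
#'
#' @param thq Output of [compute_thq()].
#' @param by Grouping keys, default `c("food", "population", "system")`.
#' @return Tibble with `hi`, `n_elements`, `contributions`, `tolerable`.
#' @export
compute_hi <- function(thq, by = c("food", "population", "system")) {
  tibble::as_tibble(thq) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      hi = sum(.data$thq),
      n_elements = dplyr::n(),
      contributions = list(setNames(.data$thq / sum(.data$thq), .data$element)),
      .groups = "drop"
    ) |>
    dplyr::mutate(tolerable = .data$hi <= 1)
}

#' Classify an incremental lifetime cancer risk
#'
#' Step classification against the USEPA benchmarks: below 1e-6 the risk is
#' negligible; between 1e-6 and 1e-4 (boundaries included) it is acceptable
#' or tolerable; above 1e-4 it is unacceptable.
#'
#' @param cr Numeric vector of cancer risks (>= 0).
#' @return Factor with levels `negligible`, `acceptable`, `unacceptable`.
#' @export
classify_cr <- function(cr) {
  if (any(cr < 0, na.rm = TRUE)) {
    abort("cancer risk must be non-negative", class = "metalrisk_validation_error")
  }
  factor(ifelse(cr < 1e-6, "negligible",
                ifelse(cr <= 1e-4, "acceptable", "unacceptable")),
         levels = c("negligible", "acceptable", "unacceptable"))
}

#' Incremental lifetime cancer risk per element
#'
#' CR = EDI x SF with the EDI converted from ug/kg/day to mg/kg/day (the
#' slope factor's unit is kg day/mg), i.e. CR = EDI/1000 x SF. Only the
#' carcinogenic elements (those with a slope factor: Cd, As, Cr, Pb, Ni by
#' default) are evaluated; requesting a non-carcinogen is an error unless
#' `drop_noncarcinogens = TRUE`, which silently filters them.
#'
#' @param edi EDI tibble from [edi_table()].
#' @param toxicity Toxicity registry, default [default_toxicity()].
#' @param drop_noncarcinogens Filter instead of erroring on elements without
#'   a slope factor. Default `TRUE` (the usual table-level call).
#' @return Filtered tibble with `sf`, `cr` and `category` columns added.
#' @export
compute_cr <- function(edi, toxicity = default_toxicity(),
                       drop_noncarcinogens = TRUE) {
  out <- dplyr::left_join(tibble::as_tibble(edi),
                          dplyr::select(toxicity, "element", "sf", "carcinogen"),
                          by = "element")
  non <- is.na(out$carcinogen) | !out$carcinogen
  if (any(non)) {
    if (!drop_noncarcinogens) {
      abort(paste0("element(s) without a cancer slope factor: ",
                   paste(unique(out$element[non]), collapse = ", ")),
            class = "metalrisk_config_error")
    }
    out <- out[!non, , drop = FALSE]
  }
  out |>
    dplyr::mutate(cr = .data$edi / 1000 * .data$sf,
                  category = classify_cr(.data$cr)) |>
    dplyr::select(-"carcinogen")
}

#' Total cancer risk
#'
#' TCR is the sum of the element cancer risks within each
#' (food, population, system) group, classified with the same benchmarks.
#' An empty input is an error: the total risk of no elements is undefined,
#' not zero.
#'
#' @param cr Output of [compute_cr()].
#' @param by Grouping keys, default `c("food", "population", "system")`.
#' @return Tibble with `tcr`, `n_elements`, `category`.
#' @export
compute_tcr <- function(cr, by = c("food", "population", "system")) {
  cr <- tibble::as_tibble(cr)
  if (nrow(cr) == 0) {
    abort("cannot aggregate total cancer risk over an empty set of elements",
          class = "metalrisk_validation_error")
  }
  cr |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(tcr = sum(.data$cr), n_elements = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(category = classify_cr(.data$tcr))
}

#' Full deterministic risk assessment
#'
#' Runs the complete deterministic chain on a concentration table: group
#' mean EDIs, per-element THQs and CRs, and the HI and TCR aggregates.
#'
#' @param table A [concentration_table()].
#' @param scenarios Scenario tibble, default [default_scenarios()].
#' @param toxicity Toxicity registry, default [default_toxicity()].
#' @param mtdi Optional MTDI registry for the intake screen.
#' @return Named list with tibbles `edi`, `thq`, `hi`, `cr`, `tcr`.
#' @export
risk_assessment <- function(table, scenarios = default_scenarios(),
                            toxicity = default_toxicity(),
                            mtdi = default_mtdi()) {
  edi <- edi_table(table, scenarios, mtdi)
  thq <- compute_thq(edi, toxicity)
  cr <- compute_cr(edi, toxicity)
  list(edi = edi, thq = thq, hi = compute_hi(thq),
       cr = cr, tcr = compute_tcr(cr))
}
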