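# Descriptive statistics of concentrations and screening against background
# values and regulatory limits.

#' Summarize element concentrations per group
#'
#' Computes n, minimum, maximum, median, mean, sample standard deviation
#' (n - 1 denominator) and the coefficient of variation CV = sd/mean x 100
#' (in percent) for each (system, medium, element) group. SD and CV are `NA`
#' for groups with a single observation; CV is `NA` when the mean is zero.
#'
#' @param table A [concentration_table()] (or compatible tibble).
#' @param by Grouping columns, default `c("system", "medium", "element")`.
#' @return Tibble of summary statistics, one row per group.
#' @export
summarize_concentrations <- function(table, by = c("system", "medium", "element")) {
  table <- tibble::as_tibble(table)
  if (nrow(table) == 0) {
    return(tibble::tibble(!!!setNames(rep(list(character()), length(by)), by),
                          n = integer(), minimum = numeric(),
                          maximum = numeric(), median = numeric(),
                          mean = numeric(), sd = numeric(),
                          cv_percent = numeric()))
  }
  table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      minimum = min(.data$value),
      maximum = max(.data$value),
      median = median(.data$value),
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() >= 2, sd(.data$value), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(cv_percent = ifelse(.data$mean == 0, NA_real_,
                                      .data$sd / .data$mean * 100))
}

#' Screen soil means against background values and regulatory limits
#'
#' Flags each element whose group mean strictly exceeds the regional soil
#' background value or the regulatory safety limit, and reports the
#' enrichment ratio mean/background. A mean exactly equal to a limit does
#' not count as an exceedance. Elements without a registry entry get `NA`
#' flags (screening unavailable, not "no exceedance").
#'
#' @param stats Summary statistics from [summarize_concentrations()] (or any
#'   tibble with `element` and `mean` columns).
#' @param limits Regulatory registry, default [default_limits()].
#' @return `stats` with `background`, `soil_safety_limit`,
#'   `exceeds_background`, `exceeds_safety_limit`, `enrichment_ratio` added.
#' @export
screen_soil <- function(stats, limits = default_limits()) {
  tibble::as_tibble(stats) |>
    dplyr::left_join(limits, by = "element") |>
    dplyr::mutate(
      exceeds_background = .data$mean > .data$background,
      exceeds_safety_limit = .data$mean > .data$soil_safety_limit,
      enrichment_ratio = .data$mean / .data$background
    )
}

#' Reshape summary statistics into the conventional report layout
#'
#' One row per statistic, one column per element, per (system, medium)
#' block — the layout regulatory summary tables are usually printed in.
#'
#' @param stats Output of [summarize_concentrations()].
#' @return Tibble with columns `system`, `medium`, `statistic`, then one
#'   column per element.
#' @export
summary_wide <- function(stats) {
  tibble::as_tibble(stats) |>
    tidyr::pivot_longer(cols = c("minimum", "maximum", "median", "mean",
                                 "sd", "cv_percent"),
                        names_to = "statistic", values_to = "value") |>
    tidyr::pivot_wider(id_cols = c("system", "medium", "statistic"),
                       names_from = "element", values_from = "value")
}
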