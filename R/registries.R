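# Default registries: toxicity parameters, exposure scenarios, regulatory
# limits, detection limits, tolerable intakes, and the bundled study means.
# Registries are data, not code: every risk function accepts an override.

#' Oral toxicity parameters for the eight tracked elements
#'
#' Reference doses (RfD, ug/kg/day) for non-carcinogenic hazard quotients and
#' cancer slope factors (SF, kg day/mg) for the five elements treated as
#' carcinogens by ingestion (Cd, As, Cr, Pb, Ni), drawn from the USEPA IRIS
#' and California OEHHA toxicity databases. `carcinogen` is `TRUE` exactly
#' when a slope factor is present.
#'
#' @return Tibble with columns `element`, `rfd`, `sf`, `carcinogen`.
#' @export
default_toxicity <- function() {
  tibble::tibble(
    element = c("As", "Hg", "Cr", "Cu", "Ni", "Zn", "Cd", "Pb"),
    rfd = c(0.3, 0.16, 1500, 40, 20, 300, 1, 3.5),
    sf = c(1.5, NA, 0.5, NA, 0.84, NA, 15, 0.0085)
  ) |>
    dplyr::mutate(carcinogen = !is.na(.data$sf))
}

#' Default adult and child exposure scenarios
#'
#' Chronic dietary scenarios for local residents: adults (BW 70 kg, ED 77 y)
#' eating 0.337 kg/day rice and 0.0555 kg/day crayfish; children (BW 25 kg,
#' ED 9 y) eating 0.24 kg/day rice and 0.02 kg/day crayfish. EF = 365
#' days/year and AT = ED x 365 days for both, so the EF*ED/AT factor is 1.
#'
#' @return Tibble with one row per population x food; see [exposure_scenario()].
#' @export
default_scenarios <- function() {
  dplyr::bind_rows(
    exposure_scenario("adult", bw = 70, ed = 77,
                      vi = c(rice = 0.337, crayfish = 0.0555)),
    exposure_scenario("child", bw = 25, ed = 9,
                      vi = c(rice = 0.24, crayfish = 0.02))
  )
}

#' Soil background values and regulatory limits
#'
#' Per-element screening references: the Anhui Province soil background
#' values and the Chinese agricultural-soil risk-control limits
#' (GB 15618-2018, grade II), both mg/kg.
#'
#' @return Tibble with columns `element`, `background`, `soil_safety_limit`.
#' @export
default_limits <- function() {
  tibble::tibble(
    element = c("As", "Hg", "Cr", "Cu", "Ni", "Zn", "Cd", "Pb"),
    background = c(9.00, 0.03, 66.5, 20.4, 29.8, 62, 0.10, 26.6),
    soil_safety_limit = c(25, 0.5, 200, 100, 90, 250, 0.45, 80)
  )
}

#' Method detection limits
#'
#' ICP-OES detection limits (mg/kg) used to substitute censored ("<LOD")
#' entries at ingest.
#'
#' @return Named numeric vector, element -> LOD in mg/kg.
#' @export
default_lods <- function() {
  c(As = 0.01, Cd = 0.01, Ni = 1.0, Cu = 1.0, Pb = 1.0,
    Hg = 0.002, Zn = 1, Cr = 2)
}

#' Maximum tolerable daily intakes
#'
#' WHO maximum tolerable daily intake (MTDI) benchmarks in ug/kg/day, used
#' as an optional screen on estimated daily intakes.
#'
#' @return Tibble with columns `element`, `mtdi`.
#' @export
default_mtdi <- function() {
  tibble::tibble(
    element = c("Cr", "Ni", "Cu", "Zn", "As", "Cd", "Hg", "Pb"),
    mtdi = c(300, 12, 500, 300, 2.14, 0.8, 0.23, 1.5)
  )
}

#' Published mean concentrations from the rice-crayfish case study
#'
#' The group mean concentrations (mg/kg dry weight) of the eight elements in
#' paddy topsoil (RCS and CRC), rice grain (RCS and CRC) and crayfish tail
#' muscle, as one pseudo-sample per (system, medium) group. These means are
#' the deterministic inputs of the risk pipeline: transfer factors, EDI, THQ,
#' HI, CR and TCR tables are all computed from them. Crayfish were sampled
#' only from the co-culture ponds, so the crayfish rows carry the RCS label.
#'
#' @return A [concentration_table()] of 40 records (5 groups x 8 elements).
#' @export
study_means <- function() {
  g <- function(id, system, medium, values) {
    tibble::tibble(sample_id = id, system = system, medium = medium,
                   element = names(values), value = unname(values))
  }
  concentration_table(dplyr::bind_rows(
    g("rcs_soil_mean", "RCS", "soil",
      c(As = 14.98, Hg = 0.08, Cr = 97.84, Cu = 49.93, Ni = 48.13,
        Zn = 114.57, Cd = 0.38, Pb = 35.97)),
    g("crc_soil_mean", "CRC", "soil",
      c(As = 12.99, Hg = 0.10, Cr = 93.90, Cu = 49.50, Ni = 46.11,
        Zn = 108.67, Cd = 0.39, Pb = 32.60)),
    g("rcs_grain_mean", "RCS", "rice_grain",
      c(As = 0.040, Cd = 0.025, Cr = 0.068, Cu = 3.120, Hg = 0.010,
        Ni = 0.183, Pb = 0.035, Zn = 11.230)),
    g("crc_grain_mean", "CRC", "rice_grain",
      c(As = 0.067, Cd = 0.023, Cr = 0.077, Cu = 3.197, Hg = 0.005,
        Ni = 0.097, Pb = 0.038, Zn = 10.963)),
    g("crayfish_mean", "RCS", "crayfish_muscle",
      c(As = 0.134, Cd = 0.001, Cr = 0.066, Cu = 2.623, Hg = 0.086,
        Ni = 0.024, Pb = 0.035, Zn = 11.767))
  ), provenance = "published group means, rice-crayfish case study")
}

#' Published soil summary statistics (means and SDs)
#'
#' Mean and standard deviation of soil element concentrations per farming
#' system, used as moment targets by the synthetic generator presets.
#'
#' @return Tibble with columns `system`, `element`, `mean`, `sd`.
#' @export
study_soil_moments <- function() {
  tibble::tibble(
    system = rep(c("RCS", "CRC"), each = 8),
    element = rep(c("As", "Hg", "Cr", "Cu", "Ni", "Zn", "Cd", "Pb"), 2),
    mean = c(14.98, 0.08, 97.84, 49.93, 48.13, 114.57, 0.38, 35.97,
             12.99, 0.10, 93.90, 49.50, 46.11, 108.67, 0.39, 32.60),
    sd = c(2.02, 0.02, 5.42, 3.77, 3.62, 8.45, 0.04, 2.59,
           0.58, 0.07, 2.03, 1.23, 1.14, 2.13, 0.02, 1.07)
  )
}

#' Published soil element correlation matrices
#'
#' Pearson correlation matrices among the eight soil elements for each
#' farming system, used as correlation targets by the synthetic generator
#' presets and as qualitative references for source apportionment.
#'
#' @param system `"RCS"` or `"CRC"`.
#' @return Symmetric 8 x 8 correlation matrix with element dimnames.
#' @export
study_soil_correlation <- function(system = c("RCS", "CRC")) {
  system <- match.arg(system)
  el <- c("As", "Hg", "Cr", "Cu", "Ni", "Zn", "Cd", "Pb")
  r <- diag(8)
  dimnames(r) <- list(el, el)
  fill <- function(r, pairs) {
    for (p in pairs) {
      r[p[[1]], p[[2]]] <- r[p[[2]], p[[1]]] <- p[[3]]
    }
    r
  }
  if (system == "RCS") {
    pairs <- list(
      list("As", "Hg", 0.273), list("As", "Cr", 0.788), list("As", "Cu", 0.748),
      list("As", "Ni", 0.826), list("As", "Zn", 0.803), list("As", "Cd", 0.318),
      list("As", "Pb", 0.785),
      list("Hg", "Cr", 0.335), list("Hg", "Cu", 0.375), list("Hg", "Ni", 0.386),
      list("Hg", "Zn", 0.411), list("Hg", "Cd", 0.292), list("Hg", "Pb", 0.427),
      list("Cr", "Cu", 0.884), list("Cr", "Ni", 0.962), list("Cr", "Zn", 0.923),
      list("Cr", "Cd", 0.335), list("Cr", "Pb", 0.848),
      list("Cu", "Ni", 0.913), list("Cu", "Zn", 0.927), list("Cu", "Cd", 0.532),
      list("Cu", "Pb", 0.793),
      list("Ni", "Zn", 0.963), list("Ni", "Cd", 0.406), list("Ni", "Pb", 0.864),
      list("Zn", "Cd", 0.510), list("Zn", "Pb", 0.856),
      list("Cd", "Pb", 0.325)
    )
  } else {
    pairs <- list(
      list("As", "Hg", 0.231), list("As", "Cr", 0.741), list("As", "Cu", 0.761),
      list("As", "Ni", 0.720), list("As", "Zn", 0.914), list("As", "Cd", 0.141),
      list("As", "Pb", 0.223),
      list("Hg", "Cr", -0.148), list("Hg", "Cu", -0.086), list("Hg", "Ni", -0.021),
      list("Hg", "Zn", 0.079), list("Hg", "Cd", -0.017), list("Hg", "Pb", 0.244),
      list("Cr", "Cu", 0.715), list("Cr", "Ni", 0.868), list("Cr", "Zn", 0.861),
      list("Cr", "Cd", 0.173), list("Cr", "Pb", 0.122),
      list("Cu", "Ni", 0.671), list("Cu", "Zn", 0.720), list("Cu", "Cd", 0.293),
      list("Cu", "Pb", 0.307),
      list("Ni", "Zn", 0.836), list("Ni", "Cd", 0.094), list("Ni", "Pb", -0.121),
      list("Zn", "Cd", 0.267), list("Zn", "Pb", 0.254),
      list("Cd", "Pb", 0.427)
    )
  }
  fill(r, pairs)
}
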