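# Domain types: concentration tables, element identity, ingest/validation.

#' Canonical toxic-element symbols
#'
#' The eight elements tracked by the package: As, Cd, Cr, Cu, Hg, Ni, Pb, Zn.
#' The set is an extensible enumeration: registries may carry additional
#' elements, but ingest validation rejects symbols absent from this list
#' unless `extra` supplies them.
#'
#' @param extra Optional character vector of additional accepted symbols.
#' @return Character vector of element symbols.
#' @export
element_symbols <- function(extra = NULL) {
  unique(c("As", "Cd", "Cr", "Cu", "Hg", "Ni", "Pb", "Zn", extra))
}

#' Canonicalize element symbols
#'
#' Element identity is case-insensitive on input and stored in canonical
#' capitalization ("hg" -> "Hg"). Unknown symbols map to `NA`.
#'
#' @param x Character vector of element symbols in any capitalization.
#' @param symbols Accepted canonical symbols, default [element_symbols()].
#' @return Character vector of canonical symbols, `NA` where unrecognized.
#' @export
canonical_element <- function(x, symbols = element_symbols()) {
  symbols[match(tolower(trimws(x)), tolower(symbols))]
}

#' Build a validated concentration table
#'
#' A concentration table is a tibble of sample-level element concentrations
#' in mg/kg dry weight keyed by (sample_id, medium, element), with a farming
#' system label (RCS = rice-crayfish co-culture, CRC = conventional rice
#' culture) and a `below_lod` flag marking values substituted for censored
#' measurements.
#'
#' @param records Data frame with columns `sample_id`, `system`, `medium`,
#'   `element`, `value` and optionally `below_lod`.
#' @param provenance Free-text provenance note stored as an attribute.
#' @param symbols Accepted element symbols.
#' @return A tibble of class `conc_tbl` with columns `sample_id`, `system`,
#'   `medium`, `element`, `value`, `below_lod`.
#' @export
concentration_table <- function(records, provenance = "", symbols = element_symbols()) {
  records <- tibble::as_tibble(records)
  required <- c("sample_id", "system", "medium", "element", "value")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("concentration table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "metalrisk_schema_error")
  }
  if (!"below_lod" %in% names(records)) records$below_lod <- FALSE

  records$sample_id <- as.character(records$sample_id)
  records$element <- canonical_element(records$element, symbols)
  if (anyNA(records$element)) {
    bad <- which(is.na(records$element))
    abort(paste0("unknown element symbol in row(s): ",
                 paste(head(bad, 10), collapse = ", ")),
          class = "metalrisk_validation_error")
  }
  bad_sys <- !records$system %in% .SYSTEMS
  if (any(bad_sys)) {
    abort(paste0("system must be one of ", paste(.SYSTEMS, collapse = ", "),
                 "; offending row(s): ",
                 paste(head(which(bad_sys), 10), collapse = ", ")),
          class = "metalrisk_validation_error")
  }
  bad_med <- !records$medium %in% .MEDIA
  if (any(bad_med)) {
    abort(paste0("medium must be one of ", paste(.MEDIA, collapse = ", "),
                 "; offending row(s): ",
                 paste(head(which(bad_med), 10), collapse = ", ")),
          class = "metalrisk_validation_error")
  }
  records$value <- as.numeric(records$value)
  if (anyNA(records$value)) {
    abort(paste0("non-numeric concentration value in row(s): ",
                 paste(head(which(is.na(records$value)), 10), collapse = ", ")),
          class = "metalrisk_validation_error")
  }
  neg <- records$value < 0
  if (any(neg)) {
    abort(paste0("negative concentration value in row(s): ",
                 paste(head(which(neg), 10), collapse = ", ")),
          class = "metalrisk_validation_error")
  }
  key <- paste(records$sample_id, records$medium, records$element, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    abort(paste0("duplicate (sample_id, medium, element) key in row(s): ",
                 paste(head(dup, 10), collapse = ", ")),
          class = "metalrisk_validation_error")
  }
  out <- records[, c("sample_id", "system", "medium", "element", "value", "below_lod")]
  attr(out, "provenance") <- provenance
  attr(out, "unit") <- "mg/kg dw"
  class(out) <- c("conc_tbl", class(out))
  out
}

#' Read a concentration table from a tidy CSV file
#'
#' Expects a UTF-8 CSV with a header row. Standard column names are
#' `sample_id`, `system`, `medium`, `element`, `value_mg_kg`; a `schema`
#' mapping renames other layouts. Censored entries written as `<LOD` or
#' `<0.01` are flagged `below_lod = TRUE` and substituted according to
#' `lod_policy` using the method detection limits in `lods` (or the numeric
#' bound embedded in the entry itself).
#'
#' Rows whose element symbol is not recognized are rejected with a warning
#' listing the offending row numbers; negative values and duplicate
#' (sample_id, medium, element) keys are errors.
#'
#' @param path Path to the CSV file.
#' @param schema Named character vector mapping standard names
#'   (`sample_id`, `system`, `medium`, `element`, `value`) to the file's
#'   column names. Defaults to the standard layout with `value_mg_kg`.
#' @param lod_policy How censored values enter the table: `"half"` (LOD/2,
#'   default), `"zero"`, or `"lod"` (the LOD itself).
#' @param lods Named numeric vector of detection limits (mg/kg) per element,
#'   default [default_lods()].
#' @param provenance Provenance note; defaults to the file path.
#' @return A validated [concentration_table()].
#' @export
read_concentrations <- function(path,
                                schema = NULL,
                                lod_policy = c("half", "zero", "lod"),
                                lods = default_lods(),
                                provenance = path) {
  lod_policy <- match.arg(lod_policy)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "metalrisk_io_error")
  }
  std <- c(sample_id = "sample_id", system = "system", medium = "medium",
           element = "element", value = "value_mg_kg")
  if (!is.null(schema)) std[names(schema)] <- schema

  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(unname(std), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("input is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "metalrisk_schema_error")
  }
  df <- tibble::tibble(
    sample_id = raw[[std["sample_id"]]],
    system = raw[[std["system"]]],
    medium = raw[[std["medium"]]],
    element = raw[[std["element"]]],
    value_raw = trimws(raw[[std["value"]]])
  )
  if (nrow(df) == 0) {
    warn("input file has a valid header but no data rows")
    return(concentration_table(tibble::tibble(
      sample_id = character(), system = character(), medium = character(),
      element = character(), value = numeric(), below_lod = logical()
    ), provenance = provenance))
  }

  known <- !is.na(canonical_element(df$element))
  if (any(!known)) {
    warn(paste0("rejecting row(s) with unknown element symbol: ",
                paste(head(which(!known), 20), collapse = ", ")))
    df <- df[known, , drop = FALSE]
  }
  df$element <- canonical_element(df$element)

  censored <- grepl("^<", df$value_raw)
  value <- suppressWarnings(as.numeric(df$value_raw))
  if (any(censored)) {
    bound <- suppressWarnings(as.numeric(sub("^<\\s*", "", df$value_raw[censored])))
    # "<LOD" carries no number: take the registry LOD for that element
    registry <- unname(lods[df$element[censored]])
    bound[is.na(bound)] <- registry[is.na(bound)]
    if (anyNA(bound)) {
      abort(paste0("censored value with no detection limit available for element(s): ",
                   paste(unique(df$element[censored][is.na(bound)]), collapse = ", ")),
            class = "metalrisk_validation_error")
    }
    value[censored] <- switch(lod_policy,
                              half = bound / 2,
                              zero = 0,
                              lod = bound)
  }
  bad_num <- is.na(value)
  if (any(bad_num)) {
    abort(paste0("unparseable concentration value in row(s): ",
                 paste(head(which(bad_num), 10), collapse = ", ")),
          class = "metalrisk_validation_error")
  }
  df$value <- value
  df$below_lod <- censored
  concentration_table(df[, c("sample_id", "system", "medium", "element",
                             "value", "below_lod")],
                      provenance = provenance)
}

#' Write a concentration table to CSV
#'
#' Inverse of [read_concentrations()]: finite decimal inputs round-trip
#' bit-identically through the standard column layout.
#'
#' @param table A [concentration_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concentrations <- function(table, path) {
  out <- tibble::as_tibble(table)
  names(out)[names(out) == "value"] <- "value_mg_kg"
  readr::write_csv(out, path)
  invisible(path)
}

#' Construct an exposure scenario
#'
#' An exposure scenario bundles the population parameters of the chronic
#' dietary intake model: body weight BW (kg), ingestion rates VI per food
#' (kg/person/day), exposure frequency EF (days/year), exposure duration ED
#' (years), and averaging time AT (days). Under the default convention
#' AT = ED x 365, which makes the EF*ED/AT factor equal 1; supplying a
#' different AT is allowed (e.g. carcinogenic averaging over a full
#' lifetime) but must be explicit.
#'
#' @param population Label, e.g. `"adult"` or `"child"`.
#' @param bw Body weight in kg (> 0).
#' @param vi Named numeric vector of ingestion rates per food (kg/day).
#' @param ef Exposure frequency, days/year.
#' @param ed Exposure duration, years.
#' @param at Averaging time, days. Default `ed * 365`.
#' @return One-row-per-food tibble with columns `population`, `food`, `vi`,
#'   `bw`, `ef`, `ed`, `at`.
#' @export
exposure_scenario <- function(population, bw, vi, ef = 365, ed, at = ed * 365) {
  stopifnot(is.numeric(bw), length(bw) == 1)
  if (is.null(names(vi)) || any(names(vi) == "")) {
    abort("`vi` must be a named vector (food -> kg/day)",
          class = "metalrisk_config_error")
  }
  vals <- c(bw = bw, ef = ef, ed = ed, at = at, vi)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all scenario numerics (bw, ef, ed, at, vi) must be positive and finite",
          class = "metalrisk_config_error")
  }
  tibble::tibble(
    population = population,
    food = names(vi),
    vi = unname(vi),
    bw = bw, ef = ef, ed = ed, at = at
  )
}
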