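# End-to-end report assembly: describe -> screen -> tf -> edi -> risk ->
# (optional) Monte Carlo -> (optional) source apportionment.

# tiny FNV-1a hash for the manifest's config fingerprint
.fnv1a <- function(s) {
  h <- 2166136261
  for (x in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), x)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

.round_cols <- function(df, cols, digits = 2) {
  for (c in intersect(cols, names(df))) df[[c]] <- round(df[[c]], digits)
  df
}

#' Run the full risk-assessment pipeline and write a report bundle
#'
#' Executes the deterministic chain (summary statistics, soil screening,
#' transfer factors, EDI, THQ/HI, CR/TCR) on a concentration table and
#' writes one CSV per stage plus a machine-readable JSON report and a
#' manifest. Optional stages: Monte Carlo simulations (a list of argument
#' lists forwarded to [run_mc()], writing a percentile table) and source
#' apportionment (a sample x element matrix for [correlations()] and
#' [pca_varimax()]).
#'
#' Report CSVs round EDI/THQ-type quantities to 2 decimals — the precision
#' such tables are conventionally printed at — while `report.json` keeps
#' full precision. The manifest records the package version, seed and a
#' config fingerprint but no timestamp, so identical configurations
#' reproduce byte-identical bundles. Any stage failure aborts with the
#' stage name and removes partial outputs.
#'
#' @param table A [concentration_table()], default the bundled study means.
#' @param out_dir Output directory (created if absent).
#' @param scenarios,toxicity,limits,mtdi Registry overrides.
#' @param mc Optional list of [run_mc()] argument lists (the global `seed`
#'   is injected into each unless it sets its own).
#' @param sources Optional sample x element matrix for correlation/PCA.
#' @param seed Global seed propagated to stochastic stages.
#' @return Invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(table = study_means(), out_dir,
                         scenarios = default_scenarios(),
                         toxicity = default_toxicity(),
                         limits = default_limits(),
                         mtdi = default_mtdi(),
                         mc = NULL, sources = NULL, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
            class = "metalrisk_pipeline_error")
    })
  }

  paths <- list()
  stats <- stage("describe", summarize_concentrations(table))
  paths$summary_stats <- emit(stats, "summary_stats.csv")

  soil_stats <- dplyr::filter(stats, .data$medium == "soil")
  if (nrow(soil_stats) > 0) {
    paths$screening <- emit(stage("screen", screen_soil(soil_stats, limits)),
                            "screening.csv")
  }

  tf <- stage("tf", if (all(c("rice_grain", "soil") %in% stats$medium)) {
    transfer_factors(table)
  } else NULL)
  edi <- stage("edi", edi_table(table, scenarios, mtdi))
  tf_edi <- if (!is.null(tf)) {
    dplyr::full_join(
      dplyr::select(tf, "system", "element", "tf"),
      edi, by = c("system", "element"))
  } else edi
  paths$tf_edi <- emit(.round_cols(tf_edi, c("edi", "mc", "mtdi")), "tf_edi.csv")

  thq <- stage("risk", compute_thq(edi, toxicity))
  hi <- compute_hi(thq)
  cr <- compute_cr(edi, toxicity)
  tcr <- compute_tcr(cr)
  thq_hi <- thq |>
    dplyr::select("system", "food", "population", "element", "thq") |>
    tidyr::pivot_wider(names_from = "element", values_from = "thq") |>
    dplyr::left_join(dplyr::select(hi, "system", "food", "population", "hi"),
                     by = c("system", "food", "population"))
  paths$thq_hi <- emit(.round_cols(thq_hi, setdiff(names(thq_hi),
                                                   c("system", "food", "population"))),
                       "thq_hi.csv")
  paths$cr_tcr <- emit(dplyr::bind_rows(
    dplyr::select(cr, "system", "food", "population", "element", value = "cr",
                  "category"),
    dplyr::mutate(dplyr::select(tcr, "system", "food", "population",
                                value = "tcr", "category"),
                  element = "TOTAL")
  ), "cr_tcr.csv")

  mc_results <- NULL
  if (!is.null(mc)) {
    mc_results <- stage("mc", lapply(mc, function(args) {
      if (is.null(args$seed)) args$seed <- seed
      do.call(run_mc, args)
    }))
    pct <- dplyr::bind_rows(lapply(mc_results, function(r) {
      tibble::tibble(metric = r$metric,
                     keys = paste(unlist(r$keys), collapse = "/"),
                     mean = r$mean,
                     !!!setNames(as.list(r$percentiles),
                                 paste0("p", c(1, 5, 25, 50, 75, 95, 99))))
    }))
    paths$mc_percentiles <- emit(pct, "mc_percentiles.csv")
  }

  pca <- NULL
  if (!is.null(sources)) {
    corr <- stage("sources", correlations(sources))
    rdf <- tibble::as_tibble(corr$r, rownames = "variable")
    paths$correlation <- emit(rdf, "correlation.csv")
    pca <- stage("sources", pca_varimax(sources))
    pdf <- tibble::tibble(
      component = seq_along(pca$eigenvalues),
      eigenvalue = pca$eigenvalues,
      pct_variance = pca$variance_percent,
      cumulative_pct = pca$cumulative_percent
    )
    paths$pca <- emit(pdf, "pca.csv")
    if (pca$n_retained > 0) {
      paths$pca_loadings <- emit(
        dplyr::bind_cols(
          tibble::tibble(variable = rownames(pca$rotated_loadings)),
          tibble::as_tibble(pca$loadings),
          tibble::as_tibble(pca$rotated_loadings, .name_repair = function(x)
            paste0("rotated_", x))),
        "pca_loadings.csv")
    }
  }

  report <- list(
    summary_stats = stats, tf = tf, edi = edi,
    thq = thq, hi = dplyr::select(hi, -"contributions"),
    cr = cr, tcr = tcr
  )
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  written <- c(written, report_path)
  paths$report <- report_path

  config_sig <- .fnv1a(paste(
    nrow(table), paste(scenarios$vi, collapse = ","),
    paste(toxicity$rfd, collapse = ","), seed, collapse = "|"))
  manifest <- list(
    package = "metalrisk",
    version = as.character(utils::packageVersion("metalrisk")),
    seed = seed,
    config_hash = config_sig,
    n_records = nrow(table),
    outputs = basename(unlist(paths))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  paths$manifest <- manifest_path

  invisible(paths)
}
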