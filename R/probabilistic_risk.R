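# Monte Carlo propagation of parameter uncertainty through the risk formulas.

#' Describe an uncertain quantity
#'
#' A distribution specification: family plus its parameters, optionally
#' truncated to `[lower, upper]`. Families and parameters:
#' * `point`: `value`
#' * `normal`: `mean`, `sd`
#' * `lognormal`: either `meanlog`/`sdlog`, or arithmetic `mean`/`sd`
#'   (moment-matched: `sdlog^2 = log(1 + cv^2)`,
#'   `meanlog = log(mean) - sdlog^2/2`)
#' * `triangular`: `min`, `mode`, `max`
#' * `uniform`: `min`, `max`
#'
#' Truncation is enforced by inverse-CDF restriction, so draws never fall
#' outside the bounds.
#'
#' @param family Distribution family.
#' @param ... Family parameters (see above).
#' @param lower,upper Optional truncation bounds.
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(family = c("point", "normal", "lognormal",
                                 "triangular", "uniform"),
                      ..., lower = NULL, upper = NULL) {
  family <- match.arg(family)
  p <- list(...)
  bad <- function(msg) abort(paste0("invalid ", family, " spec: ", msg),
                             class = "metalrisk_spec_error")
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  switch(family,
    point = if (!num1(p$value)) bad("needs `value`"),
    normal = {
      if (!num1(p$mean) || !num1(p$sd)) bad("needs `mean` and `sd`")
      if (p$sd <= 0) bad("sd must be > 0")
    },
    lognormal = {
      if (num1(p$meanlog) && num1(p$sdlog)) {
        if (p$sdlog <= 0) bad("sdlog must be > 0")
      } else if (num1(p$mean) && num1(p$sd)) {
        if (p$mean <= 0 || p$sd <= 0) bad("mean and sd must be > 0")
        sdlog <- sqrt(log(1 + (p$sd / p$mean)^2))
        p <- list(meanlog = log(p$mean) - sdlog^2 / 2, sdlog = sdlog)
      } else bad("needs `meanlog`/`sdlog` or `mean`/`sd`")
    },
    triangular = {
      if (!num1(p$min) || !num1(p$mode) || !num1(p$max)) {
        bad("needs `min`, `mode`, `max`")
      }
      if (!(p$min <= p$mode && p$mode <= p$max && p$min < p$max)) {
        bad("requires min <= mode <= max and min < max")
      }
    },
    uniform = {
      if (!num1(p$min) || !num1(p$max)) bad("needs `min` and `max`")
      if (p$min >= p$max) bad("requires min < max")
    }
  )
  if (!is.null(lower) && !is.null(upper) && lower >= upper) {
    bad("truncation bounds must satisfy lower < upper")
  }
  structure(list(family = family, params = p, lower = lower, upper = upper),
            class = "dist_spec")
}

# triangular CDF / quantile (no base-R equivalent)
.ptri <- function(q, min, mode, max) {
  ifelse(q <= min, 0,
  ifelse(q >= max, 1,
  ifelse(q <= mode,
         (q - min)^2 / ((max - min) * (mode - min)),
         1 - (max - q)^2 / ((max - min) * (max - mode)))))
}

.qtri <- function(u, min, mode, max) {
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' Draw from a distribution specification
#'
#' Identical `seed` gives identical draws. Truncation is applied by drawing
#' uniforms restricted to `[F(lower), F(upper)]` and inverting the CDF, so
#' no draw ever violates the bounds and no resampling loop is needed.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (and advanced).
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  draw <- function() {
    p <- spec$params
    cdf <- switch(spec$family,
      point = NULL,
      normal = function(q) pnorm(q, p$mean, p$sd),
      lognormal = function(q) stats::plnorm(q, p$meanlog, p$sdlog),
      triangular = function(q) .ptri(q, p$min, p$mode, p$max),
      uniform = function(q) stats::punif(q, p$min, p$max)
    )
    qf <- switch(spec$family,
      point = NULL,
      normal = function(u) qnorm(u, p$mean, p$sd),
      lognormal = function(u) qlnorm(u, p$meanlog, p$sdlog),
      triangular = function(u) .qtri(u, p$min, p$mode, p$max),
      uniform = function(u) stats::qunif(u, p$min, p$max)
    )
    if (spec$family == "point") return(rep(p$value, n))
    lo <- if (is.null(spec$lower)) 0 else cdf(spec$lower)
    hi <- if (is.null(spec$upper)) 1 else cdf(spec$upper)
    if (hi <= lo) {
      abort("truncation interval has zero probability mass under the spec",
            class = "metalrisk_spec_error")
    }
    u <- runif(n, lo, hi)
    x <- qf(u)
    if (!is.null(spec$lower)) x <- pmax(x, spec$lower)
    if (!is.null(spec$upper)) x <- pmin(x, spec$upper)
    x
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Stable 32-bit hash of a quantity id, used to derive per-quantity seed
# substreams so adding a quantity never perturbs the draws of another.
.hash_id <- function(id) {
  h <- 0
  for (x in utf8ToInt(id)) h <- (h * 31 + x) %% 1000000007
  h
}

.substream <- function(seed, id) {
  as.integer((as.numeric(seed) + .hash_id(id)) %% 2147483629)
}

#' Monte Carlo risk simulation
#'
#' Propagates uncertainty in concentrations, ingestion rate and body weight
#' through the deterministic risk formulas: per iteration, every uncertain
#' quantity is drawn from its [dist_spec()] and the metric is evaluated with
#' the same equations as the deterministic pipeline (so degenerate
#' point-mass specs reproduce it exactly). Each quantity draws from its own
#' seed substream derived from the global `seed` by a stable hash of the
#' quantity id.
#'
#' @param metric One of `"THQ"`, `"HI"`, `"CR"`, `"TCR"`. `THQ`/`CR` require
#'   a single element; `HI`/`TCR` aggregate over all elements in
#'   `conc_specs` (for `TCR`, over the carcinogens among them).
#' @param conc_specs Named list, element symbol -> [dist_spec()] for the
#'   food concentration (mg/kg dry weight).
#' @param vi_spec,bw_spec [dist_spec()]s for ingestion rate (kg/day) and
#'   body weight (kg).
#' @param toxicity Toxicity registry, default [default_toxicity()].
#' @param ef,ed,at Exposure frequency/duration/averaging time; defaults
#'   EF = 365 d/y and AT = ED x 365 d make the EF*ED/AT factor 1.
#' @param keys Optional named list of labels (element, food, population,
#'   system) carried into the result.
#' @param n_iter Number of iterations, default 10000.
#' @param seed Global integer seed, default 1.
#' @param thresholds Exceedance thresholds; default 1 for THQ/HI and
#'   c(1e-6, 1e-4) for CR/TCR.
#' @param keep_draws Retain the raw draw vector (needed by [exceedance()]
#'   at ad-hoc thresholds). Default `TRUE`.
#' @return An object of class `mc_risk`: list with `metric`, `keys`,
#'   `n_iter`, `seed`, `mean`, `percentiles` (1, 5, 25, 50, 75, 95, 99),
#'   `exceedance` (named by threshold), and `draws` if retained.
#' @export
run_mc <- function(metric = c("THQ", "HI", "CR", "TCR"),
                   conc_specs, vi_spec, bw_spec,
                   toxicity = default_toxicity(),
                   ef = 365, ed = 1, at = ed * 365,
                   keys = list(),
                   n_iter = 10000, seed = 1,
                   thresholds = NULL, keep_draws = TRUE) {
  metric <- match.arg(metric)
  stopifnot(n_iter >= 1)
  if (is.null(names(conc_specs)) || any(names(conc_specs) == "")) {
    abort("`conc_specs` must be a named list (element -> dist_spec)",
          class = "metalrisk_config_error")
  }
  for (nm in names(conc_specs)) {
    if (!inherits(conc_specs[[nm]], "dist_spec")) {
      abort(paste0("missing or invalid distribution spec for concentration of ", nm),
            class = "metalrisk_config_error")
    }
  }
  if (!inherits(vi_spec, "dist_spec")) {
    abort("missing distribution spec for ingestion rate (vi_spec)",
          class = "metalrisk_config_error")
  }
  if (!inherits(bw_spec, "dist_spec")) {
    abort("missing distribution spec for body weight (bw_spec)",
          class = "metalrisk_config_error")
  }
  elements <- names(conc_specs)
  if (metric %in% c("THQ", "CR") && length(elements) != 1) {
    abort(paste0(metric, " is a per-element metric; give exactly one concentration spec"),
          class = "metalrisk_config_error")
  }
  tox <- toxicity[match(elements, toxicity$element), , drop = FALSE]
  if (metric %in% c("THQ", "HI")) {
    bad <- is.na(tox$rfd)
    if (any(bad)) {
      abort(paste0("no reference dose for element(s): ",
                   paste(elements[bad], collapse = ", ")),
            class = "metalrisk_config_error")
    }
  }
  if (metric == "CR" && (is.na(tox$sf[1]) || !tox$carcinogen[1])) {
    abort(paste0("element ", elements[1], " has no cancer slope factor"),
          class = "metalrisk_config_error")
  }
  if (metric == "TCR") {
    keep <- !is.na(tox$sf) & tox$carcinogen
    if (!any(keep)) {
      abort("no carcinogenic element among the concentration specs",
            class = "metalrisk_config_error")
    }
    elements <- elements[keep]
    tox <- tox[keep, , drop = FALSE]
  }

  vi <- sample_dist(vi_spec, n_iter, seed = .substream(seed, "vi"))
  bw <- sample_dist(bw_spec, n_iter, seed = .substream(seed, "bw"))
  mc <- vapply(elements, function(el) {
    sample_dist(conc_specs[[el]], n_iter, seed = .substream(seed, paste0("mc_", el)))
  }, numeric(n_iter))
  mc <- matrix(mc, nrow = n_iter,
               dimnames = list(NULL, elements))  # n_iter = 1 edge case

  edi <- (ef * ed * vi * mc) / (bw * at) * 1000  # ug/kg/day, recycled by column
  draws <- switch(metric,
    THQ = edi[, 1] / tox$rfd[1],
    HI = as.numeric(edi %*% (1 / tox$rfd)),
    CR = edi[, 1] / 1000 * tox$sf[1],
    TCR = as.numeric((edi / 1000) %*% tox$sf)
  )

  if (is.null(thresholds)) {
    thresholds <- if (metric %in% c("THQ", "HI")) 1 else c(1e-6, 1e-4)
  }
  probs <- c(1, 5, 25, 50, 75, 95, 99) / 100
  res <- list(
    metric = metric,
    keys = keys,
    n_iter = n_iter,
    seed = seed,
    mean = mean(draws),
    percentiles = quantile(draws, probs = probs, names = TRUE, type = 7),
    exceedance = setNames(vapply(thresholds, function(t) mean(draws > t),
                                 numeric(1)),
                          as.character(thresholds))
  )
  if (keep_draws) res$draws <- draws
  structure(res, class = "mc_risk")
}

#' @export
print.mc_risk <- function(x, ...) {
  cat("Monte Carlo risk simulation:", x$metric,
      if (length(x$keys)) paste0("(", paste(unlist(x$keys), collapse = ", "), ")"),
      "\n")
  cat("  iterations:", x$n_iter, " seed:", x$seed, "\n")
  cat("  mean:", signif(x$mean, 4), "\n")
  cat("  percentiles:\n")
  print(signif(x$percentiles, 4))
  cat("  exceedance:\n")
  print(signif(x$exceedance, 4))
  invisible(x)
}

#' Exceedance probability of a simulated risk metric
#'
#' Fraction of Monte Carlo draws strictly above `threshold`. Uses the
#' retained draw vector; if draws were discarded, only the thresholds
#' configured at simulation time are available.
#'
#' @param result An `mc_risk` object from [run_mc()].
#' @param threshold Risk threshold.
#' @return Probability in `[0, 1]`.
#' @export
exceedance <- function(result, threshold) {
  stopifnot(inherits(result, "mc_risk"))
  if (!is.null(result$draws)) return(mean(result$draws > threshold))
  key <- as.character(threshold)
  if (key %in% names(result$exceedance)) return(unname(result$exceedance[key]))
  abort("draws were not retained; rerun run_mc() with keep_draws = TRUE for ad-hoc thresholds",
        class = "metalrisk_config_error")
}

#' Empirical CDF curve of a simulated metric
#'
#' Convenience accessor for plotting cumulative-probability curves of the
#' simulated risk metric. The curve is non-decreasing and reaches 1.
#'
#' @param result An `mc_risk` object with retained draws.
#' @return Tibble with columns `value` (sorted draws) and `prob`.
#' @export
mc_cdf <- function(result) {
  stopifnot(inherits(result, "mc_risk"))
  if (is.null(result$draws)) {
    abort("draws were not retained; rerun run_mc() with keep_draws = TRUE",
          class = "metalrisk_config_error")
  }
  v <- sort(result$draws)
  tibble::tibble(value = v, prob = seq_along(v) / length(v))
}
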