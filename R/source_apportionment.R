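# Correlation and PCA diagnostics for pollution-source inference.

#' Pearson correlation matrix with two-tailed p-values
#'
#' Pairwise Pearson correlations over a sample x variable matrix, with
#' two-tailed p-values from the t transform
#' t = r sqrt((n-2)/(1-r^2)). Rows containing missing values are removed
#' listwise (with a message reporting how many).
#'
#' @param x Numeric matrix or data frame, samples in rows, variables
#'   (elements, optionally pH) in columns.
#' @return List of class `cor_result`: `r`, `p` (diagonal `NA`), `n`,
#'   `stars` (significance markers at 0.05 and 0.01).
#' @export
correlations <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) {
    abort("input must be numeric", class = "metalrisk_validation_error")
  }
  complete <- stats::complete.cases(x)
  if (any(!complete)) {
    inform(paste0("dropping ", sum(!complete), " row(s) with missing values"))
    x <- x[complete, , drop = FALSE]
  }
  n <- nrow(x)
  if (n < 3) {
    abort("need at least 3 complete rows for correlation analysis",
          class = "metalrisk_validation_error")
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant column(s): ",
                 paste(colnames(x)[sds == 0], collapse = ", ")),
          class = "metalrisk_validation_error")
  }
  r <- cor(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  structure(list(r = r, p = p, n = n, stars = stars), class = "cor_result")
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Measures whether a correlation matrix is factorable:
#' KMO = sum(r_ij^2) / (sum(r_ij^2) + sum(q_ij^2)) over i != j, where q are
#' the anti-image partial correlations obtained from the inverse of the
#' correlation matrix, q_ij = -s_ij / sqrt(s_ii s_jj) with S = R^-1.
#' Values above 0.7 conventionally indicate good adequacy.
#'
#' @param r Correlation matrix (invertible).
#' @param ridge Optional ridge added to the diagonal before inversion when
#'   `r` is numerically singular (default 0: fail instead).
#' @return List with `overall` KMO and `per_variable` MSA values.
#' @export
kmo <- function(r, ridge = 0) {
  r <- as.matrix(r)
  stopifnot(nrow(r) == ncol(r))
  rinv <- tryCatch(solve(r + diag(ridge, nrow(r))),
                   error = function(e) {
                     abort(paste0("correlation matrix is singular; consider the `ridge` ",
                                  "argument (", conditionMessage(e), ")"),
                           class = "metalrisk_validation_error")
                   })
  d <- 1 / sqrt(diag(rinv))
  q <- -rinv * tcrossprod(d)  # anti-image partial correlations
  diag(q) <- 0
  r2 <- r^2; diag(r2) <- 0
  q2 <- q^2
  denom_overall <- sum(r2) + sum(q2)
  if (denom_overall < .Machine$double.eps) {
    abort("KMO undefined: no off-diagonal correlation structure",
          class = "metalrisk_validation_error")
  }
  per <- colSums(r2) / (colSums(r2) + colSums(q2))
  list(overall = sum(r2) / denom_overall,
       per_variable = setNames(per, colnames(r)))
}

#' Bartlett test of sphericity
#'
#' Chi-square test of the null hypothesis that the correlation matrix is the
#' identity: chi2 = -(n - 1 - (2p + 5)/6) log det(R) with
#' df = p(p - 1)/2, upper-tail p-value.
#'
#' @param r Correlation matrix.
#' @param n Sample size used to estimate `r` (must exceed the number of
#'   variables).
#' @return List with `chi2`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(r, n) {
  r <- as.matrix(r)
  p <- nrow(r)
  stopifnot(p == ncol(r))
  if (n <= p) {
    abort("sample size must exceed the number of variables",
          class = "metalrisk_validation_error")
  }
  detr <- det(r)
  if (detr <= 0) {
    abort("correlation matrix is not positive definite",
          class = "metalrisk_validation_error")
  }
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detr)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df, p_value = pchisq(chi2, df, lower.tail = FALSE))
}

# flip each loading column so its largest-magnitude entry is positive
.fix_signs <- function(l) {
  if (ncol(l) == 0) return(l)
  signs <- apply(l, 2, function(col) sign(col[which.max(abs(col))]))
  signs[signs == 0] <- 1
  sweep(l, 2, signs, `*`)
}

#' PCA with Kaiser retention and varimax rotation
#'
#' Principal component analysis of the correlation matrix: eigenvalues (sum
#' = number of variables), percent and cumulative variance explained,
#' loadings (eigenvector x sqrt(eigenvalue)) for the components retained by
#' the strict Kaiser rule (eigenvalue > 1; exactly 1 is dropped), and
#' varimax rotation with Kaiser normalization of the retained loadings.
#' Rotation preserves per-variable communalities. Each loading column is
#' sign-flipped so its largest-magnitude entry is positive. When data (not a
#' correlation matrix) are supplied, KMO and Bartlett diagnostics are
#' attached.
#'
#' @param x Either a sample x variable data matrix/data frame, or a
#'   correlation matrix (detected as square, symmetric, unit diagonal —
#'   override with `is_correlation`).
#' @param n Sample size (required for Bartlett when `x` is a correlation
#'   matrix; inferred from data otherwise).
#' @param is_correlation Force interpretation of `x`.
#' @return Object of class `pca_result`: `eigenvalues`, `variance_percent`,
#'   `cumulative_percent`, `n_retained`, `loadings`, `rotated_loadings`,
#'   `communalities`, `kmo`, `bartlett` (the last two `NULL` when not
#'   computable).
#' @export
pca_varimax <- function(x, n = NULL, is_correlation = NULL) {
  x <- as.matrix(x)
  if (is.null(is_correlation)) {
    is_correlation <- nrow(x) == ncol(x) &&
      isTRUE(all.equal(unname(x), unname(t(x)), tolerance = 1e-8)) &&
      isTRUE(all.equal(unname(diag(x)), rep(1, nrow(x)), tolerance = 1e-8))
  }
  if (is_correlation) {
    r <- x
  } else {
    n <- nrow(x)
    r <- cor(x)
  }
  p <- ncol(r)
  eig <- eigen(r, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  variance_percent <- ev / p * 100
  k <- sum(ev > 1)
  vars <- colnames(r) %||% paste0("V", seq_len(p))
  if (k == 0) {
    warn("no component has eigenvalue > 1; zero components retained")
    loadings <- rotated <- matrix(numeric(0), nrow = p, ncol = 0,
                                  dimnames = list(vars, NULL))
  } else {
    loadings <- eig$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(ev[seq_len(k)]), k)
    dimnames(loadings) <- list(vars, paste0("PC", seq_len(k)))
    loadings <- .fix_signs(loadings)
    if (k >= 2) {
      rot <- varimax(loadings, normalize = TRUE)
      rotated <- .fix_signs(unclass(rot$loadings)[, , drop = FALSE])
      dimnames(rotated) <- dimnames(loadings)
    } else {
      rotated <- loadings
    }
  }
  res <- list(
    eigenvalues = ev,
    variance_percent = variance_percent,
    cumulative_percent = cumsum(variance_percent),
    n_retained = k,
    loadings = loadings,
    rotated_loadings = rotated,
    communalities = setNames(rowSums(loadings^2), vars),
    kmo = if (p >= 2) tryCatch(kmo(r), error = function(e) NULL),
    bartlett = if (!is.null(n)) tryCatch(bartlett_sphericity(r, n),
                                         error = function(e) NULL)
  )
  structure(res, class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA of correlation matrix:", length(x$eigenvalues), "variables,",
      x$n_retained, "component(s) retained (eigenvalue > 1)\n")
  tab <- data.frame(eigenvalue = round(x$eigenvalues, 3),
                    pct_variance = round(x$variance_percent, 3),
                    cumulative_pct = round(x$cumulative_percent, 3))
  print(tab)
  if (!is.null(x$kmo)) cat("KMO:", round(x$kmo$overall, 3), "\n")
  if (!is.null(x$bartlett)) {
    cat("Bartlett sphericity: chi2 =", round(x$bartlett$chi2, 2),
        "df =", x$bartlett$df, "p =", signif(x$bartlett$p_value, 3), "\n")
  }
  if (x$n_retained > 0) {
    cat("Rotated loadings (varimax, Kaiser normalization):\n")
    print(round(x$rotated_loadings, 3))
  }
  invisible(x)
}
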