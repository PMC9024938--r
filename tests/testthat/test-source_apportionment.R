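test_that("Pearson correlations and p-values follow the t transform", {
  x <- cbind(a = c(1, 2, 3), b = c(6, 4, 5))
  res <- correlations(x)
  expect_equal(res$r["a", "b"], -0.5)   # hand computation
  expect_equal(res$n, 3)
  # p from t = r sqrt((n-2)/(1-r^2)) with df = 1
  t <- -0.5 * sqrt(1 / 0.75)
  expect_equal(res$p["a", "b"], 2 * pt(-abs(t), df = 1))

  # exact linear dependence
  y <- cbind(a = 1:5, b = 2 * (1:5) + 1)
  expect_equal(correlations(y)$r["a", "b"], 1)

  # invariance under affine transforms of one variable (up to sign)
  z <- withr::with_seed(1, matrix(rnorm(60), ncol = 3,
                                  dimnames = list(NULL, c("u", "v", "w"))))
  z2 <- z; z2[, "v"] <- -3 * z2[, "v"] + 7
  expect_equal(abs(correlations(z2)$r["u", "v"]),
               abs(correlations(z)$r["u", "v"]))
})

test_that("correlation preconditions and diagnostics are enforced", {
  expect_error(correlations(cbind(a = c(1, 1, 1), b = 1:3)), "a",
               class = "metalrisk_validation_error")
  expect_error(correlations(cbind(a = 1:2, b = 2:1)),
               class = "metalrisk_validation_error")
  withna <- cbind(a = c(1, 2, NA, 4, 3), b = c(2, 1, 5, 3, 4))
  expect_message(res <- correlations(withna), "1 row")
  expect_equal(res$n, 4)
  # significance stars reproducible from p
  big <- withr::with_seed(2, {
    f <- rnorm(100)
    cbind(p = f + rnorm(100, sd = 0.3), q = f + rnorm(100, sd = 0.3),
          r = rnorm(100))
  })
  res2 <- correlations(big)
  expect_equal(res2$stars == "**", !is.na(res2$p) & res2$p < 0.01)
})

test_that("synthetic data recover a published target correlation", {
  tg <- preset_targets("rcs_soil", n = 1000, seed = 21)
  tbl <- tibble::as_tibble(generate_concentrations(tg))
  wide <- tidyr::pivot_wider(tbl[c("sample_id", "element", "value")],
                             names_from = "element", values_from = "value")
  r <- correlations(as.matrix(wide[-1]))$r
  expect_lt(abs(r["Ni", "Cr"] - 0.962), 0.05)
})

test_that("KMO agrees with a brute-force partial-correlation oracle", {
  # 3 variables, all pairwise r = 0.5: partial corr of each pair given the
  # third is (0.5 - 0.25) / (1 - 0.25) = 1/3, so
  # KMO = 6*0.25 / (6*0.25 + 6*(1/9))
  r <- matrix(0.5, 3, 3); diag(r) <- 1
  dimnames(r) <- list(letters[1:3], letters[1:3])
  partial <- (0.5 - 0.5 * 0.5) / sqrt((1 - 0.25) * (1 - 0.25))
  oracle <- (6 * 0.5^2) / (6 * 0.5^2 + 6 * partial^2)
  res <- kmo(r)
  expect_equal(res$overall, oracle)
  expect_equal(unname(res$per_variable), rep(oracle, 3))

  # invariant under variable reordering
  perm <- c(3, 1, 2)
  expect_equal(kmo(r[perm, perm])$overall, oracle)

  # two near-perfectly-correlated independent pairs: partials saturate, KMO low
  r2 <- diag(4)
  r2[1, 2] <- r2[2, 1] <- 0.99
  r2[3, 4] <- r2[4, 3] <- 0.99
  expect_lt(kmo(r2)$overall, 0.6)

  # identity matrix: no correlation structure, KMO undefined
  expect_error(kmo(diag(3)), class = "metalrisk_validation_error")
  # singular matrix: error mentioning the ridge option
  sing <- matrix(1, 2, 2)
  expect_error(kmo(sing), "ridge", class = "metalrisk_validation_error")
})

test_that("Bartlett sphericity matches its closed form", {
  id <- bartlett_sphericity(diag(4), n = 30)
  expect_equal(id$chi2, 0)
  expect_equal(id$p_value, 1)
  expect_equal(id$df, 6)

  # hand evaluation: p = 2, r = 0.5, n = 50
  r <- matrix(c(1, 0.5, 0.5, 1), 2)
  res <- bartlett_sphericity(r, n = 50)
  expect_equal(res$chi2, -(49 - 9 / 6) * log(0.75))
  expect_equal(res$df, 1)

  expect_error(bartlett_sphericity(diag(5), n = 4),
               class = "metalrisk_validation_error")
  neg <- matrix(c(1, 1, 1, 1), 2)
  expect_error(bartlett_sphericity(neg, n = 10),
               class = "metalrisk_validation_error")
})

test_that("correlation-matrix PCA has the closed-form 2x2 solution", {
  r <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  res <- pca_varimax(r)
  expect_equal(res$eigenvalues, c(1.8, 0.2))       # 1 +/- r
  expect_equal(res$n_retained, 1)
  expect_equal(res$variance_percent[1], 90)
  expect_equal(sum(res$eigenvalues), 2)

  # identity correlation: all eigenvalues exactly 1, strict Kaiser retains none
  expect_warning(none <- pca_varimax(diag(5)), "zero components")
  expect_equal(none$n_retained, 0)
  expect_equal(ncol(none$loadings), 0)
})

test_that("varimax preserves communalities and uses an orthogonal rotation", {
  x <- generate_factor_data(
    loadings = matrix(c(0.9, 0.85, 0.8, 0, 0, 0, 0, 0,
                        0, 0, 0, 0.9, 0.85, 0, 0, 0,
                        0, 0, 0, 0, 0, 0.9, 0.85, 0.8), ncol = 3),
    noise_sd = 0.4, n = 500, seed = 13)
  res <- pca_varimax(x)
  expect_gte(res$n_retained, 2)
  pre <- rowSums(res$loadings^2)
  post <- rowSums(res$rotated_loadings^2)
  expect_lt(max(abs(pre - post)), 1e-8)
  # eigenvalue sum = variable count; variance percentages sum to 100
  expect_equal(sum(res$eigenvalues), ncol(x))
  expect_equal(sum(res$variance_percent), 100)
  # sign convention: largest-magnitude entry of each column positive
  for (j in seq_len(ncol(res$rotated_loadings))) {
    col <- res$rotated_loadings[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
})

test_that("PCA recovers a planted three-factor structure", {
  L <- matrix(0, nrow = 8, ncol = 3)
  L[1:3, 1] <- c(0.9, 0.85, 0.8)
  L[4:6, 2] <- c(0.9, 0.85, 0.8)
  L[7:8, 3] <- c(0.9, 0.85)
  x <- generate_factor_data(L, noise_sd = 0.35, n = 2000, seed = 17)
  res <- pca_varimax(x)
  expect_equal(res$n_retained, 3)
  expect_true(all(match_congruence(L, res$rotated_loadings) >= 0.95))
  # diagnostics attached when raw data are supplied
  expect_gt(res$kmo$overall, 0.5)
  expect_lt(res$bartlett$p_value, 0.05)
})
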