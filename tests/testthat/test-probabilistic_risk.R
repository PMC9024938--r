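test_that("distribution specs validate parameters before any sampling", {
  expect_error(dist_spec("normal", mean = 1, sd = 0),
               class = "metalrisk_spec_error")
  expect_error(dist_spec("uniform", min = 2, max = 1),
               class = "metalrisk_spec_error")
  expect_error(dist_spec("triangular", min = 0, mode = 3, max = 2),
               class = "metalrisk_spec_error")
  expect_error(dist_spec("lognormal", mean = -1, sd = 1),
               class = "metalrisk_spec_error")
  expect_error(dist_spec("normal", mean = 0, sd = 1, lower = 2, upper = 1),
               class = "metalrisk_spec_error")
})

test_that("sampling is seed-deterministic and honors each family's moments", {
  expect_equal(sample_dist(dist_spec("point", value = 3), 5), rep(3, 5))

  u <- sample_dist(dist_spec("uniform", min = 0, max = 1), 1e4, seed = 5)
  expect_lt(abs(mean(u) - 0.5), 3 * (1 / sqrt(12)) / 100)

  # lognormal moment-matched to arithmetic mean 0.08, sd 0.02
  ln <- sample_dist(dist_spec("lognormal", mean = 0.08, sd = 0.02),
                    1e4, seed = 5)
  expect_lt(abs(mean(ln) - 0.08), 3 * 0.02 / 100)
  expect_lt(abs(sd(ln) - 0.02) / 0.02, 0.05)
  expect_true(all(ln > 0))

  # identical seed, identical draws; different seed, different draws
  s1 <- sample_dist(dist_spec("normal", mean = 70, sd = 5), 100, seed = 9)
  s2 <- sample_dist(dist_spec("normal", mean = 70, sd = 5), 100, seed = 9)
  expect_identical(s1, s2)
  expect_false(identical(
    s1, sample_dist(dist_spec("normal", mean = 70, sd = 5), 100, seed = 10)))
})

test_that("truncation never yields out-of-bound draws", {
  tn <- sample_dist(dist_spec("normal", mean = 0, sd = 1, lower = 0),
                    5000, seed = 2)
  expect_true(all(tn >= 0))
  tt <- sample_dist(dist_spec("triangular", min = 0, mode = 1, max = 3,
                              lower = 0.5, upper = 2), 5000, seed = 2)
  expect_true(all(tt >= 0.5 & tt <= 2))
  # truncated-normal mean oracle: E[X | X > 0] for N(0,1) is sqrt(2/pi)
  expect_lt(abs(mean(tn) - sqrt(2 / pi)), 3 * 0.6 / sqrt(5000))
})

test_that("point-mass Monte Carlo collapses to the deterministic pipeline", {
  means <- study_means()
  rows <- tibble::as_tibble(means)
  cray <- rows[rows$medium == "crayfish_muscle", ]
  specs <- lapply(setNames(cray$value, cray$element),
                  function(v) dist_spec("point", value = v))
  res <- run_mc("HI", conc_specs = specs,
                vi_spec = dist_spec("point", value = 0.0555),
                bw_spec = dist_spec("point", value = 70),
                ed = 77, n_iter = 200, seed = 1)
  det <- risk_assessment(means)
  hi_det <- det$hi$hi[det$hi$food == "crayfish" & det$hi$population == "adult"]
  expect_equal(unname(res$percentiles), rep(hi_det, 7))
  expect_equal(res$mean, hi_det)
  expect_equal(unname(res$exceedance["1"]), 0)

  # TCR point-mass collapse as well
  tcr <- run_mc("TCR", conc_specs = specs,
                vi_spec = dist_spec("point", value = 0.0555),
                bw_spec = dist_spec("point", value = 70),
                ed = 77, n_iter = 50, seed = 1)
  tcr_det <- det$tcr$tcr[det$tcr$food == "crayfish" &
                           det$tcr$population == "adult"]
  expect_equal(tcr$mean, tcr_det)
})

test_that("simulated THQ matches the analytic scaled-lognormal quantiles", {
  # THQ = c * MC with c = VI/BW*1000/RfD when only MC is uncertain
  meanlog <- log(0.04); sdlog <- 0.4
  res <- run_mc("THQ",
                conc_specs = list(As = dist_spec("lognormal",
                                                 meanlog = meanlog,
                                                 sdlog = sdlog)),
                vi_spec = dist_spec("point", value = 0.337),
                bw_spec = dist_spec("point", value = 70),
                ed = 77, n_iter = 1e4, seed = 3)
  cc <- 0.337 / 70 * 1000 / 0.3
  probs <- c(1, 5, 25, 50, 75, 95, 99) / 100
  analytic <- cc * qlnorm(probs, meanlog, sdlog)
  expect_equal(unname(res$percentiles), analytic, tolerance = 0.05)
  # quantiles non-decreasing; CDF curve non-decreasing and reaching 1
  expect_true(!is.unsorted(res$percentiles))
  cdf <- mc_cdf(res)
  expect_true(!is.unsorted(cdf$prob))
  expect_equal(max(cdf$prob), 1)
})

test_that("MC means of linear metrics converge to the closed form", {
  # CR of Cd for adult rice intake, lognormal concentration, normal BW
  res <- run_mc("CR",
                conc_specs = list(Cd = dist_spec("lognormal", mean = 0.025,
                                                 sd = 0.005)),
                vi_spec = dist_spec("point", value = 0.337),
                bw_spec = dist_spec("point", value = 70),
                ed = 77, n_iter = 1e4, seed = 8)
  closed <- 0.025 * 0.337 / 70 * 1000 / 1000 * 15
  se <- sd(res$draws) / sqrt(res$n_iter)
  expect_lt(abs(res$mean - closed), 3 * se)
})

test_that("simulations are reproducible and validated up front", {
  cfg <- list(As = dist_spec("lognormal", mean = 0.134, sd = 0.03))
  r1 <- run_mc("THQ", conc_specs = cfg,
               vi_spec = dist_spec("normal", mean = 0.0555, sd = 0.005,
                                   lower = 0),
               bw_spec = dist_spec("normal", mean = 70, sd = 10, lower = 0),
               ed = 77, n_iter = 2000, seed = 4)
  r2 <- run_mc("THQ", conc_specs = cfg,
               vi_spec = dist_spec("normal", mean = 0.0555, sd = 0.005,
                                   lower = 0),
               bw_spec = dist_spec("normal", mean = 70, sd = 10, lower = 0),
               ed = 77, n_iter = 2000, seed = 4)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$percentiles, r2$percentiles)

  # missing/invalid specs are named configuration errors before simulation
  expect_error(run_mc("THQ", conc_specs = list(As = "not a spec"),
                      vi_spec = dist_spec("point", value = 0.1),
                      bw_spec = dist_spec("point", value = 70)),
               "As", class = "metalrisk_config_error")
  expect_error(run_mc("HI", conc_specs = cfg,
                      vi_spec = NULL,
                      bw_spec = dist_spec("point", value = 70)),
               class = "metalrisk_config_error")
  # THQ needs an RfD, CR needs a slope factor
  expect_error(run_mc("CR", conc_specs = list(Zn = dist_spec("point", value = 1)),
                      vi_spec = dist_spec("point", value = 0.1),
                      bw_spec = dist_spec("point", value = 70)),
               "Zn", class = "metalrisk_config_error")
})

test_that("exceedance is the fraction of draws strictly above the threshold", {
  fake <- structure(list(draws = c(0.5, 1.5, 2.0)), class = "mc_risk")
  expect_equal(exceedance(fake, 1), 2 / 3)

  # point mass at THQ = 0.337/70*1000*0.04/0.3 ~ 0.64: never exceeds 1
  point <- run_mc("THQ",
                  conc_specs = list(As = dist_spec("point", value = 0.04)),
                  vi_spec = dist_spec("point", value = 0.337),
                  bw_spec = dist_spec("point", value = 70),
                  n_iter = 100, seed = 1)
  expect_equal(exceedance(point, 1), 0)

  # lognormal THQ whose median is exactly 1: exceedance ~ 0.5
  cc <- 0.337 / 70 * 1000 / 0.3
  res <- run_mc("THQ",
                conc_specs = list(As = dist_spec("lognormal",
                                                 meanlog = log(1 / cc),
                                                 sdlog = 0.5)),
                vi_spec = dist_spec("point", value = 0.337),
                bw_spec = dist_spec("point", value = 70),
                n_iter = 1e4, seed = 6)
  expect_lt(abs(exceedance(res, 1) - 0.5), 3 * 0.5 / sqrt(1e4))

  # summaries-only object still answers configured thresholds, else errors
  slim <- run_mc("HI", conc_specs = list(As = dist_spec("point", value = 0.04)),
                 vi_spec = dist_spec("point", value = 0.337),
                 bw_spec = dist_spec("point", value = 70),
                 n_iter = 10, seed = 1, keep_draws = FALSE)
  expect_equal(exceedance(slim, 1), 0)
  expect_error(exceedance(slim, 0.123), class = "metalrisk_config_error")
})
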