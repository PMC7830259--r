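csa_levels <- c(1.806, 2.408, 3.612, 4.816, 6.02, 6.622)
cms_levels <- c(2, 6, 8, 12, 16, 20, 22)
csa_truth <- function(x) 130.1 * x - 195.3
cms_truth <- function(x) 1.425 * x^2 + 20.97 * x + 131.6

test_that("calibration fits recover exact generating polynomials", {
  lin <- fit_calibration(csa_levels, csa_truth(csa_levels), order = 1)
  expect_equal(unname(lin$coefficients), c(-195.3, 130.1), tolerance = 1e-9)
  expect_equal(lin$r_squared, 1, tolerance = 1e-12)
  expect_equal(lin$range, c(1.806, 6.622))

  quad <- fit_calibration(cms_levels, cms_truth(cms_levels), order = 2)
  expect_equal(unname(quad$coefficients), c(131.6, 20.97, 1.425),
               tolerance = 1e-9)
})

test_that("misspecified linear fit of quadratic data shows curvature", {
  lin <- fit_calibration(cms_levels, cms_truth(cms_levels), order = 1)
  expect_lt(lin$r_squared, 1)
  r <- resid(lin$lm)
  # residuals convex: positive at the ends, negative in the middle
  expect_gt(r[1], 0); expect_gt(r[length(r)], 0)
  expect_lt(min(r), 0)
})

test_that("calibration errors on bad designs", {
  expect_error(fit_calibration(c(1, 2, 3), c(1, 2, 3), order = 2), "at least 4")
  expect_error(fit_calibration(rep(5, 6), rnorm(6), order = 1), "design error")
  expect_error(fit_calibration(c(-1, 2, 3, 4), 1:4, order = 1), "positive")
})

test_that("reported coefficient SEs agree with Monte-Carlo spread", {
  est <- t(vapply(1:500, function(s) {
    set.seed(s)
    f <- fit_calibration(cms_levels, csa_truth(cms_levels) + rnorm(7, 0, 20), 1)
    c(f$coefficients, f$se)
  }, numeric(4)))
  mc_sd <- apply(est[, 1:2], 2, sd)
  mean_se <- colMeans(est[, 3:4])
  expect_true(all(abs(mean_se - mc_sd) / mc_sd < 0.20))
})

test_that("pooling F test: no between-curve variation gives F = 0, p = 1", {
  d <- data.frame(concentration = cms_levels,
                  response = csa_truth(cms_levels) + c(3, -2, 1, 0, -1, 2, -3))
  res <- pool_curves_f_test(list(d, d, d), order = 1)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_true(res$pool_supported)
})

test_that("pooling F test keeps its type-I and power behaviour", {
  mu <- csa_truth(cms_levels)
  p_null <- vapply(1:200, function(s) {
    set.seed(s)
    cur <- lapply(1:3, function(r)
      data.frame(concentration = cms_levels, response = mu + rnorm(7, 0, 20)))
    pool_curves_f_test(cur, 1)$p
  }, numeric(1))
  expect_gte(mean(p_null > 0.05), 0.90)

  # slopes differing by 5 slope-SEs must usually be detected
  se_slope <- 1.35  # typical slope SE at noise_sd = 20 on this design
  p_alt <- vapply(1:200, function(s) {
    set.seed(s)
    cur <- lapply(1:3, function(r)
      data.frame(concentration = cms_levels,
                 response = (130.1 + (r - 2) * 5 * se_slope) * cms_levels -
                            195.3 + rnorm(7, 0, 20)))
    pool_curves_f_test(cur, 1)$p
  }, numeric(1))
  expect_gte(mean(p_alt < 0.05), 0.90)
})

test_that("pooled SS is never below the sum of separate SS", {
  for (s in 1:20) {
    set.seed(s)
    cur <- lapply(1:3, function(r)
      data.frame(concentration = cms_levels,
                 response = csa_truth(cms_levels) + rnorm(7, 0, 20)))
    res <- pool_curves_f_test(cur, 1)
    expect_gte(res$ss_pooled, res$ss_separate - 1e-9)
  }
})

test_that("LOD/LOQ arithmetic and ratio", {
  expect_equal(unname(lod_loq(1, 10)), c(0.33, 1.0))
  expect_equal(unname(lod_loq(0, 5)), c(0, 0))
  # the tabulated CSA pair: LOD 0.29 implies LOQ 0.88 at the 10/3.3 ratio
  sigma_csa <- 0.29 * 130.1 / 3.3
  ll <- lod_loq(sigma_csa, 130.1)
  expect_equal(round(unname(ll), 2), c(0.29, 0.88))
  expect_equal(unname(ll["LOQ"] / ll["LOD"]), 10 / 3.3, tolerance = 1e-12)
  expect_error(lod_loq(1, 0), "> 0")
})

test_that("sigma conventions for LOD/LOQ", {
  conc <- rep(csa_levels, each = 3)
  set.seed(9)
  resp <- csa_truth(conc) + rnorm(length(conc), 0, 15)
  s_low <- calibration_sigma(conc, resp, "lowest_level")
  expect_equal(s_low, sd(resp[conc == min(conc)]))
  curve <- fit_calibration(conc, resp, 1)
  expect_equal(calibration_sigma(conc, resp, "residual", curve),
               curve$sigma_resid)
  expect_error(calibration_sigma(csa_levels, csa_truth(csa_levels),
                                 "lowest_level"), "single replicate")
})

test_that("linear-part slope of the quadratic curve uses the lowest levels", {
  resp <- cms_truth(cms_levels)
  sl <- linear_range_slope(cms_levels, resp, n_levels = 3)
  # exact OLS slope over levels 2, 6, 8 of the quadratic truth
  keep <- cms_levels <= 8
  expect_equal(sl, unname(coef(lm(resp[keep] ~ cms_levels[keep]))[2]))
  expect_error(linear_range_slope(c(1, 2), 1:2, 3), "distinct levels")
})

test_that("colistin A/B partition conserves mass at the reference split", {
  expect_equal(unname(partition_cs(22)), c(6.622, 15.378))
  expect_equal(unname(partition_cs(16)), c(4.816, 11.184))
  expect_equal(unname(partition_cs(0)), c(0, 0))
  set.seed(3)
  tot <- runif(50, 0, 60)
  for (f in c(0.2, 0.301, 0.7)) {
    p <- vapply(tot, partition_cs, numeric(2), csa_fraction = f)
    expect_equal(colSums(p), tot)
  }
  expect_error(partition_cs(10, 1.2), "inside")
})

test_that("indirect CMS determination is the CS difference with guards", {
  expect_equal(as.numeric(indirect_cms(10, 4)), 6)
  expect_equal(as.numeric(indirect_cms(10, 10)), 0)
  expect_error(indirect_cms(10, 11), "negative CMS|inconsistency")
  # completeness caveat from the kinetic model of the protocol
  ok <- indirect_cms(10, 4, hydrolysis = list(
    params = reversible_rates(0.4485, 0.00211), duration_min = 10))
  expect_false(attr(ok, "incomplete_hydrolysis"))
  expect_warning(
    bad <- indirect_cms(10, 4, hydrolysis = list(
      params = reversible_rates(0.0003), duration_min = 60)),
    "unconverted")
  expect_true(attr(bad, "incomplete_hydrolysis"))
})

test_that("calibration inversion is the identity on the fitted range", {
  lin <- fit_calibration(csa_levels, csa_truth(csa_levels), 1)
  expect_equal(invert_calibration(lin, csa_truth(5)), 5, tolerance = 1e-9)
  quad <- fit_calibration(cms_levels, cms_truth(cms_levels), 2)
  expect_equal(invert_calibration(quad, predict(quad, 22)), 22,
               tolerance = 1e-9)
  xs <- seq(2, 22, length.out = 25)
  expect_equal(invert_calibration(quad, predict(quad, xs)), xs,
               tolerance = 1e-9)
  expect_error(invert_calibration(quad, predict(quad, 2) - 1e3),
               "outside the curve")
})

test_that("accuracy and precision summaries behave at the extremes", {
  perfect <- expand.grid(level = c(2, 6), run = 1:3, rep = 1:3)
  perfect$value <- perfect$level
  v <- accuracy_precision(perfect)
  expect_equal(v$per_level$accuracy_pct_error, c(0, 0))
  expect_equal(v$per_level$repeatability_pct_rsd, c(0, 0))
  expect_equal(v$per_level$intermediate_pct_rsd, c(0, 0))

  # seed-fixed 3x3 table with 2% noise: %RSD lands in a plausible band
  set.seed(11)
  tab <- expand.grid(level = c(2, 8, 22), run = 1:3, rep = 1:3)
  tab$value <- tab$level * (1 + rnorm(nrow(tab), 0, 0.02))
  v2 <- accuracy_precision(tab)
  expect_true(all(v2$per_level$repeatability_pct_rsd >= 0.5 &
                  v2$per_level$repeatability_pct_rsd <= 5))

  # single replicate per cell: precision missing, not zero
  single <- data.frame(level = 2, run = 1, value = 2.1)
  v3 <- accuracy_precision(single)
  expect_true(is.na(v3$per_level$repeatability_pct_rsd))
  expect_error(accuracy_precision(data.frame(level = 0, run = 1, value = 1)),
               "undefined")
})
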