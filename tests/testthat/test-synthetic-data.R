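test_that("decay series are deterministic under seed and independent across T", {
  d <- study_design(seed = 7)
  a <- generate_decay_series(d, 60)
  b <- generate_decay_series(d, 60)
  expect_identical(a$value, b$value)
  c50 <- generate_decay_series(d, 50)
  expect_false(identical(a$value[-1] / remaining_pct(100, attr(a, "truth"), a$time_min)[-1],
                         c50$value[-1] / remaining_pct(100, attr(c50, "truth"), c50$time_min)[-1]))
  d2 <- study_design(seed = 8)
  expect_false(identical(a$value, generate_decay_series(d2, 60)$value))
  expect_error(generate_decay_series(d, 35), "not part of the design")
})

test_that("noiseless generation equals the closed form with t0 pinned at 100", {
  d <- study_design(seed = 1, noise_cv = 0)
  for (T in c(40, 50, 60)) {
    s <- generate_decay_series(d, T)
    expect_equal(s$value, remaining_pct(100, attr(s, "truth"), s$time_min))
    expect_equal(s$value[1], 100)
  }
  # noisy series still start at exactly 100
  s60 <- generate_decay_series(study_design(seed = 2), 60)
  expect_equal(s60$value[1], 100)
})

test_that("60 degC run ends below 10% remaining", {
  for (seed in 1:10) {
    s <- generate_decay_series(study_design(seed = seed), 60)
    expect_lt(s$value[length(s$value)], 10)
  }
})

test_that("calibration generator reproduces truth in the noiseless limit", {
  levels <- c(2, 6, 8, 12, 16, 20, 22)
  tab <- generate_calibration_set(c(-195.3, 130.1), levels, n_runs = 2,
                                  noise_sd = 0, seed = 1)
  f <- fit_calibration(tab$concentration, tab$response, 1)
  expect_equal(unname(f$coefficients), c(-195.3, 130.1), tolerance = 1e-9)
  # determinism
  t1 <- generate_calibration_set(c(-195.3, 130.1), levels, 3, 20, seed = 5)
  t2 <- generate_calibration_set(c(-195.3, 130.1), levels, 3, 20, seed = 5)
  expect_identical(t1$response, t2$response)
  expect_warning(generate_calibration_set(c(0, 1), c(1, 30), 1, 0, 1,
                                          range = c(2, 22)), "outside")
})

test_that("CS calibration levels derive from totals via the 30.1% split", {
  b <- generate_full_study(study_design(seed = 2))
  csa_levels <- sort(unique(b$calibration$CSA$concentration))
  expect_equal(max(csa_levels), 6.622)
  expect_equal(csa_levels, c(1.806, 2.408, 3.612, 4.816, 6.02, 6.622))
  csb_levels <- sort(unique(b$calibration$CSB$concentration))
  expect_equal(csb_levels, c(4.194, 5.592, 8.388, 11.184, 13.98, 15.378))
  expect_equal(sort(unique(b$calibration$CMS$concentration)),
               c(2, 6, 8, 12, 16, 20, 22))
})

test_that("noiseless end-to-end pipeline is an identity on the truth", {
  d0 <- study_design(seed = 1, noise_cv = 0)
  b0 <- generate_full_study(d0, calibration_noise_sd = 0)
  f0 <- analyze_hydrolysis_study(b0$series)
  truth <- d0$arrhenius_truth
  expect_equal(coef(f0$arrhenius)[["Ea"]], truth[["Ea"]], tolerance = 1e-6)
  expect_equal(coef(f0$arrhenius)[["lnA"]], truth[["lnA"]], tolerance = 1e-6)
  for (nm in names(b0$series)) {
    tr <- attr(b0$series[[nm]], "truth")
    est <- coef(f0$reversible[[nm]])
    expect_equal(est[["k_forward"]], tr$k_forward,
                 tolerance = 1e-4, label = nm)
    if (tr$k_reverse > 0) {
      expect_equal(est[["k_reverse"]], tr$k_reverse, tolerance = 1e-4,
                   label = paste(nm, "k_reverse"))
    } else {
      expect_lte(est[["k_reverse"]], 1e-6)
    }
  }
})

test_that("noisy end-to-end run recovers Ea within 5%", {
  d <- study_design(seed = 42)
  b <- generate_full_study(d)
  f <- suppressWarnings(analyze_hydrolysis_study(b$series))
  expect_equal(coef(f$arrhenius)[["Ea"]], d$arrhenius_truth[["Ea"]],
               tolerance = 0.05)
  # verification error at 20 degC is small under the design conditions
  expect_lt(abs(f$verification$pct_error), 0.25)
})

test_that("full-study bundle writes and re-reads losslessly", {
  dir <- file.path(tempdir(), "study-bundle-test")
  unlink(dir, recursive = TRUE)
  d <- study_design(seed = 13)
  b <- generate_full_study(d, dir = dir)
  expect_error(generate_full_study(d, dir = dir), "overwrite")

  s <- read_series(file.path(dir, "series_T60.csv"))
  expect_equal(s$value, b$series$T60$value, tolerance = 1e-12)
  expect_equal(attr(s, "temperature_C"), 60)

  cal <- read_calibration(file.path(dir, "calibration_CMS.csv"))
  expect_equal(cal$response, b$calibration$CMS$response, tolerance = 1e-12)

  tr <- read_truth_manifest(file.path(dir, "truth.json"))
  expect_equal(tr$arrhenius$Ea, b$truth$arrhenius$Ea)
  expect_equal(tr$rates$T60$k_forward, b$truth$rates$T60$k_forward)
  expect_equal(unname(unlist(tr$calibration$CMS)),
               unname(b$truth$calibration$CMS))
  unlink(dir, recursive = TRUE)
})
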