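test_that("identical configs give bit-identical cohorts", {
  c1 <- generate_cohort(cohort_config(n = 500, seed = 3))
  c2 <- generate_cohort(cohort_config(n = 500, seed = 3))
  expect_identical(as.data.frame(c1$data), as.data.frame(c2$data))
  expect_identical(c1$truth$lambda, c2$truth$lambda)
  c3 <- generate_cohort(cohort_config(n = 500, seed = 4))
  expect_false(identical(c1$data$y, c3$data$y))
})

test_that("confounder-outcome correlation is calibrated to its target", {
  for (target in c(0.18, 0.5)) {
    cohort <- generate_cohort(cohort_config(n = 5000, target_corr = target,
                                            seed = 11))
    expect_equal(cor(cohort$truth$u, cohort$data$y), target,
                 tolerance = 1e-6)
    expect_equal(cohort$truth$realized_corr, target, tolerance = 1e-6)
  }
})

test_that("instrument strength presets hit their treatment-gap bands", {
  strong <- generate_cohort(cohort_config(n = 5000, instrument = "strong",
                                          confounding_level = 1, seed = 21))
  weak <- generate_cohort(cohort_config(n = 5000, instrument = "weak",
                                        confounding_level = 1, seed = 21))
  expect_gte(strong$truth$realized_dpi, 0.6)
  expect_lte(weak$truth$realized_dpi, 0.35)
  expect_gt(weak$truth$realized_dpi, 0)
})

test_that("risk scores stay in [0,1] and outcomes in a plausible LDL range", {
  cohort <- generate_cohort(cohort_config(n = 3000, seed = 5))
  expect_true(all(cohort$data$x >= 0 & cohort$data$x <= 1))
  # LDL-like scale: centred near 3.5 mmol/l, almost all mass in (0, 8)
  expect_gt(mean(cohort$data$y > 0 & cohort$data$y < 8), 0.97)
  # the treated near-half of the cohort sits ~2 mmol/l lower
  expect_true(median(cohort$data$y) > 2 && median(cohort$data$y) < 4)
})

test_that("sharp cohorts have perfect adherence and unit treatment gap", {
  cohort <- generate_sharp_cohort(cohort_config(n = 1000, seed = 6))
  expect_equal(cohort$data$t, as.numeric(cohort$data$z))
  expect_equal(cohort$truth$realized_dpi, 1)
})

test_that("a null effect is not detected by the frequentist baseline", {
  cohort <- generate_cohort(cohort_config(n = 4000, tau = 0,
                                          instrument = "strong",
                                          confounding_level = 1, seed = 8))
  f <- ols_ate(filter_bandwidth(cohort$data, 0.25))
  expect_true(f$ci_low <= 0 && 0 <= f$ci_high)
})

test_that("empirical confounding is non-decreasing across levels", {
  strength <- sapply(1:4, function(lvl) {
    cohort <- generate_cohort(cohort_config(n = 5000,
                                            confounding_level = lvl,
                                            seed = 31))
    u <- cohort$truth$u
    abs(cor(u, cohort$data$t)) * abs(cor(u, cohort$data$y))
  })
  expect_true(all(diff(strength) > -1e-3))
})

test_that("defiers are impossible: a negative instrument coefficient is rejected", {
  expect_error(cohort_config(adherence = c(g0 = 0, gz = -1, gu = 0, gx = 0)),
               "monotonicity")
})

test_that("treatment lowers the outcome by construction (reduction convention)", {
  cohort <- generate_sharp_cohort(cohort_config(n = 4000, tau = 2,
                                                confounding_level = 1,
                                                seed = 13))
  d <- cohort$data
  # at the threshold the only change is treatment switching on
  near_b <- d$x >= 0.17 & d$x < 0.2
  near_a <- d$x >= 0.2 & d$x < 0.23
  expect_lt(mean(d$y[near_a]) - mean(d$y[near_b]), -1)
})

test_that("cohorts round-trip through the CSV + truth sidecar", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(cohort_config(n = 200, seed = 17))
  path <- file.path(dir, "cohort.csv")
  write_cohort(cohort, path)
  d <- read_rd_csv(path, x0 = 0.2)
  expect_equal(d$y, cohort$data$y)
  truth <- jsonlite::read_json(file.path(dir, "cohort_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$realized_dpi, cohort$truth$realized_dpi)
})

test_that("unattainable correlation targets fail loudly", {
  expect_error(cohort_config(n = 100, target_corr = 1.5), "target_corr")
})
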