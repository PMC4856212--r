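test_that("bins are regular, anchored at the threshold, and complete", {
  d <- rd_data(x = c(0.11, 0.19, 0.21, 0.29), t = c(0, 0, 1, 1),
               y = c(4, 4, 2, 2), x0 = 0.2)
  b <- bin_summaries(d, 0.1)
  filled <- b[b$n > 0, ]
  expect_equal(nrow(filled), 2L)
  expect_equal(filled$n, c(2L, 2L))
  expect_equal(filled$bin_low, c(0.1, 0.2))
  expect_equal(sum(b$n), nrow(d))
})

test_that("no bin ever straddles the threshold, whatever the width", {
  set.seed(77)
  d <- rd_data(x = runif(300, 0, 0.5), t = rbinom(300, 1, 0.5),
               y = rnorm(300), x0 = 0.2)
  for (w in c(0.017, 0.03, 0.05, 0.11, 0.23)) {
    b <- bin_summaries(d, w)
    expect_false(any(b$bin_low < 0.2 - 1e-9 & b$bin_high > 0.2 + 1e-9))
    expect_equal(sum(b$n), 300L)
    ok <- b$n > 0
    expect_true(all(b$prop_treated[ok] >= 0 & b$prop_treated[ok] <= 1))
    expect_true(all(is.na(b$mean_y[!ok])))
  }
})

test_that("sharp cohorts show a clean 0/1 split in binned treatment", {
  cohort <- generate_sharp_cohort(cohort_config(n = 1500, seed = 41))
  b <- bin_summaries(cohort$data, 0.02)
  filled <- b[b$n > 0, ]
  expect_true(all(filled$prop_treated[filled$side == "below"] == 0))
  expect_true(all(filled$prop_treated[filled$side == "above"] == 1))
})

test_that("an over-wide bin triggers the single-bin warning", {
  d <- toy_rd()
  expect_warning(bin_summaries(d, 10), "single")
  expect_error(bin_summaries(d, 0), "positive")
})

test_that("the binned treatment jump tracks the realised treatment gap", {
  cohort <- generate_cohort(cohort_config(n = 6000, instrument = "strong",
                                          confounding_level = 1, seed = 43))
  d <- filter_bandwidth(cohort$data, 0.15)
  b <- bin_summaries(d, 0.02)
  filled <- b[b$n > 0, ]
  jump <- mean(filled$prop_treated[filled$side == "above"]) -
    mean(filled$prop_treated[filled$side == "below"])
  expect_lt(abs(jump - cohort$truth$realized_dpi), 0.05)
})

test_that("instrument association arithmetic and edge behaviour", {
  # perfect adherence
  cohort <- generate_sharp_cohort(cohort_config(n = 500, seed = 44))
  a <- test_instrument_association(cohort$data)
  expect_equal(a$prop_diff, 1.0)
  expect_false(a$weak)

  # hand-built 2x2: 5/50 treated below, 40/50 above
  d <- rd_data(x = c(runif(50, 0, 0.19), runif(50, 0.2, 0.4)),
               t = c(rep(1, 5), rep(0, 45), rep(1, 40), rep(0, 10)),
               y = rnorm(100), x0 = 0.2)
  a <- test_instrument_association(d)
  expect_equal(a$prop_diff, 0.70)
  expect_equal(unname(a$table["0", "1"]), 5)

  # independent treatment: difference covered by its CI, flagged weak
  set.seed(45)
  d2 <- rd_data(x = runif(400, 0, 0.4), t = rbinom(400, 1, 0.5),
                y = rnorm(400), x0 = 0.2)
  a2 <- test_instrument_association(d2)
  expect_true(a2$ci_low <= 0 && 0 <= a2$ci_high)
  expect_true(a2$weak)
})

test_that("covariate continuity checks behave on known covariates", {
  set.seed(46)
  n <- 2000
  x <- runif(n, 0, 0.4)
  cov_df <- data.frame(bmi = rnorm(n, 27, 3), xcopy = x, const = 5)
  d <- rd_data(x = x, t = as.integer(x >= 0.2), y = rnorm(n), x0 = 0.2,
               covariates = cov_df)

  # independent covariate: no discontinuity
  cc <- covariate_continuity(d, "bmi", bin_width = 0.05)
  expect_true(cc$adjacent$ci_low <= 0 && 0 <= cc$adjacent$ci_high)

  # the score itself: difference forced to about one bin width
  cc2 <- covariate_continuity(d, "xcopy", bin_width = 0.05)
  expect_lt(abs(cc2$adjacent$difference - 0.05), 0.02)

  # constant covariate: exactly zero
  cc3 <- covariate_continuity(d, "const", bin_width = 0.05)
  expect_equal(cc3$adjacent$difference, 0)

  expect_error(covariate_continuity(d, "nope"), "not found")
})

test_that("figure renderings build from binned numbers without graphics errors", {
  cohort <- generate_cohort(cohort_config(n = 600, seed = 48))
  p1 <- plot_raw(cohort$data)
  p2 <- plot_binned_outcome(cohort$data, 0.02)
  p3 <- plot_binned_treatment(cohort$data, 0.05, smooth = FALSE)
  for (p in list(p1, p2, p3)) {
    expect_s3_class(p, "ggplot")
    built <- ggplot2::ggplot_build(p)
    expect_gt(nrow(built$data[[1]]), 0)
  }
})

test_that("the assumptions report states what is and is not testable", {
  cohort <- generate_cohort(cohort_config(n = 800, seed = 47))
  lines <- assumptions_report(cohort$data, print = FALSE)
  expect_match(paste(lines, collapse = "\n"), "A1 instrument relevance")
  expect_match(paste(lines, collapse = "\n"), "untestable")
  expect_match(paste(lines, collapse = "\n"), "monotonicity", ignore.case = TRUE)
})
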