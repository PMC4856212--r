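# Monte Carlo checks use 3 standard errors of the relevant estimator,
# with effective sample sizes taken from the fit diagnostics.

make_counts_data <- function(s_b, n_b, s_a, n_a) {
  rd_data(x = c(runif(n_b, 0.1, 0.199), runif(n_a, 0.2, 0.3)),
          t = c(rep(1, s_b), rep(0, n_b - s_b), rep(1, s_a), rep(0, n_a - s_a)),
          y = rnorm(n_b + n_a), x0 = 0.2)
}

test_that("unc denominator MCMC matches the conjugate Beta posterior", {
  set.seed(1)
  grid <- list(c(s = 8, n = 10), c(s = 0, n = 20), c(s = 20, n = 20),
               c(s = 5, n = 40))
  for (g in grid) {
    d <- make_counts_data(s_b = 1, n_b = 12, s_a = g[["s"]], n_a = g[["n"]])
    fit <- fit_denominator(d, prior_spec("sip", "unc"),
                           light_sampler(seed = g[["n"]] + g[["s"]]))
    a <- 1 + g[["s"]]; b <- 1 + g[["n"]] - g[["s"]]
    true_mean <- a / (a + b)
    true_var <- a * b / ((a + b)^2 * (a + b + 1))
    ess <- fit$diagnostics$ess[fit$diagnostics$parameter == "pa"]
    # mean within 3 MC standard errors
    expect_lt(abs(mean(fit$draws$pi_a) - true_mean),
              3 * sqrt(true_var / ess) + 1e-12)
    # variance within 3 MC standard errors (empirical fourth moment)
    v <- var(fit$draws$pi_a)
    m4 <- mean((fit$draws$pi_a - mean(fit$draws$pi_a))^4)
    expect_lt(abs(v - true_var), 3 * sqrt((m4 - v^2) / ess) + 1e-12)
  }
})

test_that("conjugate closed-form worked examples hold", {
  # 0 of 20 treated below, 20 of 20 above
  d <- make_counts_data(s_b = 0, n_b = 20, s_a = 20, n_a = 20)
  fit <- fit_denominator(d, prior_spec("sip", "unc"),
                         light_sampler(seed = 2, iter = 2000))
  expect_lt(abs(mean(fit$draws$pi_b) - 1 / 22), 0.01)
  expect_lt(abs(mean(fit$draws$pi_a) - 21 / 22), 0.01)
  expect_lt(abs(mean(fit$draws$dpi) - 20 / 22), 0.02)
})

test_that("flexible difference prior predictive concentrates on a gap", {
  pp <- prior_predictive_denominator(prior_spec("sip", "fdp"),
                                     n = 20000, seed = 3)
  expect_gt(mean(pp$pi_b < 0.5), 0.95)
  expect_gt(mean(pp$pi_a > 0.5), 0.95)
  # full (0,1) support on both sides
  expect_true(all(pp$pi_b > 0 & pp$pi_b < 1))
  expect_gt(max(pp$pi_b), 0.5)
  expect_lt(min(pp$pi_a), 0.5)
})

test_that("with diffuse priors the numerator approaches the OLS fit", {
  d <- random_rd(n = 300, jump = -2, seed = 4)
  prior <- prior_spec("custom", "unc", phi_mean = 0, phi_var = 1e4,
                      s0sq = 1e4, s1bsq = 1e4, s1asq = 1e4)
  fit <- fit_numerator(d, prior, light_sampler(seed = 4, iter = 800))
  f <- ols_ate(d)
  ess <- fit$diagnostics$ess[fit$diagnostics$parameter == "phi"]
  mcse <- sd(fit$draws$phi) / sqrt(ess)
  # posterior mean of the jump vs the least-squares jump, allowing both
  # MC noise and the small posterior/OLS sampling-variance mismatch
  expect_lt(abs(mean(fit$draws$phi) - f$estimate), 3 * mcse + 0.05 * f$se)
})

test_that("no-jump data shrink the posterior jump toward zero", {
  n <- 400
  set.seed(5)
  # near-constant outcome: the sampler needs some residual noise, but the
  # posterior jump must still collapse onto zero
  d <- rd_data(x = seq(0.05, 0.35, length.out = n),
               t = as.integer(seq(0.05, 0.35, length.out = n) >= 0.2),
               y = rep(3.5, n) + rnorm(n, 0, 0.01), x0 = 0.2)
  fit <- fit_numerator(d, prior_spec("wip"), light_sampler(seed = 5))
  expect_lt(abs(mean(fit$draws$phi)), 0.05)
})

test_that("the intercept identity beta0a = beta0b + phi holds draw by draw", {
  d <- random_rd(n = 150, seed = 6)
  fit <- fit_numerator(d, prior_spec("sip"), light_sampler(seed = 6))
  expect_equal(fit$draws$beta0a, fit$draws$beta0b + fit$draws$phi,
               tolerance = 1e-10)
})

test_that("the treatment-probability gap is a proper difference, draw by draw", {
  d <- make_counts_data(s_b = 3, n_b = 15, s_a = 12, n_a = 15)
  fit <- fit_denominator(d, prior_spec("sip", "fdp"), light_sampler(seed = 15))
  expect_equal(fit$draws$dpi, fit$draws$pi_a - fit$draws$pi_b)
  expect_true(all(fit$draws$dpi >= -1 & fit$draws$dpi <= 1))
})

test_that("one-sided data are rejected naming the empty side", {
  d <- rd_data(x = c(0.25, 0.3, 0.35), t = c(1, 1, 1), y = 1:3, x0 = 0.2)
  expect_error(fit_numerator(d, prior_spec("sip"), light_sampler()),
               "below")
  expect_error(fit_denominator(d, prior_spec("sip", "unc"), light_sampler()),
               "below")
})

test_that("LATE composition follows the ratio definition exactly", {
  num <- fake_numerator(rep(-2, 100))
  expect_equal(compose_late(num, fake_denominator(rep(1, 100)))$draws$late,
               rep(-2, 100))
  expect_equal(compose_late(num, fake_denominator(rep(0.5, 100)))$draws$late,
               rep(-4, 100))
  expect_error(compose_late(num, fake_denominator(rep(0.5, 99))),
               "draw counts differ")
})

test_that("near-zero denominator draws are counted, never removed", {
  num <- fake_numerator(rep(-2, 10))
  den <- fake_denominator(c(rep(0.5, 8), 0.005, -0.002))
  late <- compose_late(num, den)
  expect_equal(late$n_small_dpi, 2L)
  expect_equal(nrow(late$draws), 10L)  # nothing dropped
  expect_true(all(is.finite(late$draws$late)))
})

test_that("|LATE| is at least |ATE| whenever the gap is a proper fraction", {
  cohort <- generate_cohort(cohort_config(n = 1500, seed = 7))
  d <- filter_bandwidth(cohort$data, 0.25)
  late <- compose_late(
    fit_numerator(d, prior_spec("sip"), light_sampler(seed = 7)),
    fit_denominator(d, prior_spec("sip", "fdp"), light_sampler(seed = 8)))
  dr <- late$draws
  frac <- dr$dpi > 0 & dr$dpi <= 1
  expect_gt(mean(frac), 0.99)
  expect_true(all(abs(dr$late[frac]) >= abs(dr$phi[frac])))
})

test_that("the sharp-design limit makes LATE and ATE agree", {
  cohort <- generate_sharp_cohort(cohort_config(n = 2000, tau = 2, seed = 9))
  d <- filter_bandwidth(cohort$data, 0.25)
  num <- fit_numerator(d, prior_spec("sip"), light_sampler(seed = 9))
  den <- fit_denominator(d, prior_spec("sip", "unc"), light_sampler(seed = 10))
  late <- compose_late(num, den)
  expect_gt(mean(den$draws$dpi), 0.95)
  ate <- mean(num$draws$phi)
  expect_lt(abs(mean(late$draws$late) - ate) / abs(ate), 0.1)
})

test_that("prior informativeness matters less than the prior-mean gap", {
  d <- random_rd(n = 400, jump = -2, seed = 12)
  wip <- fit_numerator(d, prior_spec("wip"), light_sampler(seed = 12))
  sip <- fit_numerator(d, prior_spec("sip"), light_sampler(seed = 13))
  expect_lt(abs(mean(wip$draws$phi) - mean(sip$draws$phi)), 2)
})

test_that("credible interval width for the jump shrinks with sample size", {
  widths <- sapply(c(200, 800, 3200), function(n) {
    reps <- sapply(1:3, function(r) {
      cohort <- generate_cohort(cohort_config(n = n, seed = 100 * n + r))
      d <- filter_bandwidth(cohort$data, 0.25)
      fit <- fit_numerator(d, prior_spec("wip"),
                           light_sampler(seed = n + r, iter = 300,
                                         warmup = 300))
      s <- fit$summary[fit$summary$parameter == "phi", ]
      s$q97.5 - s$q2.5
    })
    mean(reps)
  })
  expect_true(all(diff(widths) < 0))
})

test_that("posterior summaries are exact functions of the draws", {
  expect_equal(summarize_draws(data.frame(v = c(1, 2, 3)))$mean, 2)
  s <- summarize_draws(data.frame(v = rep(4.2, 200)))
  expect_equal(unlist(s[c("q2.5", "q50", "q97.5")]), rep(4.2, 3),
               ignore_attr = TRUE)
  set.seed(31)
  s <- summarize_draws(data.frame(v = rnorm(1e5)))
  expect_equal(s$q97.5, qnorm(0.975), tolerance = 0.03 / 1.96)
})

test_that("requested draw counts and diagnostics are delivered", {
  d <- random_rd(n = 100, seed = 14)
  smp <- light_sampler(seed = 14, chains = 3, iter = 250)
  fit <- fit_numerator(d, prior_spec("sip"), smp)
  expect_equal(nrow(fit$draws), 3 * 250)
  expect_true(all(c("phi", "sigma") %in% fit$diagnostics$parameter))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_true(all(fit$diagnostics$ess > 0))
})
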