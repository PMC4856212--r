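# MCMC machinery for the RD outcome (numerator) and treatment-probability
# (denominator) models, fitted with JAGS via rjags. Quantile summaries use
# type-7 linear interpolation (the R default) throughout.

.numerator_model <- "
model {
  for (i in 1:nb) { yb[i] ~ dnorm(beta0b + beta1b * xb[i], tau) }
  for (i in 1:na) { ya[i] ~ dnorm(beta0a + beta1a * xa[i], tau) }
  beta0a <- beta0b + phi
  beta0b ~ dnorm(m0, prec0)
  beta1b ~ dnorm(m1b, prec1b)
  beta1a ~ dnorm(m1a, prec1a)
  phi    ~ dnorm(phi_m, prec_phi)
  sigma  ~ dunif(0, sigma_upper)
  tau   <- pow(sigma, -2)
}"

.denominator_model_unc <- "
model {
  sb ~ dbin(pb, nb)
  sa ~ dbin(pa, na)
  pb ~ dbeta(b1, b2)
  pa ~ dbeta(a1, a2)
}"

.denominator_model_fdp <- "
model {
  sb ~ dbin(pb, nb)
  sa ~ dbin(pa, na)
  logit(pb) <- lb
  logit(pa) <- la
  lb ~ dnorm(lb_m, prec_lb)
  la ~ dnorm(la_m, prec_la)
}"

# Deterministic child seeds without disturbing the caller's RNG stream.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% 2147483647L)
  sample.int(2147483646L, n)
}

# Split-chain potential scale reduction statistic. `x` is an
# iterations x chains matrix; each chain is split in half.
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  pieces <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
    cbind(x[seq_len(half), j], x[(n - half + 1):n, j])))
  m <- ncol(pieces); nn <- nrow(pieces)
  means <- colMeans(pieces)
  vars <- apply(pieces, 2, stats::var)
  B <- nn * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

run_jags <- function(model_string, data, monitor, sampler, inits_extra = NULL) {
  # block-conjugate samplers for the linear predictors mix far better
  # than the univariate defaults
  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  seeds <- derive_seeds(sampler$seed, sampler$chains)
  inits <- lapply(seeds, function(s)
    c(list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s), inits_extra))
  adapt <- max(100L, sampler$warmup %/% 2L)
  burn <- sampler$warmup - adapt
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = sampler$chains,
                          n.adapt = adapt, quiet = TRUE)
  if (burn > 0) update(jm, burn, progress.bar = "none")
  rjags::coda.samples(jm, monitor, n.iter = sampler$iter,
                      progress.bar = "none")
}

# Flatten a coda mcmc.list into a draws data frame + diagnostics table.
collect_draws <- function(samples, sampler) {
  pars <- colnames(samples[[1]])
  draws <- as.data.frame(do.call(rbind, lapply(samples, as.matrix)))
  ess_all <- coda::effectiveSize(samples)
  diag <- data.frame(
    parameter = pars,
    rhat = vapply(pars, function(p)
      split_rhat(sapply(samples, function(ch) as.matrix(ch)[, p])), 0),
    ess = unname(ess_all[pars]),
    row.names = NULL)
  bad <- diag$parameter[is.finite(diag$rhat) & diag$rhat > sampler$rhat_tol]
  warnings <- character()
  if (length(bad)) {
    warnings <- paste0("possible non-convergence (split R-hat > ",
                       sampler$rhat_tol, ") for: ",
                       paste(bad, collapse = ", "))
    warning(warnings, call. = FALSE)
  }
  list(draws = draws, diagnostics = diag, warnings = warnings)
}

#' Fit the Bayesian outcome model (LATE numerator / sharp ATE)
#'
#' Fits the two-segment local linear regression of outcome on the centred
#' assignment score: `y ~ Normal(beta0l + beta1l * (x - x0), sigma^2)`
#' separately below (`l = b`) and above (`l = a`) the threshold, with a
#' single shared `sigma` and the above-intercept parameterised as
#' `beta0a = beta0b + phi`. The jump `phi` is the average treatment
#' effect at the threshold (`ATE = beta0a - beta0b`).
#'
#' @param data an [rd_data] object, normally already restricted with
#'   [filter_bandwidth()].
#' @param prior an [prior_spec()] object; `phi` gets the numerator preset
#'   (`wip` or `sip`).
#' @param sampler a [sampler_settings()] object.
#' @return An object of class `rd_numerator`: list with `draws` (one row
#'   per kept MCMC iteration, columns `beta0b`, `beta1b`, `beta0a`,
#'   `beta1a`, `phi`, `sigma`), `summary`, `diagnostics` (split R-hat and
#'   effective sample size per parameter), `warnings`, and provenance
#'   (`prior`, `sampler`, `n_below`, `n_above`, `bandwidth`).
#' @export
fit_numerator <- function(data, prior, sampler = sampler_settings()) {
  stopifnot(inherits(data, "rd_data"), inherits(prior, "rd_prior"))
  x0 <- attr(data, "x0")
  xc <- center_scores(data$x, x0)
  below <- data$z == 0
  if (sum(below) < 2L)
    stop("need at least 2 records below the threshold (have ",
         sum(below), ")", call. = FALSE)
  if (sum(!below) < 2L)
    stop("need at least 2 records above the threshold (have ",
         sum(!below), ")", call. = FALSE)
  jd <- list(yb = data$y[below], xb = xc[below], nb = sum(below),
             ya = data$y[!below], xa = xc[!below], na = sum(!below),
             m0 = prior$m0, prec0 = 1 / prior$s0sq,
             m1b = prior$m1b, prec1b = 1 / prior$s1bsq,
             m1a = prior$m1a, prec1a = 1 / prior$s1asq,
             phi_m = prior$phi_mean, prec_phi = 1 / prior$phi_var,
             sigma_upper = prior$sigma_upper)
  samples <- run_jags(.numerator_model, jd,
                      c("beta0b", "beta1b", "beta0a", "beta1a", "phi", "sigma"),
                      sampler)
  res <- collect_draws(samples, sampler)
  structure(list(draws = res$draws,
                 summary = summarize_draws(res$draws),
                 diagnostics = res$diagnostics,
                 warnings = res$warnings,
                 prior = prior, sampler = sampler,
                 n_below = jd$nb, n_above = jd$na,
                 bandwidth = attr(data, "bandwidth")),
            class = "rd_numerator")
}

#' Fit the Bayesian treatment-probability model (LATE denominator)
#'
#' Models the number treated on each side of the threshold as
#' `sum(t) ~ Binomial(n_l, pi_l)` for `l = b` (below) and `l = a`
#' (above), and derives the treatment-probability gap
#' `dpi = pi_a - pi_b` per posterior draw. The prior follows the
#' denominator preset: independent Beta distributions (`unc`, conjugate;
#' still sampled by MCMC) or the flexible difference logit-Normal prior
#' (`fdp`).
#'
#' @inheritParams fit_numerator
#' @return An object of class `rd_denominator`: list with `draws`
#'   (`pi_b`, `pi_a`, `dpi`), `summary`, `diagnostics`, `warnings`, the
#'   observed counts (`s_below`, `n_below`, `s_above`, `n_above`) and
#'   provenance.
#' @export
fit_denominator <- function(data, prior, sampler = sampler_settings()) {
  stopifnot(inherits(data, "rd_data"), inherits(prior, "rd_prior"))
  below <- data$z == 0
  nb <- sum(below); na_ <- sum(!below)
  if (nb < 1L) stop("no records below the threshold", call. = FALSE)
  if (na_ < 1L) stop("no records above the threshold", call. = FALSE)
  sb <- sum(data$t[below]); sa <- sum(data$t[!below])

  preset <- prior$denominator_preset
  if (preset == "unc") {
    jd <- list(sb = sb, nb = nb, sa = sa, na = na_,
               b1 = prior$beta_b1, b2 = prior$beta_b2,
               a1 = prior$beta_a1, a2 = prior$beta_a2)
    samples <- run_jags(.denominator_model_unc, jd, c("pb", "pa"), sampler)
  } else if (preset == "fdp") {
    jd <- list(sb = sb, nb = nb, sa = sa, na = na_,
               lb_m = prior$lb_mean, prec_lb = 1 / prior$lb_var,
               la_m = prior$la_mean, prec_la = 1 / prior$la_var)
    samples <- run_jags(.denominator_model_fdp, jd, c("pb", "pa"), sampler)
  } else {
    stop("unknown denominator preset '", preset,
         "'; valid presets: unc, fdp", call. = FALSE)
  }
  res <- collect_draws(samples, sampler)
  draws <- data.frame(pi_b = res$draws$pb, pi_a = res$draws$pa)
  draws$dpi <- draws$pi_a - draws$pi_b
  structure(list(draws = draws,
                 summary = summarize_draws(draws),
                 diagnostics = res$diagnostics,
                 warnings = res$warnings,
                 prior = prior, sampler = sampler,
                 s_below = sb, n_below = nb, s_above = sa, n_above = na_,
                 bandwidth = attr(data, "bandwidth")),
            class = "rd_denominator")
}

#' Prior predictive draws of the treatment probabilities
#'
#' Samples `pi_b` and `pi_a` from the denominator prior alone (no data),
#' e.g. to visualise how the flexible difference prior concentrates
#' `pi_b` below 0.5 and `pi_a` above it while keeping all of (0, 1)
#' possible.
#'
#' @param prior an [prior_spec()] object.
#' @param n number of draws.
#' @param seed integer seed.
#' @return data frame with columns `pi_b`, `pi_a`, `dpi`.
#' @export
prior_predictive_denominator <- function(prior, n = 10000, seed = 1) {
  stopifnot(inherits(prior, "rd_prior"))
  set.seed(seed)
  if (prior$denominator_preset == "unc") {
    pb <- stats::rbeta(n, prior$beta_b1, prior$beta_b2)
    pa <- stats::rbeta(n, prior$beta_a1, prior$beta_a2)
  } else {
    pb <- stats::plogis(stats::rnorm(n, prior$lb_mean, sqrt(prior$lb_var)))
    pa <- stats::plogis(stats::rnorm(n, prior$la_mean, sqrt(prior$la_var)))
  }
  data.frame(pi_b = pb, pi_a = pa, dpi = pa - pb)
}

#' Compose numerator and denominator posteriors into the LATE
#'
#' The local average treatment effect is the ratio of the outcome jump to
#' the treatment-probability jump at the threshold,
#' `LATE = dbeta / dpi`. The two likelihoods share no parameters, so the
#' posteriors are composed draw-by-draw: `LATE_i = phi_i / dpi_i`. Draws
#' with `|dpi|` below `dpi_floor` are counted and reported, but never
#' removed: when the instrument is weak the ratio genuinely blows up, and
#' hiding that would misrepresent the posterior.
#'
#' @param numerator an `rd_numerator` fit.
#' @param denominator an `rd_denominator` fit with the same number of
#'   draws.
#' @param dpi_floor threshold below which `|dpi|` draws are flagged.
#' @return An object of class `rd_late`: list with `draws` (`phi`, `dpi`,
#'   `late`), `summary`, `n_small_dpi`, `frac_small_dpi`, and the two
#'   component fits.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n = 500, seed = 1))
#' d <- filter_bandwidth(cohort$data, 0.25)
#' s <- sampler_settings(chains = 2, warmup = 500, iter = 500)
#' late <- compose_late(fit_numerator(d, prior_spec("sip"), s),
#'                      fit_denominator(d, prior_spec("sip", "fdp"), s))
#' late$summary
#' }
#' @export
compose_late <- function(numerator, denominator, dpi_floor = 0.01) {
  stopifnot(inherits(numerator, "rd_numerator"),
            inherits(denominator, "rd_denominator"))
  phi <- numerator$draws$phi
  dpi <- denominator$draws$dpi
  if (length(phi) != length(dpi))
    stop("numerator and denominator draw counts differ (",
         length(phi), " vs ", length(dpi), ")", call. = FALSE)
  late <- phi / dpi
  n_small <- sum(abs(dpi) < dpi_floor)
  draws <- data.frame(phi = phi, dpi = dpi, late = late)
  structure(list(draws = draws,
                 summary = summarize_draws(draws),
                 dpi_floor = dpi_floor,
                 n_small_dpi = n_small,
                 frac_small_dpi = n_small / length(dpi),
                 numerator = numerator, denominator = denominator),
            class = "rd_late")
}

#' Summarise posterior draws
#'
#' Posterior mean, standard deviation and 2.5/50/97.5% quantiles per
#' column. Quantiles use type-7 linear interpolation (the [stats::quantile()]
#' default), so the 95% interval is the central credible interval.
#'
#' @param draws data frame or matrix of posterior draws (>= 100 rows
#'   recommended), one column per quantity.
#' @return data frame with one row per quantity: `parameter`, `mean`,
#'   `sd`, `q2.5`, `q50`, `q97.5`.
#' @examples
#' summarize_draws(data.frame(phi = rnorm(1000, -2, 0.1)))
#' @export
summarize_draws <- function(draws) {
  draws <- as.data.frame(draws)
  if (nrow(draws) < 1L) stop("no draws to summarise", call. = FALSE)
  out <- do.call(rbind, lapply(names(draws), function(p) {
    v <- draws[[p]]
    q <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    data.frame(parameter = p, mean = mean(v), sd = stats::sd(v),
               q2.5 = q[1], q50 = q[2], q97.5 = q[3])
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.rd_numerator <- function(x, ...) {
  cat("Bayesian RD outcome model (", x$prior$numerator_preset,
      " prior on the jump)\n", sep = "")
  cat("  n below/above: ", x$n_below, "/", x$n_above, sep = "")
  if (!is.null(x$bandwidth)) cat("  bandwidth: ", x$bandwidth, sep = "")
  cat("\n")
  print(x$summary, digits = 3)
  if (length(x$warnings)) cat("  WARNING:", x$warnings, "\n")
  invisible(x)
}

#' @export
print.rd_denominator <- function(x, ...) {
  cat("Bayesian RD treatment model (", x$prior$denominator_preset,
      " prior)\n", sep = "")
  cat("  treated below: ", x$s_below, "/", x$n_below,
      "   above: ", x$s_above, "/", x$n_above, "\n", sep = "")
  print(x$summary, digits = 3)
  if (length(x$warnings)) cat("  WARNING:", x$warnings, "\n")
  invisible(x)
}

#' @export
print.rd_late <- function(x, ...) {
  cat("Posterior LATE (", x$numerator$prior$numerator_preset, " numerator / ",
      x$denominator$prior$denominator_preset, " denominator)\n", sep = "")
  print(x$summary, digits = 3)
  if (x$n_small_dpi > 0)
    cat("  note: ", x$n_small_dpi, " draw(s) (",
        round(100 * x$frac_small_dpi, 2), "%) had |dpi| < ",
        x$dpi_floor, "\n", sep = "")
  invisible(x)
}
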