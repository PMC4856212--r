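# Synthetic statin-prescription cohorts with known ground truth.
#
# The generator emulates the structure of a UK primary-care statin
# scenario: a 10-year CVD risk score X on [0, 1] with most mass below the
# 0.2 prescription threshold, an unobserved confounder U playing the role
# of HDL cholesterol (predictive of both prescription and LDL outcome),
# partial GP adherence to the threshold rule, and an LDL-like outcome in
# mmol/l. All calibration constants live in the table below.

# Calibration table (frozen design constants):
#   X ~ Beta(2, 6)                      right-skewed risk score, mode ~1/6
#   logit P(T=1) = -gz/2 + gz*Z + gu*U + gx*(X - x0)
#     gz = 4.4 (strong instrument) / 1.2 (weak)
#     gu = 0.2 (confounding levels 1-2) / 3.5 (levels 3-4)
#     gx = 0.5
#   Y = 3.5 + 2*(X - x0) - tau*T + lambda*U + eps,  eps ~ N(0, 0.8^2)
#     lambda solved so the sample cor(U, Y) equals target_corr
#     (0.18 at levels 1 and 3, 0.5 at levels 2 and 4)
.cohort_constants <- list(
  x_shape1 = 2, x_shape2 = 6,
  gz_strong = 4.4, gz_weak = 1.2,
  gu_low = 0.2, gu_high = 3.5,
  gx = 0.5,
  outcome_baseline = 3.5, outcome_slope = 2, sigma_eps = 0.8,
  corr_baseline = 0.18, corr_adjusted = 0.5)

#' Configuration of a synthetic statin cohort
#'
#' `tau` is the magnitude of the LDL *reduction* caused by treatment; the
#' generated outcome jump is `-tau`, matching the convention that a
#' statin effect "of size 2" means a reduction of 2 mmol/l. The four
#' confounding levels pair the strength of the confounder's effect on
#' prescription (low at levels 1-2, high at levels 3-4) with its
#' correlation with the outcome (0.18 at levels 1 and 3, the baseline
#' LDL-HDL correlation; 0.5 at levels 2 and 4, the adjusted one). No
#' defier mechanism exists: the instrument coefficient is non-negative,
#' so monotonicity holds by construction, and the threshold indicator
#' enters the outcome only through treatment.
#'
#' @param n cohort size (the motivating primary-care extract has 5720
#'   men over 50).
#' @param tau true treatment effect magnitude, as a reduction in mmol/l
#'   (study sizes: 2, 1.09, 0.5).
#' @param confounding_level integer 1-4 (see Details).
#' @param instrument `"strong"` or `"weak"`.
#' @param target_corr confounder-outcome correlation; default follows
#'   the confounding level.
#' @param x0 threshold (default 0.2).
#' @param seed integer seed; identical configs give identical cohorts.
#' @param outcome_baseline,outcome_slope intercept and slope of the
#'   confounder-free outcome surface (mmol/l; mmol/l per unit risk).
#' @param adherence named numeric vector of logistic coefficients
#'   `c(g0, gz, gu, gx)` of the prescription model; defaults come from
#'   the calibration table and `instrument`/`confounding_level`.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 5720, tau = 2, confounding_level = 1,
                          instrument = c("strong", "weak"),
                          target_corr = NULL, x0 = 0.2, seed = 1,
                          outcome_baseline = .cohort_constants$outcome_baseline,
                          outcome_slope = .cohort_constants$outcome_slope,
                          adherence = NULL) {
  instrument <- match.arg(instrument)
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (!confounding_level %in% 1:4)
    stop("'confounding_level' must be 1, 2, 3 or 4", call. = FALSE)
  cc <- .cohort_constants
  if (is.null(target_corr))
    target_corr <- if (confounding_level %in% c(1, 3))
      cc$corr_baseline else cc$corr_adjusted
  if (abs(target_corr) >= 1)
    stop("'target_corr' must be in (-1, 1)", call. = FALSE)
  if (is.null(adherence)) {
    gz <- if (instrument == "strong") cc$gz_strong else cc$gz_weak
    gu <- if (confounding_level <= 2) cc$gu_low else cc$gu_high
    adherence <- c(g0 = -gz / 2, gz = gz, gu = gu, gx = cc$gx)
  }
  if (!all(c("g0", "gz", "gu", "gx") %in% names(adherence)))
    stop("'adherence' needs named components g0, gz, gu, gx", call. = FALSE)
  if (adherence[["gz"]] < 0)
    stop("instrument coefficient 'gz' must be >= 0 (monotonicity)",
         call. = FALSE)
  structure(list(n = as.integer(n), tau = tau,
                 confounding_level = as.integer(confounding_level),
                 instrument = instrument, target_corr = target_corr,
                 x0 = x0, seed = as.integer(seed),
                 outcome_baseline = outcome_baseline,
                 outcome_slope = outcome_slope,
                 adherence = adherence,
                 sigma_eps = cc$sigma_eps),
            class = "cohort_config")
}

# Independent named substreams derived from the config seed, so adding a
# variable to the generator never perturbs the draws of the others.
.substream_seeds <- function(seed) {
  s <- derive_seeds(seed, 5)
  names(s) <- c("x", "u", "t", "eps", "spare")
  s
}

#' Generate a synthetic fuzzy RD cohort
#'
#' Draws risk scores `X ~ Beta(2, 6)` (right-skewed on \[0, 1\] with
#' appreciable mass near the 0.2 threshold), a standard normal unobserved
#' confounder `U`, the threshold indicator `Z = 1(X >= x0)`, treatment by
#' the logistic adherence model, and the outcome
#' `Y = baseline + slope*(X - x0) - tau*T + lambda*U + eps`. The loading
#' `lambda` is solved numerically so the realised sample correlation
#' between `U` and `Y` equals `target_corr` (an error is raised if the
#' achieved value is off by more than 0.05, which cannot happen for
#' attainable targets since the calibration is exact).
#'
#' @param config a [cohort_config()].
#' @return A list of class `rd_cohort` with elements `data` (an
#'   [rd_data] object) and `truth` (a `cohort_truth` list: `tau`, the
#'   realised treatment-probability gap `dpi`, the realised
#'   confounder-outcome correlation, `lambda`, and the latent confounder
#'   `u`).
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 1000, seed = 42))
#' cohort$truth$realized_corr
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  parts <- .simulate_parts(config)
  .assemble_cohort(config, parts, t = parts$t)
}

#' Generate a sharp RD cohort (perfect guideline adherence)
#'
#' As [generate_cohort()] but with `T = Z` deterministically, so the
#' empirical treatment-probability gap is exactly 1 and the ATE equals
#' the LATE.
#'
#' @inheritParams generate_cohort
#' @return As [generate_cohort()].
#' @export
generate_sharp_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  parts <- .simulate_parts(config)
  .assemble_cohort(config, parts, t = parts$z)
}

.simulate_parts <- function(config) {
  cc <- .cohort_constants
  ss <- .substream_seeds(config$seed)
  n <- config$n
  set.seed(ss[["x"]]);   x <- stats::rbeta(n, cc$x_shape1, cc$x_shape2)
  set.seed(ss[["u"]]);   u <- stats::rnorm(n)
  z <- threshold_indicator(x, config$x0)
  g <- config$adherence
  p_treat <- stats::plogis(g[["g0"]] + g[["gz"]] * z + g[["gu"]] * u +
                           g[["gx"]] * (x - config$x0))
  set.seed(ss[["t"]]);   t <- stats::rbinom(n, 1, p_treat)
  set.seed(ss[["eps"]]); eps <- stats::rnorm(n, 0, config$sigma_eps)
  list(x = x, u = u, z = z, t = t, eps = eps, p_treat = p_treat)
}

.assemble_cohort <- function(config, parts, t) {
  # outcome minus the confounder term; lambda scales U into Y
  base <- config$outcome_baseline +
    config$outcome_slope * (parts$x - config$x0) -
    config$tau * t + parts$eps
  u <- parts$u
  f <- function(lambda) stats::cor(u, base + lambda * u) - config$target_corr
  # cor is non-decreasing in lambda (Cauchy-Schwarz), so bracket widely
  lambda <- tryCatch(stats::uniroot(f, c(-50, 50), tol = 1e-10)$root,
                     error = function(e) NA_real_)
  if (!is.finite(lambda))
    stop("confounder calibration failed: target_corr = ",
         config$target_corr, " unattainable; achieved range (",
         round(f(-50) + config$target_corr, 3), ", ",
         round(f(50) + config$target_corr, 3), ")", call. = FALSE)
  y <- base + lambda * u
  achieved <- stats::cor(u, y)
  if (abs(achieved - config$target_corr) > 0.05)
    stop("confounder calibration failed: achieved correlation ",
         round(achieved, 4), " vs target ", config$target_corr,
         call. = FALSE)

  data <- rd_data(x = parts$x, t = t, y = y, x0 = config$x0)
  dpi <- mean(t[parts$z == 1]) - mean(t[parts$z == 0])
  truth <- structure(list(tau = config$tau, realized_dpi = dpi,
                          realized_corr = achieved, lambda = lambda,
                          u = u, config = config),
                     class = "cohort_truth")
  structure(list(data = data, truth = truth), class = "rd_cohort")
}

#' @export
print.rd_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat("Synthetic statin cohort: n = ", cfg$n,
      ", tau = ", cfg$tau, " (reduction), ", cfg$instrument,
      " instrument, confounding level ", cfg$confounding_level, "\n",
      sep = "")
  cat(sprintf("  realised dpi = %.3f, cor(U, Y) = %.3f\n",
              x$truth$realized_dpi, x$truth$realized_corr))
  invisible(x)
}

#' Write a generated cohort to disk
#'
#' Writes the records as the standard input CSV (columns `id`, `x`, `t`,
#' `y`) and the ground truth (without the latent vector) as a sidecar
#' JSON next to it.
#'
#' @param cohort an `rd_cohort` from [generate_cohort()].
#' @param path output CSV path; the truth goes to `<path>_truth.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "rd_cohort"))
  utils::write.csv(cohort$data[, c("id", "x", "t", "y")], path,
                   row.names = FALSE)
  truth <- cohort$truth
  cfg <- truth$config
  meta <- list(tau = truth$tau, realized_dpi = truth$realized_dpi,
               realized_corr = truth$realized_corr, lambda = truth$lambda,
               n = cfg$n, instrument = cfg$instrument,
               confounding_level = cfg$confounding_level,
               target_corr = cfg$target_corr, x0 = cfg$x0, seed = cfg$seed)
  jsonlite::write_json(meta, sub("\\.csv$", "", path) |>
                         paste0("_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
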