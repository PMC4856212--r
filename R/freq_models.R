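#' Frequentist ATE at the threshold by ordinary least squares
#'
#' The baseline comparator: fits `y = beta0l + beta1l * (x - x0)` by OLS
#' separately below and above the threshold and reports the intercept
#' difference `beta0a - beta0b`, the outcome jump at the threshold. The
#' two fits use disjoint samples, so `se^2 = se(beta0a)^2 + se(beta0b)^2`,
#' and the 95% confidence interval uses the standard normal multiplier
#' 1.96 (at typical RD sample sizes the t correction is negligible).
#'
#' @param data an [rd_data] object, normally bandwidth-filtered.
#' @return An object of class `rd_freq`: list with `estimate`, `se`,
#'   `ci_low`, `ci_high`, `n_below`, `n_above` and the two per-side
#'   intercepts.
#' @examples
#' d <- rd_data(x = c(0.0, 0.1, 0.3, 0.4), t = c(0, 0, 1, 1),
#'              y = c(2.0, 2.5, 1.0, 1.5), x0 = 0.2)
#' ols_ate(d)$estimate  # -2.5
#' @export
ols_ate <- function(data) {
  stopifnot(inherits(data, "rd_data"))
  x0 <- attr(data, "x0")
  xc <- center_scores(data$x, x0)
  below <- data$z == 0
  for (side in c("below", "above")) {
    idx <- if (side == "below") below else !below
    if (sum(idx) < 2L)
      stop("too few records ", side, " the threshold (", sum(idx),
           "; need >= 2)", call. = FALSE)
    if (length(unique(xc[idx])) < 2L)
      stop("degenerate design ", side, " the threshold: ",
           "all assignment scores equal", call. = FALSE)
  }

  fit_side <- function(idx) {
    f <- stats::lm(y ~ xc, data = data.frame(y = data$y[idx], xc = xc[idx]))
    # summary.lm warns on exact fits; the se is then set to 0 below
    cf <- suppressWarnings(summary(f))$coefficients
    se <- cf["(Intercept)", "Std. Error"]
    # exact fit (zero residual variance) gives NaN se in summary.lm
    if (!is.finite(se)) se <- 0
    list(b0 = unname(stats::coef(f)[1]), se0 = se)
  }
  fb <- fit_side(below)
  fa <- fit_side(!below)
  est <- fa$b0 - fb$b0
  se <- sqrt(fa$se0^2 + fb$se0^2)
  structure(list(estimate = est, se = se,
                 ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
                 beta0_below = fb$b0, beta0_above = fa$b0,
                 n_below = sum(below), n_above = sum(!below),
                 bandwidth = attr(data, "bandwidth")),
            class = "rd_freq")
}

#' @export
print.rd_freq <- function(x, ...) {
  cat("Frequentist RD ATE (split OLS)\n")
  cat(sprintf("  estimate %.4f  se %.4f  95%% CI (%.4f, %.4f)\n",
              x$estimate, x$se, x$ci_low, x$ci_high))
  cat("  n below/above:", x$n_below, "/", x$n_above, "\n")
  invisible(x)
}
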