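# Exploratory and assumption-checking diagnostics. The instrument-
# relevance assumption (threshold indicator associated with treatment) is
# directly testable; continuity of observed covariates at the threshold
# is partly testable; independence of the guideline from patient
# characteristics, unconfoundedness, and monotonicity (no defiers) are
# untestable from the data and are reported as such.

#' Binned summaries across the threshold
#'
#' Partitions the observed range of the assignment score into regular
#' bins of width `bin_width`, aligned so that the threshold `x0` falls
#' exactly on a bin edge (no bin ever straddles the threshold, which
#' would smear the discontinuity). Reports, per bin, the midpoint, the
#' record count, the mean outcome and the treated proportion; empty bins
#' are kept with count 0 and `NA` means.
#'
#' @param data an [rd_data] object.
#' @param bin_width positive bin width on the scale of `x` (default 0.02
#'   on the risk-score scale).
#' @param value optional name of a column to summarise instead of the
#'   outcome (used by [covariate_continuity()]).
#' @return An object of class `binned_summary`: data frame with columns
#'   `bin_low`, `bin_high`, `midpoint`, `n`, `mean_y`, `prop_treated`,
#'   `side`, plus attributes `x0` and `bin_width`.
#' @examples
#' d <- rd_data(x = c(0.11, 0.19, 0.21, 0.29), t = c(0, 0, 1, 1),
#'              y = c(4, 4, 2, 2), x0 = 0.2)
#' bin_summaries(d, 0.1)
#' @export
bin_summaries <- function(data, bin_width = 0.02, value = "y") {
  stopifnot(inherits(data, "rd_data"))
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("'bin_width' must be a single positive number", call. = FALSE)
  x0 <- attr(data, "x0")
  rng <- range(data$x)
  if (bin_width > diff(rng) && diff(rng) > 0)
    warning("bin_width exceeds the data range; summaries use a single ",
            "bin per side", call. = FALSE)
  # edges anchored at x0: x0 + k * bin_width covering the data
  k_lo <- floor((rng[1] - x0) / bin_width)
  k_hi <- ceiling((rng[2] - x0) / bin_width)
  if (x0 + k_hi * bin_width <= rng[2]) k_hi <- k_hi + 1L
  edges <- x0 + (k_lo:k_hi) * bin_width
  # bins are [low, high), matching z = 1(x >= x0) at the threshold edge
  idx <- findInterval(data$x, edges, rightmost.closed = FALSE)
  v <- data[[value]]
  rows <- lapply(seq_len(length(edges) - 1L), function(b) {
    inb <- idx == b
    n <- sum(inb)
    data.frame(bin_low = edges[b], bin_high = edges[b + 1L],
               midpoint = (edges[b] + edges[b + 1L]) / 2, n = n,
               mean_y = if (n) mean(v[inb]) else NA_real_,
               prop_treated = if (n) mean(data$t[inb]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$side <- ifelse(out$bin_low >= x0 - 1e-12, "above", "below")
  structure(out, x0 = x0, bin_width = bin_width, value = value,
            class = c("binned_summary", "data.frame"))
}

#' Test the instrument-relevance assumption
#'
#' The threshold indicator must be associated with treatment for the RD
#' design to identify anything. Reports the 2x2 (z, t) table, the
#' difference in treated proportions above minus below with a Wald 95%
#' CI, and a chi-square test; flags a weak instrument when the proportion
#' difference falls below `weak_floor`.
#'
#' @param data an [rd_data] object.
#' @param weak_floor flag threshold for the proportion difference
#'   (default 0.1).
#' @return An object of class `rd_instrument_test`: list with `table`,
#'   `prop_diff`, `ci_low`, `ci_high`, `chisq`, `p_value`, `weak`.
#' @export
test_instrument_association <- function(data, weak_floor = 0.1) {
  stopifnot(inherits(data, "rd_data"))
  n_b <- sum(data$z == 0); n_a <- sum(data$z == 1)
  if (n_b == 0L || n_a == 0L)
    stop("both threshold groups must be non-empty", call. = FALSE)
  tab <- table(z = factor(data$z, 0:1), t = factor(data$t, 0:1))
  p_b <- mean(data$t[data$z == 0]); p_a <- mean(data$t[data$z == 1])
  diff <- p_a - p_b
  se <- sqrt(p_a * (1 - p_a) / n_a + p_b * (1 - p_b) / n_b)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(table = tab, prop_diff = diff,
                 ci_low = diff - 1.96 * se, ci_high = diff + 1.96 * se,
                 chisq = unname(chi$statistic), p_value = chi$p.value,
                 weak = diff < weak_floor, weak_floor = weak_floor),
            class = "rd_instrument_test")
}

#' @export
print.rd_instrument_test <- function(x, ...) {
  cat("Instrument relevance (threshold indicator vs treatment)\n")
  print(x$table)
  cat(sprintf("  treated proportion difference %.3f, 95%% CI (%.3f, %.3f)\n",
              x$prop_diff, x$ci_low, x$ci_high))
  cat(sprintf("  chi-square %.2f, p = %.3g\n", x$chisq, x$p_value))
  if (x$weak)
    cat("  WARNING: difference below ", x$weak_floor,
        " -- weak instrument\n", sep = "")
  invisible(x)
}

#' Covariate continuity at the threshold
#'
#' Continuity diagnostics for an observed covariate: binned means of the
#' covariate across the threshold, plus the difference between the two
#' bins adjacent to the threshold with a Wald 95% CI. A discontinuity in
#' an observed confounder at the threshold calls the design into
#' question.
#'
#' @param data an [rd_data] object carrying the covariate as a column.
#' @param covariate column name.
#' @param bin_width bin width (default 0.02).
#' @return list with `bins` (a `binned_summary` of the covariate) and
#'   `adjacent` (difference of the bins next to the threshold, with
#'   `ci_low`, `ci_high`).
#' @export
covariate_continuity <- function(data, covariate, bin_width = 0.02) {
  stopifnot(inherits(data, "rd_data"))
  if (!covariate %in% names(data))
    stop("covariate column '", covariate, "' not found", call. = FALSE)
  if (!is.numeric(data[[covariate]]))
    stop("covariate '", covariate, "' must be numeric", call. = FALSE)
  bins <- bin_summaries(data, bin_width, value = covariate)
  x0 <- attr(bins, "x0")
  below <- bins[bins$side == "below" & bins$n > 0, ]
  above <- bins[bins$side == "above" & bins$n > 0, ]
  if (nrow(below) == 0L || nrow(above) == 0L)
    stop("no non-empty bins on one side of the threshold", call. = FALSE)
  bin_b <- below[which.max(below$bin_high), ]
  bin_a <- above[which.min(above$bin_low), ]
  v <- data[[covariate]]
  in_b <- data$x >= bin_b$bin_low & data$x < bin_b$bin_high
  in_a <- data$x >= bin_a$bin_low & data$x < bin_a$bin_high
  diff <- mean(v[in_a]) - mean(v[in_b])
  se <- sqrt(stats::var(v[in_a]) / sum(in_a) + stats::var(v[in_b]) / sum(in_b))
  if (!is.finite(se)) se <- 0  # constant covariate within both bins
  list(bins = bins,
       adjacent = list(difference = diff, ci_low = diff - 1.96 * se,
                       ci_high = diff + 1.96 * se,
                       bin_below = c(bin_b$bin_low, bin_b$bin_high),
                       bin_above = c(bin_a$bin_low, bin_a$bin_high)))
}

#' Plain-text assumptions report
#'
#' Summarises what the data can and cannot say about the identifying
#' assumptions: instrument relevance (tested), covariate continuity
#' (tested per supplied covariate), and the untestable assumptions --
#' guideline independence, unconfoundedness, monotonicity -- which are
#' stated explicitly rather than silently presumed.
#'
#' @param data an [rd_data] object.
#' @param covariates character vector of covariate columns to check.
#' @param bin_width bin width for continuity checks.
#' @return character vector of report lines (also printed invisibly via
#'   `cat` when `print = TRUE`).
#' @param print print the report to the console.
#' @export
assumptions_report <- function(data, covariates = character(),
                               bin_width = 0.02, print = TRUE) {
  a1 <- test_instrument_association(data)
  lines <- c(
    "RD design assumptions report",
    "============================",
    sprintf("A1 instrument relevance: treated proportion difference %.3f (95%% CI %.3f, %.3f); chi-square p = %.3g%s",
            a1$prop_diff, a1$ci_low, a1$ci_high, a1$p_value,
            if (a1$weak) " -- WEAK instrument" else ""),
    "A2 guideline independence: untestable (involves unobserved confounders); plausible when the threshold is externally imposed.",
    "A3 unconfoundedness: untestable; requires that subjects cannot manipulate their side of the threshold.")
  if (length(covariates)) {
    for (cv in covariates) {
      cc <- covariate_continuity(data, cv, bin_width)
      lines <- c(lines, sprintf(
        "A4 continuity of '%s': adjacent-bin difference %.3f (95%% CI %.3f, %.3f)",
        cv, cc$adjacent$difference, cc$adjacent$ci_low, cc$adjacent$ci_high))
    }
  } else {
    lines <- c(lines,
      "A4 continuity: partly testable; supply observed covariates to check.")
  }
  lines <- c(lines,
    "A5 monotonicity (no defiers): untestable from the data; requires no prescriber who systematically inverts the guideline.")
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
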