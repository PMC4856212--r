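# Figure renderings. All numbers shown are computed by bin_summaries();
# the plots are pure presentation and optionally overlay a loess smoother
# per side to highlight the underlying pattern.

#' Discontinuity plots
#'
#' `plot_raw()` shows the raw assignment score against the outcome with
#' treated/untreated marked; `plot_binned_outcome()` shows per-bin mean
#' outcomes; `plot_binned_treatment()` shows per-bin treated proportions.
#' A dashed vertical line marks the threshold. Smoothers (loess per side)
#' are cosmetic and can be disabled.
#'
#' @param data an [rd_data] object.
#' @param bin_width bin width for the binned panels.
#' @param smooth overlay a per-side loess smoother.
#' @return a ggplot object.
#' @export
plot_raw <- function(data) {
  stopifnot(inherits(data, "rd_data"))
  x0 <- attr(data, "x0")
  df <- data.frame(x = data$x, y = data$y,
                   treated = factor(data$t, 0:1, c("untreated", "treated")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   shape = .data$treated)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_shape_manual(values = c(untreated = 1, treated = 4)) +
    ggplot2::geom_vline(xintercept = x0, linetype = "dashed") +
    ggplot2::labs(x = "assignment score", y = "outcome", shape = NULL) +
    ggplot2::theme_minimal()
}

.plot_binned <- function(data, bin_width, what, ylab, smooth) {
  bins <- bin_summaries(data, bin_width)
  x0 <- attr(bins, "x0")
  df <- as.data.frame(bins)
  df <- df[df$n > 0, ]
  df$value <- df[[what]]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint,
                                        y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = x0, linetype = "dashed") +
    ggplot2::labs(x = "assignment score (bin midpoint)", y = ylab) +
    ggplot2::theme_minimal()
  if (smooth && nrow(df) >= 8)
    p <- p + ggplot2::geom_smooth(ggplot2::aes(group = .data$side),
                                  method = "loess", formula = y ~ x,
                                  se = FALSE, linewidth = 0.5)
  p
}

#' @rdname plot_raw
#' @export
plot_binned_outcome <- function(data, bin_width = 0.02, smooth = TRUE) {
  .plot_binned(data, bin_width, "mean_y", "mean outcome per bin", smooth)
}

#' @rdname plot_raw
#' @export
plot_binned_treatment <- function(data, bin_width = 0.02, smooth = TRUE) {
  .plot_binned(data, bin_width, "prop_treated",
               "treated proportion per bin", smooth)
}
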