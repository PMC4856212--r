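#' Construct a regression discontinuity dataset
#'
#' Bundles patient-level records for a regression discontinuity (RD)
#' analysis: a continuous assignment score `x` (e.g. 10-year cardiovascular
#' risk), a binary treatment indicator `t` (1 = treated, e.g. statin
#' prescribed), a continuous outcome `y` (e.g. LDL cholesterol in mmol/l)
#' and the guideline threshold `x0`. The threshold indicator
#' `z = 1(x >= x0)` is derived, never supplied: a record exactly at the
#' threshold belongs to the "above" group.
#'
#' Records with missing `x`, `t` or `y` are dropped with a message; the
#' number dropped is kept in the object. Optional covariate columns (for
#' continuity diagnostics) are carried through unchanged.
#'
#' @param x numeric vector of assignment scores.
#' @param t binary (0/1) treatment indicator, same length as `x`.
#' @param y numeric outcome vector, same length as `x`.
#' @param x0 scalar threshold on the scale of `x`.
#' @param id optional subject identifiers (defaults to `seq_along(x)`).
#' @param covariates optional data frame of named covariate columns.
#' @return An object of class `rd_data`: a data frame with columns
#'   `id`, `x`, `t`, `y`, `z` plus any covariates, and attributes
#'   `x0`, `n_dropped`, and (after [filter_bandwidth()]) `bandwidth`.
#' @examples
#' d <- rd_data(x = c(0.15, 0.20, 0.30), t = c(0, 1, 1),
#'              y = c(3.9, 2.1, 2.3), x0 = 0.2)
#' d$z  # 0 1 1 -- the threshold itself counts as "above"
#' @export
rd_data <- function(x, t, y, x0, id = NULL, covariates = NULL) {
  if (!is.numeric(x) || !is.numeric(y))
    stop("'x' and 'y' must be numeric vectors", call. = FALSE)
  n <- length(x)
  if (n < 1L) stop("need at least one record", call. = FALSE)
  if (length(t) != n || length(y) != n)
    stop("'x', 't' and 'y' must have equal length", call. = FALSE)
  if (!is.numeric(x0) || length(x0) != 1L || !is.finite(x0))
    stop("'x0' must be a single finite number", call. = FALSE)
  if (is.null(id)) id <- seq_len(n)
  if (length(id) != n) stop("'id' must match the number of records", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("'covariates' must have one row per record", call. = FALSE)
  }

  keep <- !(is.na(x) | is.na(t) | is.na(y))
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message("rd_data: dropped ", n_dropped, " record(s) with missing x, t or y")
    x <- x[keep]; t <- t[keep]; y <- y[keep]; id <- id[keep]
    if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  }
  if (length(x) == 0L) stop("all records had missing values", call. = FALSE)

  bad <- which(!is.finite(x))
  if (length(bad))
    stop("non-finite assignment score at record(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(y))
  if (length(bad))
    stop("non-finite outcome at record(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  t <- as.numeric(t)
  if (!all(t %in% c(0, 1)))
    stop("'t' must contain only 0 and 1", call. = FALSE)

  out <- data.frame(id = id, x = x, t = t, y = y,
                    z = threshold_indicator(x, x0))
  if (!is.null(covariates)) out <- cbind(out, covariates)
  structure(out, x0 = x0, n_dropped = n_dropped, bandwidth = NULL,
            class = c("rd_data", "data.frame"))
}

#' Threshold indicator
#'
#' Derives the binary instrument `z` from the assignment score:
#' `z = 1` where `x >= x0` and `z = 0` where `x < x0`. The boundary is
#' inclusive above, so a score exactly at the threshold is assigned
#' `z = 1` (the guideline recommends treatment at the threshold).
#'
#' @param x numeric vector of assignment scores (all finite).
#' @param x0 scalar threshold.
#' @return integer vector of 0/1, same length as `x`.
#' @examples
#' threshold_indicator(c(0.19, 0.20, 0.21), 0.20)  # 0 1 1
#' @export
threshold_indicator <- function(x, x0) {
  bad <- which(!is.finite(x))
  if (length(bad))
    stop("non-finite assignment score at record(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  as.integer(x >= x0)
}

#' Centre assignment scores at the threshold
#'
#' Returns `x - x0`, the signed distance from the threshold used as the
#' regressor in the local linear outcome model; a subject exactly at the
#' threshold maps to 0, so the model intercepts are the expected outcomes
#' at the threshold itself.
#'
#' @inheritParams threshold_indicator
#' @return numeric vector `x - x0`.
#' @export
center_scores <- function(x, x0) {
  bad <- which(!is.finite(x))
  if (length(bad))
    stop("non-finite assignment score at record(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  x - x0
}

#' Restrict an RD dataset to a bandwidth around the threshold
#'
#' Local linear estimation uses only records within a fixed bandwidth `h`
#' either side of the threshold. The window is closed: records with
#' `|x - x0| <= h` are retained, with a tiny numerical tolerance so that
#' decimal boundaries behave as written (0.15 is kept at `x0 = 0.2`,
#' `h = 0.05` despite binary floating point). Filtering never changes the threshold
#' indicator of a retained record, is idempotent, and is monotone in `h`.
#'
#' @param data an [rd_data] object.
#' @param h positive scalar bandwidth, on the scale of `x`.
#' @return The filtered `rd_data` object, with attributes `bandwidth = h`
#'   and `n_retained = c(below, above)`. An error is raised if either side
#'   of the threshold is left empty.
#' @examples
#' d <- rd_data(x = c(0.10, 0.16, 0.24, 0.50), t = c(0, 0, 1, 1),
#'              y = c(4, 4, 2, 2), x0 = 0.2)
#' nrow(filter_bandwidth(d, 0.05))  # 2 (0.16 and 0.24)
#' @export
filter_bandwidth <- function(data, h) {
  stopifnot(inherits(data, "rd_data"))
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("bandwidth 'h' must be a single positive number", call. = FALSE)
  x0 <- attr(data, "x0")
  eps <- 1e-9 * max(1, abs(x0), h)
  keep <- abs(data$x - x0) <= h + eps
  out <- data[keep, , drop = FALSE]
  n_below <- sum(out$z == 0)
  n_above <- sum(out$z == 1)
  if (n_below == 0L)
    stop("no records below the threshold within bandwidth ", h, call. = FALSE)
  if (n_above == 0L)
    stop("no records above the threshold within bandwidth ", h, call. = FALSE)
  attr(out, "x0") <- x0
  attr(out, "n_dropped") <- attr(data, "n_dropped")
  attr(out, "bandwidth") <- h
  attr(out, "n_retained") <- c(below = n_below, above = n_above)
  class(out) <- c("rd_data", "data.frame")
  out
}

#' @export
print.rd_data <- function(x, ...) {
  x0 <- attr(x, "x0")
  h <- attr(x, "bandwidth")
  cat("RD dataset: ", nrow(x), " records, threshold x0 = ", x0, sep = "")
  if (!is.null(h)) cat(", bandwidth h = ", h, sep = "")
  cat("\n  below threshold: ", sum(x$z == 0),
      "   above: ", sum(x$z == 1),
      "   treated: ", sum(x$t == 1), "\n", sep = "")
  if (isTRUE(attr(x, "n_dropped") > 0))
    cat("  (", attr(x, "n_dropped"), " record(s) dropped for missingness)\n",
        sep = "")
  invisible(x)
}

#' Read an RD dataset from a delimited text file
#'
#' Reads a CSV with a header row and builds an [rd_data] object. The
#' threshold is always supplied by the analyst, never inferred from the
#' data. Column names are configurable; any additional columns named in
#' `covariate_cols` are carried as covariates.
#'
#' @param path path to a CSV file.
#' @param x0 scalar threshold.
#' @param x_col,t_col,y_col,id_col column names (defaults `"x"`, `"t"`,
#'   `"y"`; `id_col = NULL` uses row numbers).
#' @param covariate_cols character vector of extra columns to carry.
#' @return An [rd_data] object.
#' @export
read_rd_csv <- function(path, x0, x_col = "x", t_col = "t", y_col = "y",
                        id_col = NULL, covariate_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(x_col, t_col, y_col, id_col, covariate_cols)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  rd_data(x = df[[x_col]], t = df[[t_col]], y = df[[y_col]], x0 = x0,
          id = if (is.null(id_col)) NULL else df[[id_col]],
          covariates = if (length(covariate_cols))
            df[covariate_cols] else NULL)
}
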