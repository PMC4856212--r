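# Replicate-level simulation-study harness: run every estimator over R
# seeded cohorts per scenario and combine, mirroring the layout of a
# confounding-by-instrument-strength results table.

#' Combine replicate estimates by Rubin's rules
#'
#' Pools point estimates across replicates as their mean, and combines
#' uncertainty as total variance `W + (1 + 1/R) * B`, where `W` is the
#' mean within-replicate variance and `B` the between-replicate variance
#' of the estimates. The 95% interval uses the normal multiplier 1.96; a
#' small-sample degrees-of-freedom refinement is available via
#' `df_adjust = TRUE` (Rubin's `nu = (R - 1) * (1 + W / ((1 + 1/R) B))^2`).
#' With `R = 1` the between-replicate variance is undefined and is
#' dropped (total = W), with a message.
#'
#' @param estimates numeric vector of R point estimates.
#' @param variances numeric vector of R squared standard errors.
#' @param df_adjust use the t multiplier with Rubin's degrees of freedom
#'   instead of 1.96.
#' @return list with `estimate`, `total_var`, `within`, `between`,
#'   `ci_low`, `ci_high`, `R`.
#' @examples
#' rubin_combine(c(-2, -1, -3), c(0.25, 0.25, 0.25))
#' # pooled -2, total variance 0.25 + (1 + 1/3) * 1 = 1.5833...
#' @export
rubin_combine <- function(estimates, variances, df_adjust = FALSE) {
  if (length(estimates) != length(variances))
    stop("'estimates' and 'variances' must have equal length", call. = FALSE)
  R <- length(estimates)
  if (R < 1L) stop("need at least one replicate", call. = FALSE)
  if (any(variances < 0)) stop("variances must be >= 0", call. = FALSE)
  pooled <- mean(estimates)
  W <- mean(variances)
  if (R == 1L) {
    message("rubin_combine: single replicate, between-replicate variance dropped")
    B <- NA_real_
    total <- W
    mult <- 1.96
  } else {
    B <- stats::var(estimates)
    total <- W + (1 + 1 / R) * B
    mult <- 1.96
    if (df_adjust && B > 0) {
      nu <- (R - 1) * (1 + W / ((1 + 1 / R) * B))^2
      mult <- stats::qt(0.975, nu)
    }
  }
  list(estimate = pooled, total_var = total, within = W, between = B,
       ci_low = pooled - mult * sqrt(total),
       ci_high = pooled + mult * sqrt(total), R = R)
}

#' Combine replicate posterior summaries by averaging
#'
#' The Bayesian combination rule for replicate simulations: the
#' elementwise arithmetic mean of the posterior means and of the 95%
#' credible interval limits across replicates.
#'
#' @param means numeric vector of R posterior means.
#' @param lowers,uppers numeric vectors of R interval limits.
#' @return list with `estimate`, `ci_low`, `ci_high`, `R`.
#' @export
bayes_combine <- function(means, lowers, uppers) {
  R <- length(means)
  if (R < 1L) stop("need at least one replicate", call. = FALSE)
  if (length(lowers) != R || length(uppers) != R)
    stop("'means', 'lowers' and 'uppers' must have equal length",
         call. = FALSE)
  list(estimate = mean(means), ci_low = mean(lowers),
       ci_high = mean(uppers), R = R)
}

#' Configure a replicate simulation study
#'
#' Defines the scenario grid (confounding levels x instrument strengths
#' x effect sizes x bandwidths), the number of replicate cohorts per
#' scenario, the estimators to run, and the master seed from which every
#' replicate seed is derived deterministically (so scenarios can be run
#' in any order, or resumed, with identical results).
#'
#' @param confounding_levels integer subset of 1:4.
#' @param instruments subset of `c("strong", "weak")`.
#' @param taus true effect magnitudes (reductions, mmol/l).
#' @param bandwidths positive bandwidths (defaults 0.05, 0.15, 0.25).
#' @param replicates cohorts per scenario (the full study uses 100).
#' @param n cohort size per replicate.
#' @param estimators subset of `dbeta_freq`, `dbeta_wip`, `dbeta_sip`,
#'   `late_unct`, `late_flex`.
#' @param sampler a [sampler_settings()] template; its seed is replaced
#'   per fit.
#' @param seed master seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(confounding_levels = c(1, 3),
                         instruments = c("strong", "weak"),
                         taus = 2,
                         bandwidths = c(0.05, 0.15, 0.25),
                         replicates = 100, n = 5720,
                         estimators = c("dbeta_freq", "dbeta_wip",
                                        "dbeta_sip", "late_unct",
                                        "late_flex"),
                         sampler = sampler_settings(chains = 2, warmup = 1000,
                                                    iter = 1000),
                         seed = 1) {
  stopifnot(all(confounding_levels %in% 1:4),
            all(instruments %in% c("strong", "weak")),
            all(bandwidths > 0), replicates >= 1, n >= 1)
  estimators <- match.arg(estimators, several.ok = TRUE)
  grid <- expand.grid(confounding_level = confounding_levels,
                      instrument = instruments, tau = taus,
                      bandwidth = bandwidths,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  structure(list(grid = grid, replicates = as.integer(replicates),
                 n = as.integer(n), estimators = estimators,
                 sampler = sampler, seed = as.integer(seed)),
            class = "study_config")
}

# All estimators on one bandwidth-filtered replicate dataset. Returns one
# row per estimator; failures come back as NA with the message logged.
.fit_estimators <- function(d, estimators, sampler) {
  res <- list()
  num_sip <- NULL
  need_sip <- any(c("dbeta_sip", "late_unct", "late_flex") %in% estimators)
  safe <- function(expr) tryCatch(expr, error = function(e) e$message)
  if (need_sip)
    num_sip <- safe(fit_numerator(d, prior_spec("sip"), sampler))

  for (est in estimators) {
    row <- switch(est,
      dbeta_freq = {
        f <- safe(ols_ate(d))
        if (is.character(f)) f else
          data.frame(estimate = f$estimate, ci_low = f$ci_low,
                     ci_high = f$ci_high, variance = f$se^2)
      },
      dbeta_wip = {
        f <- safe(fit_numerator(d, prior_spec("wip"), sampler))
        if (is.character(f)) f else {
          s <- f$summary[f$summary$parameter == "phi", ]
          data.frame(estimate = s$mean, ci_low = s$q2.5,
                     ci_high = s$q97.5, variance = s$sd^2)
        }
      },
      dbeta_sip = {
        if (is.character(num_sip)) num_sip else {
          s <- num_sip$summary[num_sip$summary$parameter == "phi", ]
          data.frame(estimate = s$mean, ci_low = s$q2.5,
                     ci_high = s$q97.5, variance = s$sd^2)
        }
      },
      late_unct = ,
      late_flex = {
        if (is.character(num_sip)) num_sip else {
          pr <- prior_spec("sip", if (est == "late_flex") "fdp" else "unc")
          f <- safe(compose_late(num_sip, fit_denominator(d, pr, sampler)))
          if (is.character(f)) f else {
            s <- f$summary[f$summary$parameter == "late", ]
            data.frame(estimate = s$mean, ci_low = s$q2.5,
                       ci_high = s$q97.5, variance = s$sd^2)
          }
        }
      })
    if (is.character(row)) {
      res[[est]] <- data.frame(estimator = est, estimate = NA_real_,
                               ci_low = NA_real_, ci_high = NA_real_,
                               variance = NA_real_, error = row)
    } else {
      res[[est]] <- cbind(data.frame(estimator = est), row,
                          data.frame(error = NA_character_))
    }
  }
  do.call(rbind, c(res, make.row.names = FALSE))
}

#' Run one scenario of a simulation study
#'
#' Generates `replicates` seeded cohorts for the given scenario, filters
#' to the bandwidth, fits every requested estimator on each, and combines
#' (Rubin's rules for the frequentist estimator, averaged posterior
#' summaries for the Bayesian ones). Replicate-level failures — e.g. a
#' near-degenerate denominator — are logged, not fatal; the scenario is
#' flagged if more than 20% of replicate fits of any estimator failed.
#'
#' @param scenario one row of a [study_config()] grid (a list/data.frame
#'   with `confounding_level`, `instrument`, `tau`, `bandwidth`).
#' @param config the enclosing [study_config()].
#' @param scenario_seed integer seed for this scenario.
#' @return list with `combined` (one row per estimator) and `raw` (one
#'   row per replicate x estimator).
#' @export
run_scenario <- function(scenario, config, scenario_seed) {
  R <- config$replicates
  rep_seeds <- derive_seeds(scenario_seed, 2L * R)
  raw <- vector("list", R)
  for (r in seq_len(R)) {
    cc <- cohort_config(n = config$n, tau = scenario$tau,
                        confounding_level = scenario$confounding_level,
                        instrument = scenario$instrument,
                        seed = rep_seeds[r])
    cohort <- generate_cohort(cc)
    d <- filter_bandwidth(cohort$data, scenario$bandwidth)
    smp <- config$sampler
    smp$seed <- rep_seeds[R + r]
    fits <- .fit_estimators(d, config$estimators, smp)
    raw[[r]] <- cbind(data.frame(replicate = r), fits)
  }
  raw <- do.call(rbind, raw)

  combined <- do.call(rbind, lapply(config$estimators, function(est) {
    sub <- raw[raw$estimator == est, ]
    ok <- sub[!is.na(sub$estimate), ]
    n_failed <- nrow(sub) - nrow(ok)
    if (nrow(ok) == 0L)
      return(data.frame(estimator = est, estimate = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        method = NA_character_, n_failed = n_failed,
                        flagged = TRUE))
    if (est == "dbeta_freq") {
      cmb <- suppressMessages(rubin_combine(ok$estimate, ok$variance))
      method <- "rubin"
    } else {
      cmb <- bayes_combine(ok$estimate, ok$ci_low, ok$ci_high)
      method <- "bayes-average"
    }
    data.frame(estimator = est, estimate = cmb$estimate,
               ci_low = cmb$ci_low, ci_high = cmb$ci_high,
               method = method, n_failed = n_failed,
               flagged = n_failed > 0.2 * R)
  }))
  list(combined = combined, raw = raw)
}

#' Run a full replicate simulation study
#'
#' Loops [run_scenario()] over the scenario grid. Scenario seeds are
#' derived deterministically from the master seed and the scenario index,
#' so the same configuration always yields the same result and scenarios
#' can be recomputed independently. If `out_dir` is given, each finished
#' scenario is checkpointed as a CSV and skipped (re-read) on a rerun,
#' making an interrupted study resumable.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory for per-scenario checkpoints.
#' @param verbose print progress to stderr.
#' @return An object of class `study_result`: list with `table` (tidy
#'   data frame: scenario columns, estimator, estimate, ci_low, ci_high,
#'   method, n_failed, flagged), `raw` (per-replicate estimates), and
#'   `config`.
#' @export
run_study <- function(config, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "study_config"))
  grid <- config$grid
  scen_seeds <- derive_seeds(config$seed, nrow(grid))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  tabs <- vector("list", nrow(grid))
  raws <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    scen <- grid[i, ]
    tag <- sprintf("scenario_%02d", i)
    ck <- if (!is.null(out_dir)) file.path(out_dir, paste0(tag, ".csv"))
    scen_cols <- data.frame(scenario = i,
                            confounding_level = scen$confounding_level,
                            instrument = scen$instrument,
                            tau = scen$tau, bandwidth = scen$bandwidth)
    if (!is.null(ck) && file.exists(ck)) {
      tabs[[i]] <- utils::read.csv(ck, stringsAsFactors = FALSE)
      if (verbose) message(tag, ": restored from checkpoint")
      next
    }
    if (verbose)
      message(tag, ": level ", scen$confounding_level, ", ",
              scen$instrument, ", tau ", scen$tau, ", h ", scen$bandwidth)
    res <- run_scenario(scen, config, scen_seeds[i])
    tabs[[i]] <- cbind(scen_cols, res$combined, row.names = NULL)
    raws[[i]] <- cbind(scen_cols, res$raw, row.names = NULL)
    if (!is.null(ck)) utils::write.csv(tabs[[i]], ck, row.names = FALSE)
  }
  structure(list(table = do.call(rbind, tabs),
                 raw = do.call(rbind, raws),
                 config = config),
            class = "study_result")
}

#' Format a study result as a text table
#'
#' Renders the combined estimates as a Markdown-style table with one row
#' per scenario and one `estimate (ci_low, ci_high)` column per
#' estimator, mirroring the usual presentation of RD simulation studies.
#'
#' @param result a `study_result`.
#' @return character vector of table lines.
#' @export
format_study_table <- function(result) {
  stopifnot(inherits(result, "study_result"))
  tab <- result$table
  ests <- unique(tab$estimator)
  key <- unique(tab[c("scenario", "confounding_level", "instrument",
                      "tau", "bandwidth")])
  header <- paste0("| IV | Confounding | tau | h | ",
                   paste(ests, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", 4 + length(ests)), collapse = "|"), "|")
  rows <- vapply(seq_len(nrow(key)), function(i) {
    k <- key[i, ]
    cells <- vapply(ests, function(e) {
      r <- tab[tab$scenario == k$scenario & tab$estimator == e, ]
      if (nrow(r) == 0L || is.na(r$estimate)) return("--")
      sprintf("%.2f (%.2f, %.2f)%s", r$estimate, r$ci_low, r$ci_high,
              if (isTRUE(r$flagged)) " *" else "")
    }, "")
    paste0("| ", k$instrument, " | ", k$confounding_level, " | ", k$tau,
           " | ", k$bandwidth, " | ", paste(cells, collapse = " | "), " |")
  }, "")
  c(header, sep, rows)
}

#' @export
print.study_result <- function(x, ...) {
  cat("RD simulation study: ", length(unique(x$table$scenario)),
      " scenario(s) x ", x$config$replicates, " replicate(s)\n", sep = "")
  cat(format_study_table(x), sep = "\n")
  if (any(x$table$flagged, na.rm = TRUE))
    cat("* > 20% replicate failures\n")
  invisible(x)
}
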