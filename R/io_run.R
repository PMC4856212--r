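# Config-driven entry points tying the modules into a runnable tool:
# rd_fit() analyses one dataset (file or generated), rd_simulate() writes
# a cohort, rd_study() runs the replicate harness. Each run writes a
# manifest (config + seed + versions) sufficient to reproduce it exactly;
# no command mutates its inputs. A thin command-line wrapper over these
# functions ships in inst/cli/bayesrd.

#' Read a run configuration from YAML or JSON
#'
#' Configuration files are YAML by default; JSON is accepted by file
#' extension. The result is a plain named list; each `rd_*` entry point
#' documents the fields it uses, and function arguments override config
#' values.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

.write_manifest <- function(out_dir, command, config) {
  manifest <- list(command = command, config = config,
                   package_version = as.character(utils::packageVersion("bayesrd")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.load_input <- function(config) {
  has_file <- !is.null(config$input)
  has_gen <- !is.null(config$cohort)
  if (has_file == has_gen)
    stop("config must specify exactly one data source: 'input' (CSV path) ",
         "or 'cohort' (generator settings)", call. = FALSE)
  if (has_file) {
    if (is.null(config$x0))
      stop("config field 'x0' (threshold) is required with a CSV input",
           call. = FALSE)
    read_rd_csv(config$input, x0 = config$x0,
                x_col = config$x_col %||% "x",
                t_col = config$t_col %||% "t",
                y_col = config$y_col %||% "y",
                covariate_cols = config$covariate_cols %||% character())
  } else {
    generate_cohort(do.call(cohort_config, config$cohort))$data
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.sampler_from_config <- function(config) {
  s <- config$sampler %||% list()
  sampler_settings(chains = s$chains %||% 4,
                   warmup = s$warmup %||% 2000,
                   iter = s$iter %||% 2000,
                   seed = config$seed %||% 1,
                   rhat_tol = s$rhat_tol %||% 1.05)
}

#' Fit all RD estimators on one dataset
#'
#' Reads (or generates) a dataset, then for every configured bandwidth
#' runs the requested estimators and the assumption diagnostics, and
#' writes: `summaries.csv` (one row per bandwidth x estimator),
#' optionally `draws_<h>_<estimator>.csv` (posterior draws),
#' `assumptions.txt`, and `manifest.json`.
#'
#' Config fields: `input`+`x0` or `cohort` (one of them, never both);
#' `bandwidths` (vector, required); `estimators` (default all of
#' `dbeta_freq`, `dbeta_wip`, `dbeta_sip`, `late_unct`, `late_flex`);
#' `sampler` (`chains`, `warmup`, `iter`); `seed`; `write_draws`
#' (logical); `covariates` (columns for continuity checks).
#'
#' @param config a named list (see [read_run_config()]).
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the summary table and the per-bandwidth
#'   fit objects.
#' @export
rd_fit <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  data <- .load_input(config)
  bandwidths <- config$bandwidths
  if (is.null(bandwidths)) stop("config field 'bandwidths' is required",
                                call. = FALSE)
  estimators <- config$estimators %||%
    c("dbeta_freq", "dbeta_wip", "dbeta_sip", "late_unct", "late_flex")
  sampler <- .sampler_from_config(config)

  rows <- list(); fits <- list()
  for (h in bandwidths) {
    d <- filter_bandwidth(data, h)
    fit <- .fit_estimators(d, estimators, sampler)
    rows[[as.character(h)]] <- cbind(data.frame(bandwidth = h), fit)
    fits[[as.character(h)]] <- fit
    if (isTRUE(config$write_draws)) {
      num <- fit_numerator(d, prior_spec("sip"), sampler)
      den <- fit_denominator(d, prior_spec("sip", "fdp"), sampler)
      late <- compose_late(num, den)
      utils::write.csv(late$draws,
                       file.path(out_dir, sprintf("draws_h%s_late_flex.csv", h)),
                       row.names = FALSE)
    }
  }
  summaries <- do.call(rbind, c(rows, make.row.names = FALSE))
  utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                   row.names = FALSE)
  rep_lines <- assumptions_report(data,
                                  covariates = config$covariates %||% character(),
                                  print = FALSE)
  writeLines(rep_lines, file.path(out_dir, "assumptions.txt"))
  .write_manifest(out_dir, "fit", config)
  invisible(list(summaries = summaries, fits = fits))
}

#' Generate and write a synthetic cohort
#'
#' Config fields are the arguments of [cohort_config()], plus `sharp`
#' (logical) to force perfect adherence. Writes `cohort.csv`,
#' `cohort_truth.json` and `manifest.json`; identical configs give
#' byte-identical cohort files.
#'
#' @inheritParams rd_fit
#' @return Invisibly, the generated `rd_cohort`.
#' @export
rd_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sharp <- isTRUE(config$sharp)
  cfg_fields <- config[intersect(names(config), names(formals(cohort_config)))]
  cc <- do.call(cohort_config, cfg_fields)
  cohort <- if (sharp) generate_sharp_cohort(cc) else generate_cohort(cc)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  .write_manifest(out_dir, "simulate", config)
  invisible(cohort)
}

#' Run a replicate simulation study from a configuration
#'
#' Config fields are the arguments of [study_config()] (with `sampler` a
#' sub-list as in [rd_fit()]). Writes `study.csv` (tidy combined table),
#' `study.md` (formatted table), per-scenario checkpoints (making an
#' interrupted study resumable) and `manifest.json`.
#'
#' @inheritParams rd_fit
#' @return Invisibly, the `study_result`.
#' @export
rd_study <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sc <- study_config(
    confounding_levels = config$confounding_levels %||% c(1, 3),
    instruments = config$instruments %||% c("strong", "weak"),
    taus = config$taus %||% 2,
    bandwidths = config$bandwidths %||% c(0.05, 0.15, 0.25),
    replicates = config$replicates %||% 100,
    n = config$n %||% 5720,
    estimators = config$estimators %||%
      c("dbeta_freq", "dbeta_wip", "dbeta_sip", "late_unct", "late_flex"),
    sampler = .sampler_from_config(config),
    seed = config$seed %||% 1)
  res <- run_study(sc, out_dir = file.path(out_dir, "checkpoints"))
  utils::write.csv(res$table, file.path(out_dir, "study.csv"),
                   row.names = FALSE)
  writeLines(format_study_table(res), file.path(out_dir, "study.md"))
  .write_manifest(out_dir, "study", config)
  invisible(res)
}
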