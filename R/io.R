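# Cohort/config I/O and the command-line entry point.
#
# CSV dialect: comma-separated, UTF-8, "." decimal, header row required;
# NA tokens are "" and "NA". Missing analysis values lead to complete-case
# dropping with a logged count.

#' Read a cohort CSV
#'
#' Reads and type-checks a cohort table against a design: every design column
#' must be present and numeric (cells failing numeric coercion are an
#' error), and rows with missing analysis values are dropped (complete-case
#' analysis, logged via `message()`).
#'
#' @param path CSV file path.
#' @param design a [study_design()].
#' @return data frame of complete cases.
#' @export
read_cohort_csv <- function(path, design) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  tab <- utils::read.csv(path, header = TRUE, na.strings = c("", "NA"),
                         fileEncoding = "UTF-8")
  if (nrow(tab) == 0L) stop("cohort file is empty: ", path)
  vars <- design_vars(design)
  missing <- setdiff(vars, names(tab))
  if (length(missing))
    stop("cohort CSV is missing column(s): ", paste(missing, collapse = ", "))
  for (v in vars) {
    if (!is.numeric(tab[[v]])) {
      coerced <- suppressWarnings(as.numeric(tab[[v]]))
      bad <- !is.na(tab[[v]]) & is.na(coerced)
      if (any(bad))
        stop("non-numeric value(s) in column '", v, "' (first at row ",
             which(bad)[1], ")")
      tab[[v]] <- coerced
    }
  }
  message("read ", nrow(tab), " rows from ", basename(path))
  drop_incomplete(tab, design)
}

#' Read a synthetic-model config
#'
#' YAML schema mirroring [synthetic_model()]:
#' ```yaml
#' n: 510
#' noise_sd: 1
#' singles:
#'   - {name: age, mean: 73.5, sd: 3}
#' categories:
#'   obesity:
#'     rho: 0.5
#'     members:
#'       - {name: bmi, mean: 27, sd: 4, effect: 0.05}
#' ```
#' Alternatively `template: salia` loads [salia_template()] (with optional
#' `n` and `n_snps` overrides).
#'
#' @param path YAML file path.
#' @return a `synthetic_model`.
#' @export
read_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (identical(cfg$template, "salia"))
    return(salia_template(n = cfg$n %||% 510, n_snps = cfg$n_snps %||% 20))
  synthetic_model(
    n = cfg$n %||% stop("model config lacks 'n'"),
    singles = cfg$singles %||% list(),
    categories = cfg$categories %||% list(),
    noise_sd = cfg$noise_sd %||% 1,
    single_cor = if (!is.null(cfg$single_cor))
      do.call(rbind, cfg$single_cor))
}

#' Write pipeline results to a directory
#'
#' Writes `contributions.csv` (predictor, median and CI bounds of the LMG
#' share, as percentages, sorted by descending median), `coefficients.csv`
#' (term, median, CI bounds, bootstrap p-value), `weights.csv` (median
#' risk-score weight per member) and `manifest.json` (config echo, seed,
#' input digests, package version, flag counts, wall clock) — enough to
#' reproduce the run bit for bit given the same code version.
#'
#' @param fit an `rscontrib` fit.
#' @param dir output directory (created if needed).
#' @param inputs optional named character vector of input file paths to
#'   digest into the manifest.
#' @param elapsed optional wall-clock seconds to record.
#' @return `dir`, invisibly.
#' @export
write_results <- function(fit, dir, inputs = character(), elapsed = NA_real_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- fit$summary
  contr <- s$contributions
  contr[-1] <- lapply(contr[-1], function(v) round(100 * v, 6))
  utils::write.csv(contr, file.path(dir, "contributions.csv"),
                   row.names = FALSE)
  utils::write.csv(s$coefficients, file.path(dir, "coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(s$weights, file.path(dir, "weights.csv"),
                   row.names = FALSE)

  flags <- table(unlist(lapply(fit$replicates, function(r)
    sub(":.*$", "", r$flags))))
  manifest <- list(
    package = "rscontrib",
    version = as.character(utils::packageVersion("rscontrib")),
    config = unclass(fit$config),
    n = fit$n,
    n_failed_replicates = sum(fit$failed),
    flag_counts = as.list(flags),
    input_digests = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    elapsed_seconds = elapsed,
    note = paste("bootstrap p-values are the sign-crossing interpretation",
                 "2*min(f+, f-); the percentile CI convention is type 7"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

# write a CSV whose doubles round-trip exactly (17 significant digits);
# used for simulated cohorts so simulate -> write -> read is lossless
write_csv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

# ---- command-line interface -------------------------------------------------

cli_usage <- function() {
  cat("usage: rscontrib <simulate|run|report> [options]\n",
      "  simulate --model FILE --seed N --out DIR\n",
      "  run      --cohort FILE --design FILE [--config FILE] [--seed N]\n",
      "           [--bootstrap B] [--train-fraction F]\n",
      "           [--standardize-on train|full] [--cv-repeats N] --out DIR\n",
      "  report   --results DIR\n", sep = "")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    if (i == length(args)) stop("flag ", a, " needs a value")
    flags[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

cli_simulate <- function(flags) {
  model <- read_model(flags$model %||% stop("simulate needs --model"))
  seed <- as.integer(flags$seed %||% 1)
  out <- flags$out %||% stop("simulate needs --out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(model, seed)
  write_csv_full(cohort$data, file.path(out, "cohort.csv"))
  write_design(cohort$design, file.path(out, "design.yaml"))
  truth <- true_contributions(model)
  jsonlite::write_json(list(r2 = truth$r2, shares = as.list(truth$shares)),
                       file.path(out, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  message("wrote cohort.csv, design.yaml, truth.json to ", out)
  0L
}

cli_run <- function(flags) {
  design <- read_design(flags$design %||% stop("run needs --design"))
  cohort <- read_cohort_csv(flags$cohort %||% stop("run needs --cohort"),
                            design)
  config <- analysis_config(
    B = as.integer(flags$bootstrap %||% 200),
    train_fraction = as.numeric(flags$`train-fraction` %||% 0.6),
    cv_repeats = as.integer(flags$`cv-repeats` %||% 20),
    seed = as.integer(flags$seed %||% 1),
    standardize_on = flags$`standardize-on` %||% "train")
  out <- flags$out %||% stop("run needs --out")
  t0 <- proc.time()[["elapsed"]]
  fit <- rscontrib(cohort, design, config)
  write_results(fit, out,
                inputs = c(cohort = flags$cohort, design = flags$design),
                elapsed = proc.time()[["elapsed"]] - t0)
  message("results written to ", out)
  0L
}

cli_report <- function(flags) {
  dir <- flags$results %||% stop("report needs --results")
  contr <- utils::read.csv(file.path(dir, "contributions.csv"))
  contr <- contr[order(-contr$median), ]
  cat("Relative contributions (% of outcome variance), sorted by median\n")
  print(contr, row.names = FALSE)
  coefs <- utils::read.csv(file.path(dir, "coefficients.csv"))
  cat("\nRegression coefficients (bootstrap median, CI, p)\n")
  print(coefs, row.names = FALSE)
  0L
}

#' Command-line entry point
#'
#' Dispatcher behind the `inst/cli/rscontrib` script. Subcommands:
#' `simulate` (synthetic-model config to cohort CSV + design + ground-truth
#' JSON), `run` (cohort + design to result CSVs and a manifest) and `report`
#' (human-readable tables sorted by descending median share).
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code (0 on success).
#' @export
rd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) { cli_usage(); return(1L) }
  cmd <- args[1]
  res <- tryCatch({
    flags <- parse_flags(args[-1])
    switch(cmd,
           simulate = cli_simulate(flags),
           run = cli_run(flags),
           report = cli_report(flags),
           { cli_usage(); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(res)
}
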