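#' Pipeline run configuration
#'
#' Bundles everything a reproducible run needs: either an input cohort
#' CSV or a simulation spec, the contrast, optional covariates, the
#' validation and training settings, panel reduction, and the output
#' directory.  The seed is mandatory and drives every stochastic stage.
#'
#' @param input_csv Path to a cohort CSV (mutually exclusive with
#'   `simulate`).
#' @param simulate A [cohort_spec()] to generate the cohort from.
#' @param contrast A [contrast()] or `"NEG:POS"` string.
#' @param covariates `NULL` or subset of `c("age", "bmi", "sex")`.
#' @param panel Optional metabolite subset.
#' @param reduce_to `NULL`, or the steroid count to backward-eliminate
#'   to (e.g. 10).
#' @param comparators Clinical scores to evaluate alongside (default
#'   FIB-4 and NAFLD fibrosis score).
#' @param n_splits,test_fraction Validation settings.
#' @param uncorrected Per-litre mode (skip creatinine correction).
#' @param train_config A [gmlvq_train_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_csv = NULL, simulate = NULL,
                       contrast = NULL,
                       covariates = NULL, panel = NULL,
                       reduce_to = NULL,
                       comparators = c("fib4", "nfs"),
                       n_splits = 50, test_fraction = 0.2,
                       uncorrected = FALSE,
                       train_config = gmlvq_train_config(),
                       out_dir = ".", seed = 1L) {
  if (is.null(input_csv) == is.null(simulate)) {
    stopf("exactly one of input_csv / simulate must be given")
  }
  if (!is.null(contrast) && is.character(contrast)) {
    contrast <- parse_contrast(contrast)
  }
  structure(list(input_csv = input_csv, simulate = simulate,
                 contrast = contrast, covariates = covariates,
                 panel = panel, reduce_to = reduce_to,
                 comparators = comparators, n_splits = n_splits,
                 test_fraction = test_fraction,
                 uncorrected = uncorrected, train_config = train_config,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

load_records <- function(config) {
  if (!is.null(config$simulate)) {
    generate_cohort(config$simulate)
  } else {
    read_cohort_csv(config$input_csv)
  }
}

# Machine-readable manifest: the settings, seed and package version,
# plus an md5 of the serialised configuration — enough to reproduce the
# run exactly.
write_manifest <- function(config, out_dir, outputs) {
  cfg_path <- file.path(out_dir, "config.json")
  doc <- list(
    input_csv = config$input_csv,
    simulate = if (!is.null(config$simulate)) {
      spec <- config$simulate
      list(n_per_class = as.list(spec$n_per_class), panel = spec$panel,
           noise_sd = spec$noise_sd,
           detection_floor = spec$detection_floor, seed = spec$seed)
    },
    contrast = if (!is.null(config$contrast)) config$contrast$tag,
    covariates = config$covariates, panel = config$panel,
    reduce_to = config$reduce_to, comparators = config$comparators,
    n_splits = config$n_splits, test_fraction = config$test_fraction,
    uncorrected = config$uncorrected,
    train_config = unclass(config$train_config),
    seed = config$seed)
  jsonlite::write_json(doc, cfg_path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  manifest <- list(
    package = "steroidstage",
    version = as.character(utils::packageVersion("steroidstage")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(manifest)
}

#' Run the simulation stage
#'
#' Generates the synthetic cohort and writes it (plus a config echo and
#' manifest) into the output directory.
#'
#' @param config A [run_config()] with a `simulate` spec.
#' @return Invisible path of the written cohort CSV.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$simulate)) stopf("run_simulate needs a simulate spec")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config$simulate)
  path <- file.path(config$out_dir, "cohort.csv")
  write_cohort_csv(cohort, path)
  write_manifest(config, config$out_dir, outputs = "cohort.csv")
  invisible(path)
}

#' Run the staging analysis
#'
#' Full pipeline for one binary contrast: preprocessing and GMLVQ
#' repeated-split validation (optionally with covariates — the
#' augmented-model variant), optional backward panel reduction, and
#' optional comparator-score ROCs.  All artifacts (report JSON, pooled
#' ROC CSV, trajectory JSON/CSV, manifest) are written to the output
#' directory.
#'
#' @param config A [run_config()] with a `contrast`.
#' @return Invisible list: `report` (a `validation_report`),
#'   `trajectory` (`panel_trajectory` or `NULL`), `comparators` (named
#'   list of [comparator_roc()] results).
#' @export
run_stage <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$contrast)) stopf("run_stage needs a contrast")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- load_records(config)
  unknown <- setdiff(c(config$contrast$negative, config$contrast$positive),
                     unique(records$stage))
  if (length(unknown)) {
    stopf("contrast label(s) absent from the cohort: %s",
          paste(unknown, collapse = ", "))
  }
  report <- repeated_split_validation(
    records, config$contrast, n_splits = config$n_splits,
    test_fraction = config$test_fraction, seed = config$seed,
    covariates = config$covariates, panel = config$panel,
    uncorrected = config$uncorrected, train_config = config$train_config)
  outputs <- c("report.json", "pooled_roc.csv")
  report_to_json(report, file.path(config$out_dir, "report.json"))
  write_roc_csv(report$pooled_roc,
                file.path(config$out_dir, "pooled_roc.csv"))
  trajectory <- NULL
  if (!is.null(config$reduce_to)) {
    trajectory <- backward_eliminate(
      records, config$contrast, stop_at = config$reduce_to,
      n_splits = config$n_splits, test_fraction = config$test_fraction,
      seed = config$seed, covariates = config$covariates,
      panel = config$panel, uncorrected = config$uncorrected,
      train_config = config$train_config)
    trajectory_write(trajectory,
                     json_path = file.path(config$out_dir,
                                           "trajectory.json"),
                     csv_path = file.path(config$out_dir,
                                          "trajectory.csv"))
    outputs <- c(outputs, "trajectory.json", "trajectory.csv")
  }
  comparators <- list()
  for (sc in config$comparators) {
    comparators[[sc]] <- comparator_roc(records, config$contrast, sc)
    path <- sprintf("roc_%s.csv", sc)
    write_roc_csv(comparators[[sc]]$curve,
                  file.path(config$out_dir, path))
    outputs <- c(outputs, path)
  }
  write_manifest(config, config$out_dir, outputs = outputs)
  invisible(list(report = report, trajectory = trajectory,
                 comparators = comparators))
}

#' Run the clinical-score stage
#'
#' Batch computation of the five comparator scores; subjects that cannot
#' be scored are listed in an exclusion report, never silently dropped.
#'
#' @param config A [run_config()].
#' @return Invisible path of the written score CSV (exclusions, if any,
#'   in `excluded.csv` next to it).
#' @export
run_scores <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- load_records(config)
  panel <- score_cohort(records)
  path <- file.path(config$out_dir, "scores.csv")
  write.csv(panel, path, row.names = FALSE)
  outputs <- "scores.csv"
  excl <- attr(panel, "excluded")
  if (nrow(excl)) {
    write.csv(excl, file.path(config$out_dir, "excluded.csv"),
              row.names = FALSE)
    outputs <- c(outputs, "excluded.csv")
  }
  write_manifest(config, config$out_dir, outputs = outputs)
  invisible(path)
}
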