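#' Rank features by mean relevance
#'
#' Orders features by descending mean diagonal relevance from a
#' [repeated_split_validation()] report; exact ties are broken
#' alphabetically and flagged.
#'
#' @param report A `validation_report` with `relevance_mean` (i.e. from
#'   a GMLVQ run, not a comparator).
#' @return Character vector of feature names, most relevant first, with
#'   logical attribute `"tie"` marking features tied with a neighbour.
#' @export
rank_features <- function(report) {
  rel <- if (inherits(report, "validation_report")) {
    report$relevance_mean
  } else {
    report  # a named relevance vector is accepted directly
  }
  if (is.null(rel)) stopf("report carries no relevance information")
  ord <- order(-rel, names(rel))
  ranked <- names(rel)[ord]
  sorted <- rel[ord]
  tie <- rep(FALSE, length(sorted))
  if (length(sorted) > 1) {
    same <- sorted[-length(sorted)] == sorted[-1]
    tie[which(same)] <- TRUE
    tie[which(same) + 1] <- TRUE
  }
  attr(ranked, "tie") <- tie
  ranked
}

#' Backward elimination to a reduced steroid panel
#'
#' Sequentially removes the least discriminatory metabolite: each round
#' runs [repeated_split_validation()] on the current panel, records the
#' mean AUC and CI, then drops the steroid with the smallest mean
#' relevance, until `stop_at` steroids remain (the reduced-panel model).
#' Covariates (age/BMI/sex), when enabled, are part of every model but
#' exempt from removal.  `mode = "fixed_rank"` instead prunes against
#' the full-panel ranking without re-validating the ranking at each
#' step (one validation per panel size is still run to track AUC).
#'
#' @inheritParams repeated_split_validation
#' @param stop_at Target number of steroids (default 10).
#' @param mode `"sequential"` (re-rank after every removal; default) or
#'   `"fixed_rank"`.
#' @return An object of class `panel_trajectory`: `steps` (data frame
#'   `panel_size`, `removed_feature`, `auc_mean`, `ci_lo`, `ci_hi`),
#'   `final_panel`, `ranking` (full-panel relevance ranking), and the
#'   final size's `report`.
#' @export
backward_eliminate <- function(records, contrast, stop_at = 10,
                               n_splits = 20, test_fraction = 0.2,
                               seed = 1L, covariates = NULL,
                               panel = NULL, uncorrected = FALSE,
                               train_config = gmlvq_train_config(),
                               mode = c("sequential", "fixed_rank")) {
  mode <- match.arg(mode)
  if (is.null(panel)) panel <- intersect(default_panel(), names(records))
  if (stop_at >= length(panel)) {
    stopf("stop_at (%d) must be smaller than the starting panel (%d)",
          stop_at, length(panel))
  }
  validate <- function(pn, s) {
    repeated_split_validation(records, contrast, n_splits = n_splits,
                              test_fraction = test_fraction, seed = s,
                              covariates = covariates, panel = pn,
                              uncorrected = uncorrected,
                              train_config = train_config)
  }
  # Per-step seeds derived deterministically from the master seed.
  n_steps <- length(panel) - stop_at + 1
  step_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1,
                                           n_steps))
  steroid_rel <- function(report, pn) {
    report$relevance_mean[intersect(names(report$relevance_mean), pn)]
  }
  current <- panel
  steps <- data.frame(panel_size = integer(0),
                      removed_feature = character(0),
                      auc_mean = numeric(0), ci_lo = numeric(0),
                      ci_hi = numeric(0), stringsAsFactors = FALSE)
  report <- validate(current, step_seeds[1])
  ranking <- rank_features(report)
  fixed_order <- rank_features(
    stats::setNames(steroid_rel(report, current), current))
  removed <- NA_character_
  step <- 1L
  repeat {
    steps <- rbind(steps, data.frame(
      panel_size = length(current), removed_feature = removed,
      auc_mean = report$auc_mean, ci_lo = report$ci95[["lo"]],
      ci_hi = report$ci95[["hi"]], stringsAsFactors = FALSE))
    if (length(current) == stop_at) break
    removed <- if (mode == "sequential") {
      rel <- steroid_rel(report, current)
      rank_features(rel)[length(rel)]
    } else {
      rev(intersect(fixed_order, current))[1]
    }
    current <- setdiff(current, removed)
    step <- step + 1L
    report <- validate(current, step_seeds[step])
  }
  structure(list(steps = steps, final_panel = current,
                 ranking = ranking, contrast = report$contrast,
                 report = report, mode = mode, seed = seed),
            class = "panel_trajectory")
}

#' @export
print.panel_trajectory <- function(x, ...) {
  first <- x$steps[1, ]
  last <- x$steps[nrow(x$steps), ]
  cat(sprintf(
    "Panel trajectory [%s]: %d -> %d steroids, mean AUC %.3f -> %.3f\n",
    x$contrast$tag, first$panel_size, last$panel_size, first$auc_mean,
    last$auc_mean))
  cat("  final panel: ", paste(x$final_panel, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Serialise a panel trajectory
#'
#' JSON with the step table, final panel and full ranking, plus a flat
#' CSV of the steps (`panel_size`, `removed_feature`, `auc_mean`,
#' `ci_lo`, `ci_hi`).
#'
#' @param trajectory A `panel_trajectory`.
#' @param json_path,csv_path Output paths (either may be `NULL` to
#'   skip).
#' @return Invisible list of written paths.
#' @export
trajectory_write <- function(trajectory, json_path = NULL,
                             csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(steps = trajectory$steps,
           final_panel = trajectory$final_panel,
           ranking = as.character(trajectory$ranking),
           mode = trajectory$mode, seed = trajectory$seed),
      json_path, digits = I(17), auto_unbox = TRUE, null = "null")
  }
  if (!is.null(csv_path)) {
    write.csv(trajectory$steps, csv_path, row.names = FALSE)
  }
  invisible(list(json = json_path, csv = csv_path))
}
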