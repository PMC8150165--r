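#' Feature matrix container
#'
#' Lightweight container for an n x d numeric feature table with class
#' labels and, once standardised, the normalisation statistics captured
#' at fit time.
#'
#' @param values Numeric matrix (subjects x features), finite, with
#'   column names.
#' @param labels Character/factor vector of length `nrow(values)`.
#' @param normalisation Optional list with numeric vectors `mean` and
#'   `sd` (one entry per feature, population SD > 0); present only on
#'   matrices that have been z-scored.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, normalisation = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stopf("values must have column names")
  if (anyDuplicated(colnames(values))) {
    stopf("feature names must be unique")
  }
  if (!all(is.finite(values))) stopf("values must be finite (no NaN/Inf)")
  if (length(labels) != nrow(values)) {
    stopf("labels length (%d) != number of rows (%d)", length(labels),
          nrow(values))
  }
  if (!is.null(normalisation)) {
    stopifnot(length(normalisation$mean) == ncol(values),
              length(normalisation$sd) == ncol(values),
              all(normalisation$sd > 0))
  }
  structure(list(values = values,
                 feature_names = colnames(values),
                 labels = as.character(labels),
                 normalisation = normalisation),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d subjects x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$normalisation)) "raw scale" else "z-scored"))
  tab <- table(x$labels)
  cat("  labels: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Creatinine correction of urinary concentrations
#'
#' Normalises a spot-urine concentration (ug/L) to grams of urinary
#' creatinine, adjusting for urine dilution:
#' `ug/g = ug/L * 100 / creatinine(mg/dL)` (100 mg/dL = 1 g/L).
#'
#' @param concentration_ug_l Concentration(s), ug/L, >= 0.
#' @param creatinine_mg_dl Urinary creatinine, mg/dL, > 0; recycled
#'   against `concentration_ug_l`.
#' @param subject_id Optional ids used in error messages.
#' @return Concentration in ug steroid / g creatinine.
#' @export
#' @examples
#' creatinine_correct(50, 100)  # 50 ug/g
creatinine_correct <- function(concentration_ug_l, creatinine_mg_dl,
                               subject_id = NULL) {
  if (any(concentration_ug_l < 0, na.rm = TRUE)) {
    stopf("negative steroid concentration")
  }
  bad <- which(!(creatinine_mg_dl > 0))
  if (length(bad)) {
    who <- if (!is.null(subject_id)) {
      paste(subject_id[bad], collapse = ", ")
    } else paste("index", paste(bad, collapse = ", "))
    stopf("non-positive creatinine for: %s", who)
  }
  concentration_ug_l * 100 / creatinine_mg_dl
}

# Per-feature detection floor: half the smallest positive value of each
# column; columns with no positive value fall back to `fallback`.
log10_floors <- function(values, fallback = 0.5) {
  apply(as.matrix(values), 2, function(col) {
    pos <- col[col > 0]
    if (length(pos)) min(pos) / 2 else fallback
  })
}

#' Floored log10 transform
#'
#' Replaces each value by `log10(max(value, floor))`.  The floor handles
#' concentrations reported as 0 (below the assay detection limit)
#' without dropping subjects; by default it is half the smallest positive
#' value of each feature, computed from `values` itself (pass the floors
#' computed on a training split to transform held-out data without
#' leakage).
#'
#' @param values Numeric matrix of non-negative values (columns =
#'   features) or a [feature_matrix()].
#' @param floor Positive scalar or per-feature vector; `NULL` (default)
#'   computes per-feature floors from `values` via half-minimum-positive.
#' @return Same shape as the input, log10-transformed; the applied floors
#'   are attached as attribute `"floors"`.
#' @export
#' @examples
#' log10_transform(matrix(c(100, 0), 2, 1,
#'                        dimnames = list(NULL, "x")), floor = 0.5)
log10_transform <- function(values, floor = NULL) {
  fm <- NULL
  if (inherits(values, "feature_matrix")) {
    fm <- values
    values <- fm$values
  }
  values <- as.matrix(values)
  if (any(values < 0)) stopf("log10_transform requires values >= 0")
  if (is.null(floor)) floor <- log10_floors(values)
  if (any(floor <= 0)) stopf("floor must be > 0")
  floors <- rep_len(floor, ncol(values))
  out <- log10(pmax(values, matrix(floors, nrow(values), ncol(values),
                                   byrow = TRUE)))
  dimnames(out) <- dimnames(values)
  attr(out, "floors") <- stats::setNames(floors, colnames(values))
  if (!is.null(fm)) {
    res <- feature_matrix(out, fm$labels)
    attr(res, "floors") <- attr(out, "floors")
    return(res)
  }
  out
}

#' Fit-and-apply z-scoring without test-set leakage
#'
#' Standardises the training matrix to per-feature mean 0 and SD 1
#' (population convention, divide by n) and applies the *training* means
#' and SDs to any further matrices, so no statistic of held-out data ever
#' enters the transform.  Re-standardising an already z-scored matrix is
#' refused.
#'
#' @param train A [feature_matrix()] without normalisation.
#' @param ... Further `feature_matrix` objects transformed with the
#'   training statistics.
#' @return A list with `train` and one entry per extra matrix (named as
#'   passed, else `other1`, `other2`, ...), each carrying the training
#'   normalisation.
#' @export
zscore_fit_apply <- function(train, ...) {
  stopifnot(inherits(train, "feature_matrix"))
  if (!is.null(train$normalisation)) {
    stopf("matrix is already z-scored; refusing to re-standardise")
  }
  m <- colMeans(train$values)
  n <- nrow(train$values)
  sdev <- sqrt(colMeans(sweep(train$values, 2, m)^2))
  zero <- which(sdev <= 0 | !is.finite(sdev))
  if (length(zero)) {
    stopf("zero-variance feature(s) in training data: %s",
          paste(train$feature_names[zero], collapse = ", "))
  }
  norm <- list(mean = stats::setNames(m, train$feature_names),
               sd = stats::setNames(sdev, train$feature_names))
  others <- list(...)
  if (length(others) && is.null(names(others))) {
    names(others) <- paste0("other", seq_along(others))
  }
  out <- c(list(train = zscore_apply(train, norm)),
           lapply(others, zscore_apply, norm = norm))
  out
}

#' @rdname zscore_fit_apply
#' @param fm A `feature_matrix` to transform.
#' @param norm Normalisation list (`mean`, `sd`) from a fitted training
#'   matrix.
#' @export
zscore_apply <- function(fm, norm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!is.null(fm$normalisation)) {
    stopf("matrix is already z-scored; refusing to re-standardise")
  }
  if (!identical(fm$feature_names, names(norm$mean))) {
    stopf("feature names do not match the fitted normalisation")
  }
  z <- sweep(sweep(fm$values, 2, norm$mean), 2, norm$sd, "/")
  feature_matrix(z, fm$labels, normalisation = norm)
}

#' Metabolites summed into total glucocorticoid excretion
#'
#' The 11 cortisol/cortisone metabolites whose sum quantifies total
#' glucocorticoid output.
#' @return Character vector of 11 metabolite names.
#' @export
total_f_metabolites <- function() {
  c("6b_hydroxycortisol", "tetrahydrocortisol", "5a_tetrahydrocortisol",
    "a_cortol", "b_cortol", "11b_hydroxyetiocholanolone", "cortisone",
    "tetrahydrocortisone", "a_cortolone", "b_cortolone",
    "11_oxoetiocholanolone")
}

#' Glucocorticoid enzyme-activity ratios and total excretion
#'
#' Computes, from creatinine-corrected (non-log) concentrations:
#' 11beta-HSD1 activity `(THF + 5aTHF) / THE` (cortisol regeneration),
#' A-ring (5alpha-)reductase activity `5aTHF / THF` (cortisol
#' inactivation), and total cortisol-metabolite excretion as the sum of
#' the 11 metabolites in [total_f_metabolites()].  Ratios cancel the
#' creatinine factor, so they are identical on corrected and uncorrected
#' data.  A zero denominator yields `NA` for that subject's ratio with a
#' warning — it never aborts the batch.
#'
#' @param corrected Data frame or matrix of creatinine-corrected
#'   concentrations with (at least) columns `tetrahydrocortisol`,
#'   `5a_tetrahydrocortisol`, `tetrahydrocortisone` and the 11 total-F
#'   metabolites.
#' @return Data frame with columns `hsd11b1_activity`,
#'   `a_ring_reductase_activity`, `total_f_metabolites` (ug/g
#'   creatinine), one row per input row.
#' @export
compute_ratios <- function(corrected) {
  corrected <- as.data.frame(corrected, check.names = FALSE)
  need <- c("tetrahydrocortisol", "5a_tetrahydrocortisol",
            "tetrahydrocortisone")
  miss <- setdiff(need, names(corrected))
  if (length(miss)) stopf("missing metabolite column(s): %s",
                          paste(miss, collapse = ", "))
  thf <- corrected[["tetrahydrocortisol"]]
  athf <- corrected[["5a_tetrahydrocortisol"]]
  the <- corrected[["tetrahydrocortisone"]]
  hsd <- ifelse(the > 0, (thf + athf) / the, NA_real_)
  aring <- ifelse(thf > 0, athf / thf, NA_real_)
  n_flagged <- sum(the <= 0) + sum(thf <= 0)
  if (n_flagged > 0) {
    warnf("%d ratio(s) undefined (zero denominator); returned as NA",
          n_flagged)
  }
  tot_names <- total_f_metabolites()
  miss <- setdiff(tot_names, names(corrected))
  if (length(miss)) stopf("missing total-F metabolite column(s): %s",
                          paste(miss, collapse = ", "))
  total <- rowSums(as.matrix(corrected[tot_names]))
  data.frame(hsd11b1_activity = hsd,
             a_ring_reductase_activity = aring,
             total_f_metabolites = total)
}

#' Append clinical covariates to a feature matrix
#'
#' Adds age, BMI and/or sex columns to a steroid feature matrix, on the
#' raw scale (sex coded F = 0, M = 1).  Standardisation of the augmented
#' matrix then happens through the usual [zscore_fit_apply()] discipline,
#' so covariates obey the same train-only fit as the steroids.
#'
#' @param fm A [feature_matrix()] (not yet z-scored).
#' @param records Cohort data frame aligned row-for-row with `fm`.
#' @param covariates Subset of `c("age", "bmi", "sex")`.
#' @return A `feature_matrix` with `length(covariates)` extra columns
#'   (`age_years`, `bmi_kg_m2`, `sex`).
#' @export
augment_covariates <- function(fm, records,
                               covariates = c("age", "bmi")) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(covariates) == 0) return(fm)
  covariates <- match.arg(covariates, c("age", "bmi", "sex"),
                          several.ok = TRUE)
  if (nrow(records) != nrow(fm$values)) {
    stopf("records (%d rows) do not align with the feature matrix (%d)",
          nrow(records), nrow(fm$values))
  }
  colmap <- c(age = "age_years", bmi = "bmi_kg_m2", sex = "sex")
  cols <- lapply(covariates, function(cv) {
    src <- colmap[[cv]]
    if (!src %in% names(records)) stopf("records lack column '%s'", src)
    val <- records[[src]]
    if (cv == "sex") val <- as.numeric(records[[src]] == "M")
    if (anyNA(val)) {
      stopf("missing %s for subject(s): %s", cv,
            paste(records$subject_id[is.na(val)], collapse = ", "))
    }
    val
  })
  newnames <- colmap[covariates]
  dup <- intersect(newnames, fm$feature_names)
  if (length(dup)) stopf("feature(s) already present: %s",
                         paste(dup, collapse = ", "))
  aug <- cbind(fm$values,
               matrix(unlist(cols), ncol = length(cols),
                      dimnames = list(NULL, newnames)))
  feature_matrix(aug, fm$labels)
}

#' Steroid features for a cohort table
#'
#' Convenience builder: extracts the panel columns from a cohort data
#' frame and creatinine-corrects them (ug/g creatinine), or, in
#' uncorrected mode, leaves them as ug/L (numerically equal to ug/1000 mL
#' urine).  No log transform or scaling is applied here; those are fitted
#' per training split downstream.
#'
#' @param records Cohort data frame (see [generate_cohort()]).
#' @param panel Metabolite columns to use; default: every
#'   [default_panel()] name present in `records`.
#' @param uncorrected If `TRUE`, skip creatinine correction.
#' @return Numeric matrix (subjects x metabolites).
#' @export
cohort_steroid_matrix <- function(records, panel = NULL,
                                  uncorrected = FALSE) {
  if (is.null(panel)) panel <- intersect(default_panel(), names(records))
  miss <- setdiff(panel, names(records))
  if (length(miss)) stopf("cohort lacks metabolite column(s): %s",
                          paste(miss, collapse = ", "))
  raw <- as.matrix(records[panel])
  if (uncorrected) return(raw)
  out <- apply(raw, 2, creatinine_correct,
               creatinine_mg_dl = records$creatinine_mg_dl,
               subject_id = records$subject_id)
  matrix(out, nrow = nrow(raw), dimnames = list(NULL, panel))
}
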