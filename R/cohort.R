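#' Default 32-steroid urinary panel
#'
#' The urinary steroid metabolites quantified by the GC-MS multi-steroid
#' profile: androgen, glucocorticoid and mineralocorticoid metabolites.
#' The 26 metabolites that appear in the enzyme-activity formulas, the
#' total-glucocorticoid sum and the discriminatory rankings are padded to
#' 32 with common panel steroids; the padding entries are placeholders and
#' fully configurable through [cohort_spec()].
#'
#' @return Character vector of 32 metabolite names (snake_case).
#' @export
#' @examples
#' default_panel()
default_panel <- function() {
  c("androsterone", "etiocholanolone", "dehydroepiandrosterone",
    "16a_hydroxy_dhea", "androstenedione", "11b_hydroxyandrosterone",
    "11b_hydroxyetiocholanolone", "11_oxoetiocholanolone",
    "pregnanediol", "pregnenediol", "pregnanetriol", "pregnenetriol",
    "pregnanetriolone", "tetrahydrocortisol", "5a_tetrahydrocortisol",
    "tetrahydrocortisone", "cortisol", "cortisone", "6b_hydroxycortisol",
    "a_cortol", "b_cortol", "a_cortolone", "b_cortolone",
    "tetrahydrocorticosterone", "5a_tetrahydrocorticosterone",
    "tetrahydro_11_dehydrocorticosterone",
    "5a_tetrahydro_11_dehydrocorticosterone",
    "tetrahydro_11_deoxycorticosterone", "tetrahydrodeoxycortisol",
    "tetrahydroaldosterone", "5a_dihydrotestosterone", "testosterone")
}

# Baseline log10 concentration (ug/L) per metabolite, chosen to span the
# abundance range seen in adult spot urine: major glucocorticoid
# tetrahydro-metabolites in the mg/L range, trace androgens near the
# detection limit (so the low-value handling downstream is exercised).
default_baseline_log10 <- function() {
  c(androsterone = 3.0, etiocholanolone = 3.0,
    dehydroepiandrosterone = 2.0, `16a_hydroxy_dhea` = 2.3,
    androstenedione = 1.5, `11b_hydroxyandrosterone` = 2.6,
    `11b_hydroxyetiocholanolone` = 2.3, `11_oxoetiocholanolone` = 2.5,
    pregnanediol = 2.7, pregnenediol = 2.3, pregnanetriol = 2.8,
    pregnenetriol = 2.1, pregnanetriolone = 1.5,
    tetrahydrocortisol = 3.2, `5a_tetrahydrocortisol` = 3.2,
    tetrahydrocortisone = 3.5, cortisol = 1.9, cortisone = 2.0,
    `6b_hydroxycortisol` = 1.5, a_cortol = 2.5, b_cortol = 2.4,
    a_cortolone = 2.8, b_cortolone = 2.6,
    tetrahydrocorticosterone = 2.3, `5a_tetrahydrocorticosterone` = 2.4,
    tetrahydro_11_dehydrocorticosterone = 2.2,
    `5a_tetrahydro_11_dehydrocorticosterone` = 2.1,
    tetrahydro_11_deoxycorticosterone = 1.6,
    tetrahydrodeoxycortisol = 1.3, tetrahydroaldosterone = 1.6,
    `5a_dihydrotestosterone` = 0.3, testosterone = 0.7)
}

# Class-conditional covariate and serum-chemistry parameters.  Values for
# controls, F0-2 and F3-4 follow the demographic table of the emulated
# study design (mean +/- SD); entries the study reports as n/a for
# controls use normal-range clinical values.  F0/F1/F2 share the early-
# fibrosis parameters, F3/F4 the advanced-fibrosis parameters.
default_class_params <- function() {
  control <- list(age = c(55.5, 11.1), bmi = c(30.7, 5.8), t2d = 0.038,
                  ast = c(22, 8), alt = c(13.2, 8.7),
                  platelets = c(250, 60), albumin = c(4.5, 0.3),
                  hba1c = c(38.6, 10.4))
  early <- list(age = c(45.6, 12.0), bmi = c(38.5, 7.0), t2d = 0.308,
                ast = c(34.4, 22.0), alt = c(63.4, 51.4),
                platelets = c(242.5, 64.2), albumin = c(4.4, 0.4),
                hba1c = c(40.8, 8.2))
  advanced <- list(age = c(61.8, 10.8), bmi = c(33.7, 5.8), t2d = 0.634,
                   ast = c(49.1, 31.8), alt = c(49.9, 36.9),
                   platelets = c(183.9, 67.0), albumin = c(4.1, 0.5),
                   hba1c = c(50.0, 13.5))
  alcohol <- list(age = c(58, 11), bmi = c(29, 5), t2d = 0.25,
                  ast = c(70, 35), alt = c(40, 25),
                  platelets = c(150, 60), albumin = c(3.6, 0.6),
                  hba1c = c(40, 10))
  list(control = control, F0 = early, F1 = early, F2 = early,
       F3 = advanced, F4 = advanced, alcohol_cirrhosis = alcohol)
}

# Informative-feature map: per class contrast, the classes whose log10
# means are shifted and the shift per metabolite in units of noise_sd.
# The metabolite lists follow the discriminatory rankings of the emulated
# study; effect sizes decay with rank.  Contrasts whose negative arm is
# the control group are encoded as (negated) shifts of the control class
# itself, so that within the NAFLD spectrum each stage contrast is
# discriminated by its own ranked list rather than by spill-over from
# the screening contrasts.  The enzyme_shift entry raises
# 5a-tetrahydrocortisol and lowers tetrahydrocortisone in advanced
# fibrosis so both glucocorticoid activity ratios rise by construction.
default_informative <- function() {
  r10 <- function(hi, lo) seq(hi, lo, length.out = 10)
  list(
    `F0-2_vs_F3-4` = list(
      classes = c("F3", "F4"),
      effects = stats::setNames(r10(1.1, 0.5), c(
        "etiocholanolone", "dehydroepiandrosterone",
        "5a_tetrahydro_11_dehydrocorticosterone", "androstenedione",
        "5a_tetrahydrocorticosterone", "pregnenetriol",
        "tetrahydro_11_deoxycorticosterone", "tetrahydroaldosterone",
        "cortisone", "11_oxoetiocholanolone"))),
    `F0-3_vs_F4` = list(
      classes = "F4",
      effects = stats::setNames(r10(0.5, 0.15), c(
        "etiocholanolone", "tetrahydrocorticosterone",
        "5a_tetrahydro_11_dehydrocorticosterone",
        "tetrahydro_11_deoxycorticosterone", "dehydroepiandrosterone",
        "androsterone", "tetrahydrocortisone", "tetrahydrocortisol",
        "pregnenetriol", "5a_tetrahydrocorticosterone"))),
    `control_vs_F3-4` = list(
      classes = "control",
      effects = stats::setNames(-r10(0.5, 0.15), c(
        "5a_tetrahydro_11_dehydrocorticosterone", "11_oxoetiocholanolone",
        "etiocholanolone", "cortisone", "pregnenediol", "pregnanetriol",
        "tetrahydro_11_deoxycorticosterone", "11b_hydroxyetiocholanolone",
        "pregnanediol", "5a_tetrahydrocorticosterone"))),
    `control_vs_F4` = list(
      classes = "control",
      effects = stats::setNames(-r10(0.3, 0.1), c(
        "5a_tetrahydro_11_dehydrocorticosterone", "11_oxoetiocholanolone",
        "etiocholanolone", "cortisone",
        "tetrahydro_11_deoxycorticosterone", "pregnenediol",
        "pregnanetriol", "tetrahydrocorticosterone", "pregnanediol",
        "5a_tetrahydrocorticosterone"))),
    `control_vs_F0-4` = list(
      classes = c("F0", "F1", "F2", "F3", "F4"),
      effects = c(androsterone = 0.4, a_cortolone = 0.4,
                  b_cortolone = 0.3, pregnanediol = 0.3)),
    `enzyme_shift_F3-4` = list(
      classes = c("F3", "F4"),
      effects = c(`5a_tetrahydrocortisol` = 0.6,
                  tetrahydrocortisone = -0.4)),
    `F4_vs_alcohol_cirrhosis` = list(
      classes = "alcohol_cirrhosis",
      effects = c(androsterone = -1.0, etiocholanolone = -0.8,
                  dehydroepiandrosterone = -0.8,
                  `11b_hydroxyandrosterone` = 0.6,
                  tetrahydrocortisol = 0.5)))
}

#' Specification of a synthetic steroid-metabolome cohort
#'
#' Defines the statistical structure of a simulated case-control cohort:
#' per-class sample sizes, the steroid panel, which metabolites carry
#' class-dependent shifts (and how large, in units of the within-class
#' log10 SD), per-class covariate and serum-chemistry distributions, the
#' urinary creatinine distribution, and the within-class biological noise.
#'
#' Default per-class sizes mirror a secondary-care NAFLD case-control
#' design: 106 controls, 39 early-fibrosis (F0-F2) and 82
#' advanced-fibrosis (F3-F4) biopsy-staged NAFLD patients and 48
#' alcohol-related cirrhosis patients.  Steroid concentrations are drawn
#' log-normally (normal on the log10 scale, then exponentiated) so they
#' are positive by construction; informative metabolites receive additive
#' shifts on the log10 mean for the classes in each contrast's positive
#' arm.  Alcohol-related cirrhosis reuses the F4 parameterisation plus its
#' own metabolite shift, so aetiology separation is present but imperfect.
#'
#' @param n_per_class Named integer vector: subjects per class label.
#'   Allowed labels: `control`, `F0`..`F4`, `alcohol_cirrhosis`.
#' @param panel Ordered character vector of metabolite names.
#' @param informative_features Named list; each element has `classes`
#'   (labels whose log10 mean is shifted) and `effects` (named numeric
#'   vector, shift in units of `noise_sd`).  Names of the list are
#'   contrast tags used by [ground_truth()].
#' @param class_params Per-class list of covariate/chemistry parameters
#'   (`age`, `bmi`, `ast`, `alt`, `platelets`, `albumin`, `hba1c` as
#'   `c(mean, sd)`; `t2d` as a probability).
#' @param baseline_log10 Named numeric vector of baseline log10
#'   concentrations (ug/L) per panel metabolite.
#' @param creatinine_lognormal `c(meanlog, sdlog)` of urinary creatinine
#'   (mg/dL) on the natural-log scale.
#' @param noise_sd Within-class SD of log10 concentrations.
#' @param detection_floor Concentrations simulated below this value
#'   (ug/L) are reported as 0, emulating the assay detection limit.
#' @param seed Integer seed; the generated cohort is a pure function of
#'   the spec including this seed.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [ground_truth()]
#' @export
cohort_spec <- function(n_per_class = c(control = 106, F0 = 13, F1 = 13,
                                        F2 = 13, F3 = 41, F4 = 41,
                                        alcohol_cirrhosis = 48),
                        panel = default_panel(),
                        informative_features = default_informative(),
                        class_params = default_class_params(),
                        baseline_log10 = default_baseline_log10(),
                        creatinine_lognormal = c(meanlog = log(100),
                                                 sdlog = 0.5),
                        noise_sd = 0.25,
                        detection_floor = 1,
                        seed = 1L) {
  known <- c("control", "F0", "F1", "F2", "F3", "F4", "alcohol_cirrhosis")
  if (is.null(names(n_per_class)) || any(names(n_per_class) == "")) {
    stopf("n_per_class must be a named vector of class sizes")
  }
  bad <- setdiff(names(n_per_class), known)
  if (length(bad)) stopf("unknown class label(s): %s",
                         paste(bad, collapse = ", "))
  if (any(n_per_class < 2)) {
    stopf("every requested class needs n >= 2 (got %s)",
          paste(sprintf("%s=%d", names(n_per_class), n_per_class),
                collapse = ", "))
  }
  if (anyDuplicated(panel)) stopf("panel metabolite names must be unique")
  for (tag in names(informative_features)) {
    entry <- informative_features[[tag]]
    miss <- setdiff(names(entry$effects), panel)
    if (length(miss)) {
      stopf("informative feature(s) not in panel for contrast '%s': %s",
            tag, paste(miss, collapse = ", "))
    }
    badc <- setdiff(entry$classes, known)
    if (length(badc)) stopf("contrast '%s' shifts unknown class: %s",
                            tag, paste(badc, collapse = ", "))
  }
  if (noise_sd <= 0) stopf("noise_sd must be > 0")
  if (creatinine_lognormal[2] <= 0) stopf("creatinine sdlog must be > 0")
  base <- baseline_log10[panel]
  base[is.na(base)] <- 2  # unlisted metabolites default to 100 ug/L
  names(base) <- panel
  structure(list(n_per_class = n_per_class,
                 class_labels = names(n_per_class),
                 panel = panel,
                 informative_features = informative_features,
                 class_params = class_params,
                 baseline_log10 = base,
                 creatinine_lognormal = creatinine_lognormal,
                 noise_sd = noise_sd,
                 detection_floor = detection_floor,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# log10 mean per (class, metabolite) after applying every informative
# shift; alcohol-related cirrhosis starts from the F4 row.
class_log10_means <- function(spec) {
  classes <- union(spec$class_labels, "F4")
  mu <- matrix(rep(spec$baseline_log10, each = length(classes)),
               nrow = length(classes),
               dimnames = list(classes, spec$panel))
  apply_entry <- function(mu, entry, only = NULL) {
    cls <- intersect(entry$classes, rownames(mu))
    if (!is.null(only)) cls <- intersect(cls, only)
    for (cl in cls) {
      mu[cl, names(entry$effects)] <-
        mu[cl, names(entry$effects)] + entry$effects * spec$noise_sd
    }
    mu
  }
  for (entry in spec$informative_features) {
    mu <- apply_entry(mu, entry, only = setdiff(classes,
                                               "alcohol_cirrhosis"))
  }
  if ("alcohol_cirrhosis" %in% rownames(mu)) {
    mu["alcohol_cirrhosis", ] <- mu["F4", ]
    for (entry in spec$informative_features) {
      mu <- apply_entry(mu, entry, only = "alcohol_cirrhosis")
    }
  }
  mu[spec$class_labels, , drop = FALSE]
}

#' Generate a synthetic cohort
#'
#' Draws one subject table from a [cohort_spec()].  Steroid
#' concentrations are normal on the log10 scale with class-specific means
#' and common SD `noise_sd`, then exponentiated; values under the
#' detection floor are reported as 0.  Covariates and serum chemistry are
#' drawn normally per class and truncated to plausible ranges (age 18-90
#' years, BMI 15-60 kg/m2, positive chemistry), so that by construction
#' mean FIB-4 is higher in advanced (F3-F4) than early (F0-F2) fibrosis.
#' NAFLD activity scores (NAS, 0-8) are sampled independently of the
#' steroid signal.
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame`, one row per subject: `subject_id`, `stage`,
#'   `sex` ("M"/"F"), `age_years`, `bmi_kg_m2`, `t2d` (logical),
#'   `ast_iu_l`, `alt_iu_l`, `platelets_1e9_l`, `albumin_g_dl`,
#'   `hba1c_mmol_mol`, `nas_score` (NA outside NAFLD classes),
#'   `creatinine_mg_dl`, then one column per panel metabolite (ug/L).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(
#'   n_per_class = c(F0 = 5, F4 = 5), seed = 7))
#' dim(cohort)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  mu <- class_log10_means(spec)
  with_seed(spec$seed, {
    rows <- lapply(spec$class_labels, function(cl) {
      n <- spec$n_per_class[[cl]]
      p <- spec$class_params[[cl]]
      if (is.null(p)) stopf("no class_params entry for class '%s'", cl)
      d <- length(spec$panel)
      logv <- matrix(rnorm(n * d, mean = rep(mu[cl, ], each = n),
                           sd = spec$noise_sd), nrow = n)
      conc <- 10^logv
      conc[conc < spec$detection_floor] <- 0
      colnames(conc) <- spec$panel
      nas <- if (cl %in% c("F0", "F1", "F2", "F3", "F4")) {
        as.integer(clamp(round(rnorm(n, 4.3, 1.5)), 0, 8))
      } else rep(NA_integer_, n)
      df <- data.frame(
        subject_id = sprintf("%s_%03d", cl, seq_len(n)),
        stage = cl,
        sex = ifelse(runif(n) < 0.5, "F", "M"),
        age_years = clamp(rnorm(n, p$age[1], p$age[2]), 18, 90),
        bmi_kg_m2 = clamp(rnorm(n, p$bmi[1], p$bmi[2]), 15, 60),
        t2d = runif(n) < p$t2d,
        ast_iu_l = clamp(rnorm(n, p$ast[1], p$ast[2]), 5, 500),
        alt_iu_l = clamp(rnorm(n, p$alt[1], p$alt[2]), 5, 500),
        platelets_1e9_l = clamp(rnorm(n, p$platelets[1], p$platelets[2]),
                                50, 600),
        albumin_g_dl = clamp(rnorm(n, p$albumin[1], p$albumin[2]),
                             2, 5.5),
        hba1c_mmol_mol = clamp(rnorm(n, p$hba1c[1], p$hba1c[2]), 20, 130),
        nas_score = nas,
        creatinine_mg_dl = rlnorm(n, spec$creatinine_lognormal[1],
                                  spec$creatinine_lognormal[2]),
        stringsAsFactors = FALSE)
      cbind(df, as.data.frame(conc, check.names = FALSE))
    })
    cohort <- do.call(rbind, rows)
    rownames(cohort) <- NULL
    stopifnot(!anyNA(cohort[setdiff(names(cohort), "nas_score")]),
              all(cohort$creatinine_mg_dl > 0))
    cohort
  })
}

#' Informative metabolites a contrast was simulated with
#'
#' Returns the metabolite names whose log10 means the generator shifts
#' for the given contrast tag — the ground truth against which relevance
#' recovery is judged.
#'
#' @param spec A [cohort_spec()].
#' @param contrast Name of an entry of `spec$informative_features`,
#'   e.g. `"F0-2_vs_F3-4"`.
#' @return Character vector of metabolite names (possibly empty).
#' @export
ground_truth <- function(spec, contrast) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!contrast %in% names(spec$informative_features)) {
    stopf("unknown contrast '%s'; available: %s", contrast,
          paste(names(spec$informative_features), collapse = ", "))
  }
  names(spec$informative_features[[contrast]]$effects)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic steroid cohort specification\n")
  cat("  classes: ",
      paste(sprintf("%s (n=%d)", x$class_labels, x$n_per_class),
            collapse = ", "), "\n", sep = "")
  cat("  panel: ", length(x$panel), " metabolites; noise_sd = ",
      x$noise_sd, " log10 units; seed = ", x$seed, "\n", sep = "")
  cat("  contrasts with simulated signal: ",
      paste(names(x$informative_features), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Write / read a cohort table as CSV
#'
#' Plain UTF-8 CSV with "." as decimal separator; columns are subject id,
#' stage, covariates, serum chemistry, creatinine, then the panel
#' metabolites in spec order.  `read_cohort_csv` restores column types
#' (logical `t2d`, integer `nas_score`).
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly;
#'   `read_cohort_csv` returns the cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialise / restore a cohort specification
#'
#' Writes a [cohort_spec()] as a JSON configuration (17 significant
#' digits) and restores it, so that a spec file fully reproduces a
#' cohort.  The default specification ships with the package:
#' `system.file("extdata", "default_cohort_spec.json",
#' package = "steroidstage")`.
#'
#' @param spec A [cohort_spec()].
#' @param path File path.
#' @return `write_cohort_spec` returns `path` invisibly;
#'   `read_cohort_spec` returns the `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  doc <- list(
    n_per_class = as.list(spec$n_per_class),
    panel = spec$panel,
    informative_features = lapply(spec$informative_features, function(e) {
      list(classes = e$classes, effects = as.list(e$effects))
    }),
    class_params = spec$class_params,
    baseline_log10 = as.list(spec$baseline_log10),
    creatinine_lognormal = as.list(spec$creatinine_lognormal),
    noise_sd = spec$noise_sd,
    detection_floor = spec$detection_floor,
    seed = spec$seed)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_spec(
    n_per_class = unlist(doc$n_per_class),
    panel = doc$panel,
    informative_features = lapply(doc$informative_features, function(e) {
      list(classes = e$classes, effects = unlist(e$effects))
    }),
    class_params = lapply(doc$class_params, function(p) {
      p$t2d <- as.numeric(p$t2d)
      p
    }),
    baseline_log10 = unlist(doc$baseline_log10),
    creatinine_lognormal = unlist(doc$creatinine_lognormal),
    noise_sd = doc$noise_sd,
    detection_floor = doc$detection_floor,
    seed = doc$seed)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  if ("t2d" %in% names(df)) df$t2d <- as.logical(df$t2d)
  if ("nas_score" %in% names(df)) df$nas_score <- as.integer(df$nas_score)
  df
}
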