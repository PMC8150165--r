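#' Serum-based fibrosis comparator scores
#'
#' The five non-invasive serum/clinical scores used as comparators for
#' steroid-based staging.  All are deterministic pure functions of their
#' arguments and vectorised over subjects.
#'
#' * `apri(ast, ast_uln, platelets)` = (AST / ULN) / platelets x 100.
#' * `fib4(age, ast, alt, platelets)` = age x AST / (platelets x
#'   sqrt(ALT)) — the established Fibrosis-4 formula, with the square
#'   root of ALT in the denominator.
#' * `ast_alt_ratio(ast, alt)` = AST / ALT.
#' * `nfs(...)`: NAFLD fibrosis score, the published linear combination
#'   -1.675 + 0.037 age + 0.094 BMI + 1.13 [IFG/T2D] + 0.99 AST/ALT -
#'   0.013 platelets - 0.66 albumin.
#' * `bard(bmi, ratio, t2d)`: BMI > 28 scores 1, AST/ALT ratio > 0.8
#'   scores 2, T2D scores 1 (strict inequalities); sum in 0..4.
#'
#' @param ast_iu_l,alt_iu_l Serum AST / ALT, IU/L.
#' @param ast_uln_iu_l Upper limit of normal for AST, IU/L (default 40).
#' @param platelets_1e9_l Platelet count, 10^9/L.
#' @param age_years Age in years.
#' @param bmi_kg_m2 Body mass index, kg/m2.
#' @param ifg_or_t2d,t2d Logical: impaired fasting glycaemia or type 2
#'   diabetes.
#' @param albumin_g_dl Serum albumin, g/dL.
#' @param ratio AST/ALT ratio.
#' @return Numeric score per subject (`bard`: integer 0-4).
#' @name clinical_scores
#' @examples
#' apri(40, 40, 100)            # 1.0
#' fib4(60, 49, 49, 60)         # 7.0
#' nfs(50, 30, TRUE, 25, 25, 250, 4.0)  # -0.775
#' bard(30, 0.9, TRUE)          # 4
NULL

#' @rdname clinical_scores
#' @export
apri <- function(ast_iu_l, ast_uln_iu_l = 40, platelets_1e9_l) {
  if (any(ast_iu_l <= 0) || any(ast_uln_iu_l <= 0) ||
      any(platelets_1e9_l <= 0)) {
    stopf("apri requires positive AST, ULN and platelet count")
  }
  (ast_iu_l / ast_uln_iu_l) / platelets_1e9_l * 100
}

#' @rdname clinical_scores
#' @export
fib4 <- function(age_years, ast_iu_l, alt_iu_l, platelets_1e9_l) {
  if (any(age_years <= 0) || any(ast_iu_l <= 0) || any(alt_iu_l <= 0) ||
      any(platelets_1e9_l <= 0)) {
    stopf("fib4 requires positive age, AST, ALT and platelet count")
  }
  age_years * ast_iu_l / (platelets_1e9_l * sqrt(alt_iu_l))
}

#' @rdname clinical_scores
#' @export
ast_alt_ratio <- function(ast_iu_l, alt_iu_l) {
  if (any(alt_iu_l <= 0)) stopf("ast_alt_ratio requires ALT > 0")
  if (any(ast_iu_l < 0)) stopf("ast_alt_ratio requires AST >= 0")
  ast_iu_l / alt_iu_l
}

#' @rdname clinical_scores
#' @export
nfs <- function(age_years, bmi_kg_m2, ifg_or_t2d, ast_iu_l, alt_iu_l,
                platelets_1e9_l, albumin_g_dl) {
  ratio <- ast_alt_ratio(ast_iu_l, alt_iu_l)
  out_of_range <- age_years < 18 | age_years > 100 |
    bmi_kg_m2 < 10 | bmi_kg_m2 > 80 |
    platelets_1e9_l < 10 | platelets_1e9_l > 1500 |
    albumin_g_dl < 1 | albumin_g_dl > 6
  if (any(out_of_range)) {
    warnf("%d subject(s) outside physiological ranges for NFS",
          sum(out_of_range))
  }
  -1.675 + 0.037 * age_years + 0.094 * bmi_kg_m2 +
    1.13 * as.numeric(ifg_or_t2d) + 0.99 * ratio -
    0.013 * platelets_1e9_l - 0.66 * albumin_g_dl
}

#' @rdname clinical_scores
#' @export
bard <- function(bmi_kg_m2, ratio, t2d) {
  stopifnot(all(is.finite(bmi_kg_m2)), all(is.finite(ratio)))
  as.integer((bmi_kg_m2 > 28) + 2L * (ratio > 0.8) + as.numeric(t2d))
}

#' Batch clinical scores for a cohort
#'
#' Computes all five comparator scores per subject.  Subjects with
#' missing or non-positive chemistry are reported in the `excluded`
#' attribute (with the offending field) and carry `NA` scores — they are
#' never silently dropped.
#'
#' @param records Cohort data frame with columns `subject_id`,
#'   `age_years`, `bmi_kg_m2`, `t2d`, `ast_iu_l`, `alt_iu_l`,
#'   `platelets_1e9_l`, `albumin_g_dl`.
#' @param ast_uln_iu_l AST upper limit of normal used by APRI.
#' @return Data frame (`subject_id`, `apri`, `fib4`, `ast_alt_ratio`,
#'   `nfs`, `bard`) with attribute `excluded`: a data frame of
#'   subject_id / reason for subjects that could not be scored.
#' @export
score_cohort <- function(records, ast_uln_iu_l = 40) {
  need <- c("subject_id", "age_years", "bmi_kg_m2", "t2d", "ast_iu_l",
            "alt_iu_l", "platelets_1e9_l", "albumin_g_dl")
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("records lack column(s): %s",
                          paste(miss, collapse = ", "))
  ok <- rep(TRUE, nrow(records))
  reason <- rep(NA_character_, nrow(records))
  for (fld in c("age_years", "ast_iu_l", "alt_iu_l", "platelets_1e9_l")) {
    bad <- is.na(records[[fld]]) | records[[fld]] <= 0
    reason[bad & ok] <- sprintf("invalid %s", fld)
    ok <- ok & !bad
  }
  for (fld in c("bmi_kg_m2", "albumin_g_dl", "t2d")) {
    bad <- is.na(records[[fld]])
    reason[bad & ok] <- sprintf("missing %s", fld)
    ok <- ok & !bad
  }
  out <- data.frame(subject_id = records$subject_id,
                    apri = NA_real_, fib4 = NA_real_,
                    ast_alt_ratio = NA_real_, nfs = NA_real_,
                    bard = NA_integer_, stringsAsFactors = FALSE)
  if (any(ok)) {
    r <- records[ok, ]
    ratio <- ast_alt_ratio(r$ast_iu_l, r$alt_iu_l)
    out$apri[ok] <- apri(r$ast_iu_l, ast_uln_iu_l, r$platelets_1e9_l)
    out$fib4[ok] <- fib4(r$age_years, r$ast_iu_l, r$alt_iu_l,
                         r$platelets_1e9_l)
    out$ast_alt_ratio[ok] <- ratio
    out$nfs[ok] <- suppressWarnings(
      nfs(r$age_years, r$bmi_kg_m2, r$t2d, r$ast_iu_l, r$alt_iu_l,
          r$platelets_1e9_l, r$albumin_g_dl))
    out$bard[ok] <- bard(r$bmi_kg_m2, ratio, r$t2d)
  }
  attr(out, "excluded") <- data.frame(
    subject_id = records$subject_id[!ok],
    reason = reason[!ok], stringsAsFactors = FALSE)
  out
}
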