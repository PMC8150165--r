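#' Binary contrast between class-label groups
#'
#' @param negative,positive Disjoint, non-empty character vectors of
#'   class labels forming the two arms.
#' @return A list of class `contrast` with a `tag` used in reports.
#' @export
#' @examples
#' contrast(c("F0", "F1", "F2"), c("F3", "F4"))
contrast <- function(negative, positive) {
  if (!length(negative) || !length(positive)) {
    stopf("both contrast arms must be non-empty")
  }
  if (length(intersect(negative, positive))) {
    stopf("contrast arms overlap: %s",
          paste(intersect(negative, positive), collapse = ", "))
  }
  structure(list(negative = negative, positive = positive,
                 tag = paste(paste(negative, collapse = ","),
                             paste(positive, collapse = ","),
                             sep = ":")),
            class = "contrast")
}

#' @rdname contrast
#' @param spec String `"NEG:POS"` with comma-separated labels per arm,
#'   e.g. `"F0,F1,F2:F3,F4"`.
#' @export
parse_contrast <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stopf("contrast must be 'NEG:POS'")
  arms <- lapply(parts, function(p) {
    trimws(strsplit(p, ",", fixed = TRUE)[[1]])
  })
  contrast(arms[[1]], arms[[2]])
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values (ties
#' cross simultaneously, which is equivalent to half-credit for tied
#' positive/negative pairs) and integrates the curve by the trapezoidal
#' rule; the AUC therefore equals the Mann-Whitney concordance
#' probability.
#'
#' @param scores Numeric scores, larger = more positive-like.
#' @param labels Logical (or 0/1) vector: `TRUE` for the positive class.
#' @return List with `curve` (data frame `fpr`, `tpr`, `threshold`,
#'   from (0,0) to (1,1)) and `auc`.
#' @export
#' @examples
#' roc_auc(c(1, 2, 3, 2, 3, 4),
#'         c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))$auc  # 7/9
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stopf("both classes must be present to compute a ROC curve")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & !labels), numeric(1))
  curve <- data.frame(fpr = c(0, fp / n_neg),
                      tpr = c(0, tp / n_pos),
                      threshold = c(Inf, thr))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  list(curve = curve, auc = auc)
}

# Vertical averaging of per-split ROC curves on a fixed FPR grid.
pool_roc <- function(curves, grid = seq(0, 1, length.out = 101)) {
  tprs <- vapply(curves, function(cv) {
    approx(cv$fpr, cv$tpr, xout = grid, method = "linear",
           ties = max, rule = 2)$y
  }, numeric(length(grid)))
  data.frame(fpr = grid, tpr = rowMeans(as.matrix(tprs)))
}

# Stratified test-index draw: round(frac * n) per arm, at least 1.
draw_split <- function(is_pos, test_fraction) {
  idx_pos <- which(is_pos)
  idx_neg <- which(!is_pos)
  n_take <- function(k) max(1L, round(test_fraction * k))
  test <- c(sample(idx_pos, n_take(length(idx_pos))),
            sample(idx_neg, n_take(length(idx_neg))))
  sort(test)
}

#' Repeated stratified-split validation of the steroid classifier
#'
#' The full pipeline, repeated over `n_splits` random stratified
#' train/test partitions: detection floors, log10 transform and
#' z-scoring are fitted on the training subjects only and applied to the
#' held-out subjects; a binary GMLVQ model is initialised and trained on
#' the training split; held-out subjects are scored by the signed
#' relative-distance statistic, and the per-split test AUC is recorded.
#' The pooled ROC is the vertical average of per-split curves on a
#' 101-point FPR grid, the 95% CI is the 2.5/97.5 percentile of the
#' per-split AUCs, and feature relevances are averaged over splits.
#' Everything is deterministic given `seed`, and the split membership is
#' drawn from labels alone before any value is inspected.
#'
#' @param records Cohort data frame (see [generate_cohort()]).
#' @param contrast A [contrast()] (or `"NEG:POS"` string).
#' @param n_splits Number of repeated splits.
#' @param test_fraction Fraction of each arm held out per split.
#' @param seed Master seed for splits and model initialisation.
#' @param covariates Covariates appended to the steroid features
#'   (`NULL`, or subset of `c("age", "bmi", "sex")`) — the augmented
#'   model.
#' @param panel Metabolite subset to use (default: full panel present).
#' @param uncorrected Use per-litre concentrations instead of
#'   creatinine-corrected ones.
#' @param train_config A [gmlvq_train_config()] (its seed is reassigned
#'   per split).
#' @param scorer Optional override for testing: a
#'   `function(train_fm, test_fm, positive_label)` returning scores for
#'   the test rows (bypasses GMLVQ).
#' @return An object of class `validation_report`: `per_split_auc`,
#'   `auc_mean`, `ci95`, `pooled_roc`, `relevance_mean`,
#'   `training_logs`, `test_indices`, plus the settings.
#' @export
repeated_split_validation <- function(records, contrast,
                                      n_splits = 100,
                                      test_fraction = 0.1,
                                      seed = 1L,
                                      covariates = NULL,
                                      panel = NULL,
                                      uncorrected = FALSE,
                                      train_config = gmlvq_train_config(),
                                      scorer = NULL) {
  if (is.character(contrast)) contrast <- parse_contrast(contrast)
  stopifnot(inherits(contrast, "contrast"))
  keep <- records$stage %in% c(contrast$negative, contrast$positive)
  records <- records[keep, , drop = FALSE]
  is_pos <- records$stage %in% contrast$positive
  if (sum(is_pos) < 2 || sum(!is_pos) < 2) {
    stopf("each contrast arm needs at least 2 subjects")
  }
  # Split membership and per-split model seeds are fixed up front, as a
  # function of labels and seed only (leakage-free by construction).
  plan <- with_seed(seed, {
    splits <- vector("list", n_splits)
    for (s in seq_len(n_splits)) {
      for (try in 1:10) {
        test <- draw_split(is_pos, test_fraction)
        if (length(unique(is_pos[test])) == 2 &&
            length(unique(is_pos[-test])) == 2) break
        if (try == 10) stopf("could not draw a two-class split")
      }
      splits[[s]] <- test
    }
    list(splits = splits,
         model_seeds = sample.int(.Machine$integer.max - 1, n_splits))
  })
  steroid <- cohort_steroid_matrix(records, panel = panel,
                                   uncorrected = uncorrected)
  label <- ifelse(is_pos, "positive", "negative")
  per_auc <- numeric(n_splits)
  curves <- vector("list", n_splits)
  relevances <- NULL
  logs <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    test <- plan$splits[[s]]
    tr_raw <- steroid[-test, , drop = FALSE]
    te_raw <- steroid[test, , drop = FALSE]
    floors <- log10_floors(tr_raw)
    tr_fm <- feature_matrix(log10_transform(tr_raw, floor = floors),
                            label[-test])
    te_fm <- feature_matrix(log10_transform(te_raw, floor = floors),
                            label[test])
    if (!is.null(covariates)) {
      tr_fm <- augment_covariates(tr_fm, records[-test, , drop = FALSE],
                                  covariates)
      te_fm <- augment_covariates(te_fm, records[test, , drop = FALSE],
                                  covariates)
    }
    z <- zscore_fit_apply(tr_fm, test = te_fm)
    if (!is.null(scorer)) {
      scores <- scorer(z$train, z$test, "positive")
      logs[[s]] <- numeric(0)
    } else {
      cfg <- train_config
      cfg$seed <- plan$model_seeds[s]
      model <- gmlvq_init(z$train, seed = plan$model_seeds[s])
      model <- gmlvq_train(model, z$train, cfg)
      scores <- gmlvq_score(model, z$test, "positive")
      logs[[s]] <- model$training_log
      rel <- gmlvq_relevances(model)
      relevances <- if (is.null(relevances)) rel else relevances + rel
    }
    roc <- roc_auc(scores, label[test] == "positive")
    per_auc[s] <- roc$auc
    curves[[s]] <- roc$curve
  }
  structure(list(contrast = contrast,
                 n_splits = n_splits,
                 test_fraction = test_fraction,
                 seed = seed,
                 covariates = covariates,
                 per_split_auc = per_auc,
                 auc_mean = mean(per_auc),
                 ci95 = stats::setNames(
                   quantile(per_auc, c(0.025, 0.975), names = FALSE,
                            type = 7),
                   c("lo", "hi")),
                 pooled_roc = pool_roc(curves),
                 relevance_mean = if (!is.null(relevances)) {
                   relevances / n_splits
                 },
                 training_logs = logs,
                 test_indices = plan$splits),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "Validation report [%s]: mean AUC %.3f (95%% CI %.3f-%.3f), %d splits\n",
    x$contrast$tag, x$auc_mean, x$ci95[["lo"]], x$ci95[["hi"]],
    x$n_splits))
  if (!is.null(x$relevance_mean)) {
    top <- sort(x$relevance_mean, decreasing = TRUE)
    cat("  top relevances: ",
        paste(sprintf("%s=%.3f", names(head(top, 5)), head(top, 5)),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' ROC of a serum comparator score against a contrast
#'
#' Computes the named clinical score per subject (no training, no
#' splits) and its ROC against the contrast labels.
#'
#' @param records Cohort data frame.
#' @param contrast A [contrast()] or `"NEG:POS"` string.
#' @param score_name One of `"apri"`, `"fib4"`, `"ast_alt_ratio"`,
#'   `"nfs"`, `"bard"`.
#' @param ast_uln_iu_l AST upper limit of normal (APRI only).
#' @return As [roc_auc()], plus the per-subject `scores`.
#' @export
comparator_roc <- function(records, contrast, score_name,
                           ast_uln_iu_l = 40) {
  if (is.character(contrast)) contrast <- parse_contrast(contrast)
  score_name <- match.arg(score_name,
                          c("apri", "fib4", "ast_alt_ratio", "nfs",
                            "bard"))
  keep <- records$stage %in% c(contrast$negative, contrast$positive)
  records <- records[keep, , drop = FALSE]
  panel <- score_cohort(records, ast_uln_iu_l = ast_uln_iu_l)
  scores <- panel[[score_name]]
  if (anyNA(scores)) {
    stopf("comparator '%s' undefined for subject(s): %s", score_name,
          paste(panel$subject_id[is.na(scores)], collapse = ", "))
  }
  out <- roc_auc(scores, records$stage %in% contrast$positive)
  out$scores <- scores
  out
}

#' Kruskal-Wallis omnibus test with Dunn's pairwise post hoc
#'
#' Nonparametric comparison of a metabolite (or ratio) across >= 2
#' groups: the tie-corrected Kruskal-Wallis H statistic (via
#' [stats::kruskal.test()]) followed by Dunn's z-tests on pairwise mean
#' rank differences, Bonferroni-corrected over the number of pairs.
#'
#' @param values Numeric vector of pooled observations.
#' @param groups Group membership, same length as `values`.
#' @param alpha Significance threshold applied to adjusted p-values.
#' @return List: `H`, `df`, `p_value`, and `pairwise` data frame
#'   (`group1`, `group2`, `z`, `p_unadjusted`, `p_adjusted`,
#'   `significant`).
#' @export
#' @examples
#' group_compare(1:9, rep(c("a", "b", "c"), each = 3))$H  # 7.2
group_compare <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2) stopf("need at least 2 groups")
  if (any(tab < 2)) stopf("every group needs n >= 2 (empty or singleton: %s)",
                          paste(names(tab)[tab < 2], collapse = ", "))
  kw <- kruskal.test(values, factor(groups))
  r <- rank(values)
  n <- length(values)
  # tie correction term for the Dunn variance
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (n - 1))
  mean_rank <- tapply(r, groups, mean)
  gn <- names(tab)
  pairs <- utils::combn(gn, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / tab[[p[1]]] + 1 / tab[[p[2]]]))
    (mean_rank[[p[1]]] - mean_rank[[p[2]]]) / se
  })
  p_un <- 2 * pnorm(-abs(z))
  p_adj <- pmin(1, p_un * ncol(pairs))
  list(H = unname(kw$statistic),
       df = unname(kw$parameter),
       p_value = kw$p.value,
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             z = z, p_unadjusted = p_un,
                             p_adjusted = p_adj,
                             significant = p_adj < alpha,
                             stringsAsFactors = FALSE))
}

#' Serialise a validation report
#'
#' `report_to_json` writes the full report (settings, per-split AUCs,
#' CI, pooled ROC, mean relevances) as JSON; `write_roc_csv` exports a
#' ROC curve as a flat CSV (`fpr`, `tpr`, and `threshold` when present).
#'
#' @param report A `validation_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  doc <- list(contrast = list(negative = report$contrast$negative,
                              positive = report$contrast$positive),
              n_splits = report$n_splits,
              test_fraction = report$test_fraction,
              seed = report$seed,
              covariates = report$covariates,
              per_split_auc = report$per_split_auc,
              auc_mean = report$auc_mean,
              ci95 = as.list(report$ci95),
              relevance_mean = as.list(report$relevance_mean),
              pooled_roc = report$pooled_roc)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname report_to_json
#' @param curve Data frame with `fpr`, `tpr` (e.g. `pooled_roc`, or the
#'   `curve` from [roc_auc()]).
#' @export
write_roc_csv <- function(curve, path) {
  write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
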