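test_that("ROC handles separation, ties and the worked example", {
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13),
                       c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))$auc, 1)
  # worked example with ties: class0 = {1,2,3}, class1 = {2,3,4} -> 7/9
  r <- roc_auc(c(1, 2, 3, 2, 3, 4), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 7 / 9)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("trapezoidal AUC equals pairwise concordance on random score sets", {
  withr::with_seed(99, {
    for (i in 1:40) {
      n <- sample(6:25, 1)
      # integer scores force plenty of ties
      scores <- sample(1:6, n, replace = TRUE)
      labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
      expect_lt(abs(roc_auc(scores, labels)$auc -
                    concordance_auc(scores, labels)), 1e-12)
    }
  })
})

test_that("AUC is antisymmetric under score negation", {
  withr::with_seed(15, {
    scores <- rnorm(30)
    labels <- rep(c(TRUE, FALSE), 15)
    expect_equal(roc_auc(scores, labels)$auc +
                 roc_auc(-scores, labels)$auc, 1)
  })
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(27, {
    scores <- round(rnorm(40), 1)
    labels <- rep(c(TRUE, FALSE), 20)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels)$auc, ref)
  })
})

test_that("contrast parsing validates arms", {
  ct <- parse_contrast("F0,F1,F2:F3,F4")
  expect_equal(ct$negative, c("F0", "F1", "F2"))
  expect_equal(ct$positive, c("F3", "F4"))
  expect_error(contrast(character(0), "F4"), "non-empty")
  expect_error(contrast(c("F0", "F4"), "F4"), "overlap")
})

test_that("repeated-split validation is deterministic and leakage-free", {
  cohort <- generate_cohort(separable_spec(5, effect = 2, n = 40))
  ct <- contrast("F0", "F4")
  a <- repeated_split_validation(cohort, ct, n_splits = 4,
                                 test_fraction = 0.2, seed = 77,
                                 train_config = gmlvq_train_config(epochs = 15))
  b <- repeated_split_validation(cohort, ct, n_splits = 4,
                                 test_fraction = 0.2, seed = 77,
                                 train_config = gmlvq_train_config(epochs = 15))
  expect_identical(a[names(a) != "training_logs"],
                   b[names(b) != "training_logs"])
  expect_length(a$per_split_auc, 4)
  expect_true(all(a$per_split_auc >= 0 & a$per_split_auc <= 1))
  expect_lte(a$ci95[["lo"]], a$auc_mean)
  expect_gte(a$ci95[["hi"]], a$auc_mean)
  # poisoning the test subjects of a split leaves its training untouched
  for (s in c(1, 3)) {
    poisoned <- cohort
    test_rows <- a$test_indices[[s]]
    poisoned[test_rows, default_panel()] <-
      poisoned[test_rows, default_panel()] * 1000 + 5
    p <- repeated_split_validation(poisoned, ct, n_splits = 4,
                                   test_fraction = 0.2, seed = 77,
                                   train_config = gmlvq_train_config(epochs = 15))
    expect_identical(p$training_logs[[s]], a$training_logs[[s]])
  }
})

test_that("an oracle scorer yields perfect per-split AUCs", {
  cohort <- generate_cohort(
    cohort_spec(n_per_class = c(F0 = 20, F4 = 20),
                informative_features = list(), seed = 8))
  rep1 <- repeated_split_validation(
    cohort, contrast("F0", "F4"), n_splits = 5, test_fraction = 0.25,
    seed = 3,
    scorer = function(train, test, positive) {
      as.numeric(test$labels == positive)
    })
  expect_equal(rep1$per_split_auc, rep(1, 5))
})

test_that("destroying the labels drives the AUC to chance", {
  cohort <- generate_cohort(separable_spec(21, effect = 4, n = 50))
  shuffled <- cohort
  shuffled$stage <- withr::with_seed(1, sample(shuffled$stage))
  rep1 <- repeated_split_validation(shuffled, contrast("F0", "F4"),
                                    n_splits = 20, test_fraction = 0.2,
                                    seed = 5,
                                    train_config = gmlvq_train_config(epochs = 20))
  expect_gte(rep1$auc_mean, 0.4)
  expect_lte(rep1$auc_mean, 0.6)
})

test_that("comparator ROC reflects the built-in FIB-4 gradient and antisymmetry", {
  cohort <- generate_cohort(cohort_spec(seed = 14))
  ct <- parse_contrast("F0,F1,F2:F3,F4")
  fib <- comparator_roc(cohort, ct, "fib4")
  expect_gt(fib$auc, 0.5)
  neg <- roc_auc(-fib$scores, cohort$stage[cohort$stage %in%
                   c(ct$negative, ct$positive)] %in% ct$positive)
  expect_equal(neg$auc, 1 - fib$auc)
})

test_that("Kruskal-Wallis H matches the hand-rank oracle with Dunn flags", {
  # three identical groups: H ~ 0, nothing significant
  same <- group_compare(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_lt(same$H, 1e-10)
  expect_false(any(same$pairwise$significant))
  # ranks 1..9 split into consecutive triples: H = 7.2 exactly
  g <- group_compare(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(g$H, 7.2)
  expect_equal(g$df, 2)
  expect_equal(nrow(g$pairwise), 3)
  # H is invariant under strictly monotone transforms
  g2 <- group_compare(exp(1:9), rep(c("a", "b", "c"), each = 3))
  expect_equal(g2$H, g$H)
  expect_error(group_compare(1:5, c("a", "a", "b", "b", "c")),
               "n >= 2")
})

test_that("Dunn z-statistics follow the rank-sum formula under ties", {
  # hand-computed example with a tie: values {1,2,2,4,5,6}, groups aabbcc
  v <- c(1, 2, 2, 4, 5, 6)
  g <- rep(c("a", "b", "c"), each = 2)
  res <- group_compare(v, g)
  r <- rank(v)                  # 1, 2.5, 2.5, 4, 5, 6
  n <- 6
  tie_term <- (2^3 - 2) / (12 * (n - 1))
  se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / 2 + 1 / 2))
  z_ab <- (mean(r[1:2]) - mean(r[3:4])) / se
  expect_equal(res$pairwise$z[res$pairwise$group1 == "a" &
                              res$pairwise$group2 == "b"], z_ab)
  # Bonferroni over the three pairs
  expect_equal(res$pairwise$p_adjusted,
               pmin(1, res$pairwise$p_unadjusted * 3))
})

test_that("reports serialise to JSON and ROC curves to CSV", {
  cohort <- generate_cohort(separable_spec(2, effect = 3, n = 30))
  rep1 <- repeated_split_validation(cohort, "F0:F4", n_splits = 3,
                                    test_fraction = 0.2, seed = 2,
                                    train_config = gmlvq_train_config(epochs = 10))
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  report_to_json(rep1, jp)
  doc <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(doc$auc_mean, rep1$auc_mean)
  expect_equal(length(doc$per_split_auc), 3)
  write_roc_csv(rep1$pooled_roc, cp)
  curve <- utils::read.csv(cp)
  expect_equal(nrow(curve), 101)
  expect_true(all(diff(curve$tpr) >= -1e-12))
})
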