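make_blobs <- function(seed, n = 50, d = 5, shift = c(4, 4, 0, 0, 0),
                       sep_gap = NULL) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(n * d), n, d)
    B <- matrix(rnorm(n * d), n, d) + rep(shift, each = n)
    if (!is.null(sep_gap)) {
      # enforce genuine linear separability on feature 1
      A[, 1] <- pmin(A[, 1], sep_gap[1])
      B[, 1] <- pmax(B[, 1], sep_gap[2])
    }
    X <- rbind(A, B)
    colnames(X) <- paste0("f", seq_len(d))
    feature_matrix(X, rep(c("a", "b"), each = n))
  })
}

test_that("initialisation places prototypes at class means with unit-trace metric", {
  withr::with_seed(2, {
    X <- rbind(matrix(rnorm(40, -1, 0.1), 20),
               matrix(rnorm(40, 1, 0.1), 20))
    colnames(X) <- c("f1", "f2")
    fm <- feature_matrix(X, rep(c("a", "b"), each = 20))
  })
  m <- gmlvq_init(fm, seed = 5)
  means <- rbind(colMeans(fm$values[1:20, ]), colMeans(fm$values[21:40, ]))
  expect_lt(max(abs(m$prototypes - means)), 0.05)
  d <- ncol(fm$values)
  expect_equal(m$omega, diag(d) / sqrt(d))
  expect_equal(sum(diag(crossprod(m$omega))), 1)
  # Lambda = I/d  =>  relevances all 1/d
  expect_equal(unname(gmlvq_relevances(m)), rep(1 / d, d))
  # determinism
  expect_identical(m, gmlvq_init(fm, seed = 5))
  expect_error(gmlvq_init(feature_matrix(X, c("a", rep("b", 39)))),
               "< 2 samples")
})

test_that("distances match the closed form and the naive oracle", {
  inst <- random_instance(101, n = 8, d = 4)
  m <- inst$model
  # x = w gives 0
  expect_equal(unname(gmlvq_distances(m, m$prototypes[1, ])[1]), 0)
  # Omega = I/sqrt(d), x - w = 1 vector: distance (1/d) * d = 1
  m2 <- m
  m2$omega <- diag(4) / 2
  x <- m2$prototypes[2, ] + 1
  expect_equal(unname(gmlvq_distances(m2, x)[2]), 1)
  # oracle equivalence on random parameters
  for (i in seq_len(nrow(inst$fm$values))) {
    got <- gmlvq_distances(m, inst$fm$values[i, ])
    for (p in seq_len(nrow(m$prototypes))) {
      expect_equal(unname(got[p]),
                   naive_distance(m$omega, m$prototypes[p, ],
                                  inst$fm$values[i, ]))
    }
  }
  expect_error(gmlvq_distances(m, c(1, 2)), "dimension mismatch")
})

test_that("cost terms behave at the limit cases and match the oracle", {
  inst <- random_instance(7, n = 6, d = 3)
  m <- inst$model
  # sample exactly at its own prototype, other prototype distinct: mu = -1
  own <- m$prototype_class[1]
  fm1 <- feature_matrix(m$prototypes[1, , drop = FALSE], own)
  expect_equal(gmlvq_cost(m, fm1), -1)
  # equidistant sample: mu = 0 (construct via symmetric prototypes)
  msym <- m
  msym$prototypes <- rbind(c(-1, 0, 0), c(1, 0, 0))
  colnames(msym$prototypes) <- m$feature_names
  msym$omega <- diag(3) / sqrt(3)
  mid <- feature_matrix(matrix(c(0, 0.5, -2), 1,
                               dimnames = list(NULL, m$feature_names)),
                        msym$prototype_class[1])
  expect_equal(gmlvq_cost(msym, mid), 0)
  # random instance equals brute-force enumeration
  expect_equal(gmlvq_cost(m, inst$fm),
               naive_cost(m, inst$fm$values, inst$fm$labels))
  # identity phi keeps per-sample terms in [-1, 1]
  n <- nrow(inst$fm$values)
  expect_lte(abs(gmlvq_cost(m, inst$fm)), n)
})

test_that("analytic gradients match central finite differences", {
  for (seed in c(3, 17)) {
    inst <- random_instance(seed, n = 5, d = 3)
    got <- steroidstage:::gmlvq_gradients(inst$model, inst$fm)
    want <- fd_gradients(inst$model, inst$fm)
    scale <- max(abs(unlist(want)), 1e-8)
    expect_lt(max(abs(got$prototypes - want$prototypes)) / scale, 1e-4)
    expect_lt(max(abs(got$omega - want$omega)) / scale, 1e-4)
  }
})

test_that("training separates separable blobs and logs a non-increasing cost", {
  fm <- make_blobs(1, n = 50, d = 5, sep_gap = c(1.5, 2.5))
  z <- zscore_fit_apply(fm)$train
  m <- gmlvq_train(gmlvq_init(z, seed = 1), z,
                   gmlvq_train_config(epochs = 100))
  expect_equal(mean(predict(m, z) == z$labels), 1.0)
  expect_true(all(diff(m$training_log) <= 0))
  expect_lt(abs(sum(m$omega^2) - 1), 1e-10)
})

test_that("training is deterministic and a zero step leaves the model unchanged", {
  fm <- make_blobs(3, n = 20, d = 4, shift = c(2, 0, 0, 0))
  z <- zscore_fit_apply(fm)$train
  m0 <- gmlvq_init(z, seed = 9)
  cfg <- gmlvq_train_config(epochs = 10)
  expect_identical(gmlvq_train(m0, z, cfg), gmlvq_train(m0, z, cfg))
  tiny <- gmlvq_train_config(epochs = 5, lr_prototype = 1e-300,
                             lr_omega = 1e-300)
  m1 <- gmlvq_train(m0, z, tiny)
  expect_equal(m1$prototypes, m0$prototypes)
  expect_equal(m1$omega, m0$omega)
})

test_that("stochastic mode trains, renormalises and is seed-deterministic", {
  fm <- make_blobs(11, n = 30, d = 4, shift = c(3, 3, 0, 0))
  z <- zscore_fit_apply(fm)$train
  cfg <- gmlvq_train_config(epochs = 10, mode = "stochastic",
                            lr_prototype = 0.05, seed = 2)
  m <- gmlvq_train(gmlvq_init(z, seed = 2), z, cfg)
  expect_lt(abs(sum(m$omega^2) - 1), 1e-10)
  expect_gt(mean(predict(m, z) == z$labels), 0.9)
  expect_identical(m, gmlvq_train(gmlvq_init(z, seed = 2), z, cfg))
})

test_that("prediction matches exhaustive nearest-prototype search and breaks ties low", {
  inst <- random_instance(23, n = 20, d = 5)
  m <- inst$model
  got <- predict(m, inst$fm)
  expect_equal(as.character(got), naive_predict(m, inst$fm$values))
  # a prototype classifies as its own class
  expect_equal(as.character(predict(m, m$prototypes[1, ])),
               m$prototype_class[1])
  # symmetric tie goes to the first class in sort order, flagged
  msym <- m
  msym$prototypes <- rbind(c(-1, 0, 0, 0, 0), c(1, 0, 0, 0, 0))
  colnames(msym$prototypes) <- m$feature_names
  msym$omega <- diag(5) / sqrt(5)
  p <- predict(msym, rep(0, 5))
  expect_equal(as.character(p), sort(m$classes)[1])
  expect_true(attr(p, "tie"))
})

test_that("decision scores are antisymmetric, bounded and consistent with predict", {
  inst <- random_instance(37, n = 20, d = 4)
  m <- inst$model
  X <- inst$fm$values
  sA <- gmlvq_score(m, X, m$classes[1])
  sB <- gmlvq_score(m, X, m$classes[2])
  expect_equal(sA, -sB)
  expect_true(all(abs(sA) <= 1))
  expect_equal(unname(gmlvq_score(m, m$prototypes[1, ],
                                  m$prototype_class[1])), 1)
  pred <- ifelse(sA > 0, m$classes[1], m$classes[2])
  agree <- sA != 0
  expect_equal(pred[agree], as.character(predict(m, X))[agree])
  # non-binary models are refused
  fm3 <- feature_matrix(matrix(rnorm(24), 12, 2,
                               dimnames = list(NULL, c("f1", "f2"))),
                        rep(c("a", "b", "c"), 4))
  m3 <- gmlvq_init(fm3, seed = 1)
  expect_error(gmlvq_score(m3, fm3$values[1, ], "a"), "binary")
})

test_that("relevances sum to one and recover a single informative feature", {
  hits <- 0
  for (seed in 1:20) {
    fm <- withr::with_seed(seed, {
      X <- matrix(rnorm(60 * 8), 60, 8)
      X[31:60, 3] <- X[31:60, 3] + 3
      colnames(X) <- paste0("f", 1:8)
      feature_matrix(X, rep(c("a", "b"), each = 30))
    })
    z <- zscore_fit_apply(fm)$train
    m <- gmlvq_train(gmlvq_init(z, seed = seed), z,
                     gmlvq_train_config(epochs = 40))
    rel <- gmlvq_relevances(m)
    expect_lt(abs(sum(rel) - 1), 1e-10)
    if (names(which.max(rel)) == "f3") hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("predictions are invariant under a joint orthogonal rotation", {
  inst <- random_instance(51, n = 20, d = 4)
  m <- inst$model
  R <- withr::with_seed(4, qr.Q(qr(matrix(rnorm(16), 4, 4))))
  mrot <- m
  mrot$prototypes <- m$prototypes %*% t(R)
  colnames(mrot$prototypes) <- m$feature_names
  mrot$omega <- m$omega %*% t(R)
  Xrot <- inst$fm$values %*% t(R)
  expect_equal(as.character(predict(m, inst$fm$values)),
               as.character(predict(mrot, Xrot)))
  expect_equal(gmlvq_score(m, inst$fm$values, m$classes[2]),
               gmlvq_score(mrot, Xrot, m$classes[2]))
})

test_that("2D projection respects the metric and degenerate ranks", {
  inst <- random_instance(61, n = 15, d = 5)
  m <- inst$model
  X <- inst$fm$values
  coords <- gmlvq_project(m, X)
  expect_equal(dim(coords), c(15, 2))
  # projected squared distances never exceed the full metric distance
  full <- as.matrix(stats::dist(X %*% t(m$omega)))^2
  proj <- as.matrix(stats::dist(coords))^2
  expect_true(all(proj <= full + 1e-10))
  # rank-1 metric: second coordinate is zero with a warning
  m1 <- m
  v <- matrix(0, 5, 5)
  v[1, ] <- rnorm(5)
  m1$omega <- v / sqrt(sum(v^2))
  expect_warning(c1 <- gmlvq_project(m1, X), "rank")
  expect_equal(unname(c1[, 2]), rep(0, 15))
  # rank <= 2: projection preserves metric distances exactly
  m2 <- m
  v2 <- matrix(0, 5, 5)
  v2[1:2, ] <- rnorm(10)
  m2$omega <- v2 / sqrt(sum(v2^2))
  c2 <- gmlvq_project(m2, X)
  expect_equal(as.matrix(stats::dist(c2))^2,
               as.matrix(stats::dist(X %*% t(m2$omega)))^2,
               tolerance = 1e-10)
})

test_that("JSON round trip reproduces the model and its predictions exactly", {
  fm <- make_blobs(71, n = 25, d = 4, shift = c(2, 1, 0, 0))
  z <- zscore_fit_apply(fm)$train
  m <- gmlvq_train(gmlvq_init(z, seed = 3), z,
                   gmlvq_train_config(epochs = 20))
  path <- withr::local_tempfile(fileext = ".json")
  gmlvq_write_json(m, path)
  back <- gmlvq_read_json(path)
  expect_identical(back$prototypes, m$prototypes)
  expect_identical(back$omega, m$omega)
  expect_identical(as.character(predict(back, z)),
                   as.character(predict(m, z)))
  expect_identical(gmlvq_score(back, z$values, "b"),
                   gmlvq_score(m, z$values, "b"))
})
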