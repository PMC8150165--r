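#' Generalised Matrix Learning Vector Quantisation (GMLVQ)
#'
#' Prototype-based classifier with a globally adaptive quadratic metric.
#' Each class is represented by one (or more) prototype vector(s) w; the
#' dissimilarity of a profile x and a prototype is
#' `d(w, x) = (x - w)' Lambda (x - w)` with the relevance matrix
#' `Lambda = Omega' Omega` learned jointly with the prototypes.  Lambda
#' is symmetric positive semi-definite by construction and is kept at
#' `trace(Lambda) = 1`, so its diagonal is a normalised measure of each
#' feature's importance to the classification.
#'
#' Training minimises the relative-distance cost `sum_i phi(mu_i)` with
#' `mu = (dJ - dK) / (dJ + dK)`, where `dJ` is the distance to the
#' closest prototype of the sample's own class and `dK` the distance to
#' the closest prototype of any other class; `mu < 0` iff the sample is
#' correctly classified, and with `phi` = identity each term lies in
#' \[-1, 1\].
#'
#' @param fm A z-scored [feature_matrix()] with >= 2 classes, each with
#'   >= 2 samples.
#' @param prototypes_per_class Number of prototypes per class (default 1:
#'   one typical steroid profile per disease stage).
#' @param seed Integer seed for the prototype jitter.
#' @param jitter_sd SD (z-units) of the seeded jitter added to the
#'   class-conditional means at initialisation.
#' @return An object of class `gmlvq_model`: `prototypes` (matrix, one
#'   row per prototype), `prototype_class`, `omega` (d x d), `classes`,
#'   `feature_names`, `trained`, `training_log`.
#' @seealso [gmlvq_train()], [gmlvq_relevances()], [gmlvq_score()]
#' @export
gmlvq_init <- function(fm, prototypes_per_class = 1, seed = 1L,
                       jitter_sd = 0.01) {
  stopifnot(inherits(fm, "feature_matrix"))
  classes <- sort(unique(fm$labels))
  if (length(classes) < 2) stopf("need at least 2 classes")
  counts <- table(fm$labels)
  small <- names(counts)[counts < 2]
  if (length(small)) stopf("class(es) with < 2 samples: %s",
                           paste(small, collapse = ", "))
  d <- ncol(fm$values)
  proto_class <- rep(classes, each = prototypes_per_class)
  W <- with_seed(seed, {
    t(vapply(proto_class, function(cl) {
      colMeans(fm$values[fm$labels == cl, , drop = FALSE]) +
        rnorm(d, 0, jitter_sd)
    }, numeric(d)))
  })
  dimnames(W) <- list(NULL, fm$feature_names)
  omega <- diag(d) / sqrt(d)  # trace(Omega' Omega) = 1
  structure(list(prototypes = W, prototype_class = proto_class,
                 omega = omega, classes = classes,
                 feature_names = fm$feature_names,
                 trained = FALSE, training_log = numeric(0)),
            class = "gmlvq_model")
}

#' @export
print.gmlvq_model <- function(x, ...) {
  cat(sprintf("GMLVQ model: %d prototypes (%s), %d features, %s\n",
              nrow(x$prototypes),
              paste(x$classes, collapse = " / "),
              ncol(x$prototypes),
              if (x$trained) {
                sprintf("trained (%d epochs, final cost %.4f)",
                        length(x$training_log),
                        x$training_log[length(x$training_log)])
              } else "untrained"))
  rel <- sort(gmlvq_relevances(x), decreasing = TRUE)
  cat("  top relevances: ",
      paste(sprintf("%s=%.3f", names(head(rel, 5)), head(rel, 5)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

check_dim <- function(model, X) {
  if (ncol(X) != ncol(model$prototypes)) {
    stopf("dimension mismatch: model has %d features, data has %d",
          ncol(model$prototypes), ncol(X))
  }
}

as_row_matrix <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  check_dim(model, X)
  X
}

#' Squared adaptive-metric distances to every prototype
#'
#' `d(w, x) = (x - w)' Omega' Omega (x - w) = ||Omega (x - w)||^2`.
#'
#' @param model A `gmlvq_model`.
#' @param x Numeric vector of length d, or an n x d matrix.
#' @return An n x (number of prototypes) matrix of non-negative squared
#'   distances (a vector drops to a named numeric vector).
#' @export
gmlvq_distances <- function(model, x) {
  X <- as_row_matrix(model, x)
  P <- X %*% t(model$omega)          # rows: Omega x
  Q <- model$prototypes %*% t(model$omega)
  D <- outer(rowSums(P^2), rep(1, nrow(Q))) +
    outer(rep(1, nrow(P)), rowSums(Q^2)) - 2 * P %*% t(Q)
  D[D < 0] <- 0  # numerical guard
  colnames(D) <- model$prototype_class
  if (!is.matrix(x)) D[1, ] else D
}

# Per-sample winner bookkeeping shared by cost / gradients / prediction.
# Returns, per sample: index and distance of the closest correct-class
# (J) and closest wrong-class (K) prototype, and mu.
winner_stats <- function(model, fm) {
  X <- fm$values
  check_dim(model, X)
  D <- gmlvq_distances(model, X)
  if (!is.matrix(D)) D <- matrix(D, nrow = 1)
  own <- outer(fm$labels, model$prototype_class, "==")
  missing_cls <- setdiff(unique(fm$labels), model$classes)
  if (length(missing_cls)) {
    stopf("no prototype for class(es): %s",
          paste(missing_cls, collapse = ", "))
  }
  pick <- function(mask) {
    Dm <- D
    Dm[!mask] <- Inf
    j <- max.col(-Dm, ties.method = "first")
    list(idx = j, dist = Dm[cbind(seq_len(nrow(D)), j)])
  }
  J <- pick(own)
  K <- pick(!own)
  denom <- J$dist + K$dist
  mu <- ifelse(denom > 0, (J$dist - K$dist) / denom, 0)
  if (any(denom == 0)) {
    warnf("%d sample(s) coincide with prototypes of both classes; mu=0",
          sum(denom == 0))
  }
  list(j = J$idx, k = K$idx, dj = J$dist, dk = K$dist, mu = mu,
       denom = denom)
}

phi_eval <- function(mu, phi = "identity", slope = 1) {
  switch(phi,
         identity = list(value = mu, deriv = rep(1, length(mu))),
         sigmoid = {
           s <- 1 / (1 + exp(-slope * mu))
           list(value = s, deriv = slope * s * (1 - s))
         },
         stopf("unknown phi '%s'", phi))
}

#' GMLVQ cost function
#'
#' Sum over samples of `phi(mu)` with
#' `mu = (dJ - dK) / (dJ + dK)`; see [gmlvq_init()] for notation.
#'
#' @param model A `gmlvq_model`.
#' @param fm A [feature_matrix()] whose classes all have prototypes.
#' @param phi Margin transfer function: `"identity"` (default) or
#'   `"sigmoid"`.
#' @param slope Sigmoid slope (ignored for identity).
#' @return Scalar cost; per-sample terms are in \[-1, 1\] for the
#'   identity transfer.
#' @export
gmlvq_cost <- function(model, fm, phi = "identity", slope = 1) {
  ws <- winner_stats(model, fm)
  sum(phi_eval(ws$mu, phi, slope)$value)
}

# Analytic gradients of the summed cost w.r.t. prototypes and Omega.
# d mu / d dJ = 2 dK / (dJ+dK)^2 ; d mu / d dK = -2 dJ / (dJ+dK)^2 ;
# d d(w,x) / d w = -2 Lambda (x - w) ;
# d d(w,x) / d Omega = 2 Omega (x-w)(x-w)'.
gmlvq_gradients <- function(model, fm, phi = "identity", slope = 1) {
  ws <- winner_stats(model, fm)
  X <- fm$values
  n <- nrow(X)
  dphi <- phi_eval(ws$mu, phi, slope)$deriv
  safe <- ifelse(ws$denom > 0, ws$denom^2, Inf)
  gJ <- dphi * 2 * ws$dk / safe
  gK <- dphi * (-2) * ws$dj / safe
  P <- nrow(model$prototypes)
  A <- matrix(0, n, P)
  A[cbind(seq_len(n), ws$j)] <- A[cbind(seq_len(n), ws$j)] + gJ
  A[cbind(seq_len(n), ws$k)] <- A[cbind(seq_len(n), ws$k)] + gK
  lambda <- crossprod(model$omega)
  grad_W <- -2 * (t(A) %*% X - diag(colSums(A), P) %*% model$prototypes) %*%
    lambda
  U <- X - model$prototypes[ws$j, , drop = FALSE]
  V <- X - model$prototypes[ws$k, , drop = FALSE]
  S <- crossprod(U * gJ, U) + crossprod(V * gK, V)
  grad_omega <- 2 * model$omega %*% S
  dimnames(grad_W) <- dimnames(model$prototypes)
  dimnames(grad_omega) <- NULL
  list(prototypes = grad_W, omega = grad_omega)
}

normalise_omega <- function(omega) omega / sqrt(sum(omega^2))

#' Training configuration for GMLVQ
#'
#' Defaults are deterministic full-batch gradient descent with step
#' halving whenever a proposed step would increase the cost (so the
#' batch-mode cost is non-increasing across epochs), and a mild
#' multiplicative step-size decay.  A seeded stochastic
#' (sample-by-sample) mode is available.
#'
#' @param epochs Number of passes over the data.
#' @param lr_prototype Initial prototype step size.
#' @param lr_omega Initial metric step size (default `lr_prototype/10`).
#' @param schedule Multiplicative step-size decay per epoch, in (0, 1].
#' @param mode `"batch"` or `"stochastic"`.
#' @param seed Seed for the stochastic shuffling.
#' @param phi,slope Margin transfer function (see [gmlvq_cost()]).
#' @return A list of class `gmlvq_train_config`.
#' @export
gmlvq_train_config <- function(epochs = 60, lr_prototype = 0.5,
                               lr_omega = lr_prototype / 10,
                               schedule = 0.99,
                               mode = c("batch", "stochastic"),
                               seed = 1L, phi = "identity", slope = 1) {
  mode <- match.arg(mode)
  stopifnot(epochs >= 0, lr_prototype > 0, lr_omega > 0,
            schedule > 0, schedule <= 1)
  structure(list(epochs = as.integer(epochs),
                 lr_prototype = lr_prototype, lr_omega = lr_omega,
                 schedule = schedule, mode = mode, seed = as.integer(seed),
                 phi = phi, slope = slope),
            class = "gmlvq_train_config")
}

#' Train a GMLVQ model
#'
#' Gradient descent on the relative-distance cost with respect to all
#' prototypes and the metric matrix Omega.  Omega is rescaled to
#' `trace(Omega' Omega) = 1` after every accepted update (the cost is
#' invariant under this rescaling, which prevents metric degeneration).
#' In batch mode a step that would increase the cost is halved (both
#' step sizes) until it does not, so the recorded cost is non-increasing;
#' the run is fully deterministic given the config seed.
#'
#' @param model An initialised `gmlvq_model`.
#' @param fm The z-scored training [feature_matrix()].
#' @param config A [gmlvq_train_config()].
#' @return The trained model; `training_log` holds the cost after each
#'   epoch.
#' @export
gmlvq_train <- function(model, fm, config = gmlvq_train_config()) {
  stopifnot(inherits(model, "gmlvq_model"),
            inherits(config, "gmlvq_train_config"))
  check_dim(model, fm$values)
  n <- nrow(fm$values)
  lr_w <- config$lr_prototype
  lr_o <- config$lr_omega
  log_cost <- numeric(config$epochs)
  if (config$mode == "batch") {
    current <- gmlvq_cost(model, fm, config$phi, config$slope)
    for (ep in seq_len(config$epochs)) {
      gr <- gmlvq_gradients(model, fm, config$phi, config$slope)
      if (!all(is.finite(gr$prototypes)) || !all(is.finite(gr$omega))) {
        stopf("non-finite gradient at epoch %d", ep)
      }
      hw <- lr_w
      ho <- lr_o
      repeat {
        W_new <- model$prototypes - hw * gr$prototypes / n
        O_new <- normalise_omega(model$omega - ho * gr$omega / n)
        cand <- model
        cand$prototypes <- W_new
        cand$omega <- O_new
        new_cost <- gmlvq_cost(cand, fm, config$phi, config$slope)
        if (!is.finite(new_cost)) stopf("non-finite cost at epoch %d", ep)
        if (new_cost <= current) {
          model <- cand
          current <- new_cost
          break
        }
        hw <- hw / 2
        ho <- ho / 2
        if (hw < 1e-12) break  # no descent step found; keep parameters
      }
      stopifnot(abs(sum(model$omega^2) - 1) < 1e-10)
      log_cost[ep] <- current
      lr_w <- lr_w * config$schedule
      lr_o <- lr_o * config$schedule
    }
  } else {
    order_seeds <- with_seed(config$seed, {
      replicate(config$epochs, sample.int(n), simplify = FALSE)
    })
    for (ep in seq_len(config$epochs)) {
      for (i in order_seeds[[ep]]) {
        fi <- feature_matrix(fm$values[i, , drop = FALSE], fm$labels[i])
        gr <- gmlvq_gradients(model, fi, config$phi, config$slope)
        model$prototypes <- model$prototypes - lr_w * gr$prototypes
        model$omega <- normalise_omega(model$omega - lr_o * gr$omega)
      }
      cost <- gmlvq_cost(model, fm, config$phi, config$slope)
      if (!is.finite(cost)) stopf("non-finite cost at epoch %d", ep)
      stopifnot(abs(sum(model$omega^2) - 1) < 1e-10)
      log_cost[ep] <- cost
      lr_w <- lr_w * config$schedule
      lr_o <- lr_o * config$schedule
    }
  }
  model$trained <- TRUE
  model$training_log <- log_cost
  model$config <- config
  model
}

#' Predict class labels by nearest prototype
#'
#' Assigns the class of the prototype closest under the learned metric.
#' Exact ties are broken deterministically towards the lowest class
#' label in sort order and flagged in the `"tie"` attribute.
#'
#' @param object A `gmlvq_model`.
#' @param newdata Numeric vector, matrix, or [feature_matrix()].
#' @param ... Unused.
#' @return Character vector of predicted labels with logical attribute
#'   `"tie"`.
#' @export
predict.gmlvq_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  X <- as_row_matrix(object, newdata)
  D <- gmlvq_distances(object, X)
  if (!is.matrix(D)) D <- matrix(D, nrow = 1)
  # per sample: minimal distance per class, then lowest-sorted class wins
  per_class <- vapply(object$classes, function(cl) {
    apply(D[, object$prototype_class == cl, drop = FALSE], 1, min)
  }, numeric(nrow(D)))
  if (!is.matrix(per_class)) per_class <- matrix(per_class, nrow = 1,
                                                 dimnames = list(NULL, object$classes))
  best <- apply(per_class, 1, min)
  tie <- rowSums(per_class == best) > 1
  labels <- object$classes[max.col(-per_class, ties.method = "first")]
  attr(labels, "tie") <- tie
  labels
}

#' Signed relative-distance decision score
#'
#' For a binary model, `(d_neg - d_pos) / (d_neg + d_pos)` where `d_pos`
#' (`d_neg`) is the distance to the closest prototype of the positive
#' (negative) class: +1 at a positive prototype, -1 at a negative one,
#' 0 on the decision boundary; thresholding at 0 reproduces
#' [predict.gmlvq_model()].  Antisymmetric under swapping the positive
#' class.  This is the statistic the ROC analysis sweeps.
#'
#' @param model A binary `gmlvq_model`.
#' @param x Vector, matrix, or [feature_matrix()].
#' @param positive_class One of the model's two classes.
#' @return Numeric score(s) in \[-1, 1\].
#' @export
gmlvq_score <- function(model, x, positive_class) {
  if (length(model$classes) != 2) {
    stopf("decision scores require a binary model (got %d classes)",
          length(model$classes))
  }
  if (!positive_class %in% model$classes) {
    stopf("unknown positive class '%s'", positive_class)
  }
  if (inherits(x, "feature_matrix")) x <- x$values
  X <- as_row_matrix(model, x)
  D <- gmlvq_distances(model, X)
  if (!is.matrix(D)) D <- matrix(D, nrow = 1)
  pos <- model$prototype_class == positive_class
  d_pos <- apply(D[, pos, drop = FALSE], 1, min)
  d_neg <- apply(D[, !pos, drop = FALSE], 1, min)
  denom <- d_pos + d_neg
  ifelse(denom > 0, (d_neg - d_pos) / denom, 0)
}

#' Per-feature relevances
#'
#' The diagonal of the relevance matrix `Lambda = Omega' Omega`:
#' non-negative weights summing to 1 that quantify the importance of
#' each feature (steroid metabolite) to the classifier.
#'
#' @param model A `gmlvq_model`.
#' @return Named numeric vector over features.
#' @export
gmlvq_relevances <- function(model) {
  stats::setNames(colSums(model$omega^2), model$feature_names)
}

#' Relevance-metric 2D projection
#'
#' Projects data onto the two leading eigenvectors of the relevance
#' matrix, scaled by the square roots of the eigenvalues, giving the
#' planar view in which the learned metric measures distance.  If Lambda
#' has rank < 2 the second coordinate is zero-filled with a warning.
#' Eigenvector signs are fixed deterministically (largest-magnitude
#' component positive).
#'
#' @param model A `gmlvq_model`.
#' @param fm A [feature_matrix()] (or plain matrix) to project.
#' @return An n x 2 matrix of coordinates with attribute
#'   `"eigenvalues"`.
#' @export
gmlvq_project <- function(model, fm) {
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  check_dim(model, X)
  lambda <- crossprod(model$omega)
  eig <- eigen(lambda, symmetric = TRUE)
  vec <- eig$vectors[, 1:2, drop = FALSE]
  for (k in 1:2) {
    pivot <- which.max(abs(vec[, k]))
    if (vec[pivot, k] < 0) vec[, k] <- -vec[, k]
  }
  ev <- pmax(eig$values[1:2], 0)
  tol <- max(eig$values[1], 0) * 1e-12
  if (ev[2] <= tol) {
    warnf("relevance matrix has rank < 2; second coordinate zero-filled")
    ev[2] <- 0
  }
  coords <- X %*% vec %*% diag(sqrt(ev), 2)
  colnames(coords) <- c("dim1", "dim2")
  attr(coords, "eigenvalues") <- eig$values[1:2]
  coords
}

#' Serialise / restore a GMLVQ model as JSON
#'
#' Writes feature names, classes, prototypes, Omega (row-major), the
#' training config and the training log to a JSON document with 17
#' significant digits, so a reloaded model reproduces predictions
#' bit-identically.
#'
#' @param model A `gmlvq_model`.
#' @param path File path.
#' @return `gmlvq_write_json` returns `path` invisibly;
#'   `gmlvq_read_json` returns the model.
#' @export
gmlvq_write_json <- function(model, path) {
  doc <- list(feature_names = model$feature_names,
              classes = model$classes,
              prototype_class = model$prototype_class,
              prototypes = as.vector(t(model$prototypes)),
              omega = as.vector(t(model$omega)),
              d = ncol(model$prototypes),
              trained = model$trained,
              training_log = model$training_log,
              config = if (!is.null(model$config)) {
                unclass(model$config)
              })
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname gmlvq_write_json
#' @export
gmlvq_read_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- doc$d
  W <- matrix(doc$prototypes, ncol = d, byrow = TRUE)
  colnames(W) <- doc$feature_names
  model <- structure(list(prototypes = W,
                          prototype_class = doc$prototype_class,
                          omega = matrix(doc$omega, ncol = d,
                                         byrow = TRUE),
                          classes = doc$classes,
                          feature_names = doc$feature_names,
                          trained = isTRUE(doc$trained),
                          training_log = as.numeric(doc$training_log)),
                     class = "gmlvq_model")
  if (!is.null(doc$config)) {
    model$config <- structure(doc$config, class = "gmlvq_train_config")
  }
  model
}
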