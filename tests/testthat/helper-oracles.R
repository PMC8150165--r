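# Independent naive reference implementations used as oracles.  They are
# deliberately written as plain elementwise loops, sharing no code with
# the package internals.

# (x - w)' Omega' Omega (x - w) via an explicit triple loop.
naive_distance <- function(omega, w, x) {
  d <- length(x)
  lambda <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      for (k in seq_len(d)) {
        lambda[i, j] <- lambda[i, j] + omega[k, i] * omega[k, j]
      }
    }
  }
  diff <- unname(x - w)
  acc <- 0
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      acc <- acc + diff[i] * lambda[i, j] * diff[j]
    }
  }
  acc
}

# Cost by per-sample enumeration of all prototypes.
naive_cost <- function(model, X, labels) {
  total <- 0
  for (i in seq_len(nrow(X))) {
    dj <- Inf
    dk <- Inf
    for (p in seq_len(nrow(model$prototypes))) {
      dist <- naive_distance(model$omega, model$prototypes[p, ], X[i, ])
      if (model$prototype_class[p] == labels[i]) {
        dj <- min(dj, dist)
      } else {
        dk <- min(dk, dist)
      }
    }
    total <- total + if (dj + dk > 0) (dj - dk) / (dj + dk) else 0
  }
  total
}

# Nearest-prototype labels by exhaustive scan; ties -> first in the
# sorted class order.
naive_predict <- function(model, X) {
  out <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    best <- Inf
    best_class <- NA_character_
    for (cl in sort(model$classes)) {
      for (p in which(model$prototype_class == cl)) {
        dist <- naive_distance(model$omega, model$prototypes[p, ], X[i, ])
        if (dist < best) {
          best <- dist
          best_class <- cl
        }
      }
    }
    out[i] <- best_class
  }
  out
}

# Mann-Whitney concordance with half credit for ties, by exhaustive
# pair enumeration.
concordance_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  acc <- 0
  for (p in pos) {
    for (q in neg) {
      acc <- acc + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  acc / (length(pos) * length(neg))
}

# Small random labelled instance plus a model whose parameters are
# random (not trained), for oracle-equivalence checks.
random_instance <- function(seed, n = 12, d = 4, classes = c("a", "b")) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * d), n, d,
                dimnames = list(NULL, paste0("f", seq_len(d))))
    labels <- sample(classes, n, replace = TRUE)
    # ensure both classes occur at least twice
    labels[1:4] <- rep(classes, 2)
    fm <- feature_matrix(X, labels)
    model <- gmlvq_init(fm, seed = seed)
    model$prototypes <- model$prototypes +
      matrix(rnorm(length(model$prototypes), 0, 0.5),
             nrow(model$prototypes))
    model$omega <- matrix(rnorm(d * d), d, d)
    model$omega <- model$omega / sqrt(sum(model$omega^2))
    list(fm = fm, model = model)
  })
}

# Two-class cohort spec with a given effect (in noise-SD units) on the
# first n_inf panel metabolites; the acceptance-battery construction.
separable_spec <- function(seed, effect = 4, n_inf = 5, n = 100) {
  eff <- stats::setNames(rep(effect, n_inf), default_panel()[seq_len(n_inf)])
  cohort_spec(
    n_per_class = c(F0 = n, F4 = n),
    informative_features = list(sep = list(classes = "F4", effects = eff)),
    seed = seed)
}

# Central finite differences of the GMLVQ cost in every prototype
# coordinate and Omega entry.
fd_gradients <- function(model, fm, eps = 1e-5) {
  cost_at <- function(m) gmlvq_cost(m, fm)
  gW <- model$prototypes * 0
  for (p in seq_len(nrow(gW))) {
    for (j in seq_len(ncol(gW))) {
      up <- model; up$prototypes[p, j] <- up$prototypes[p, j] + eps
      dn <- model; dn$prototypes[p, j] <- dn$prototypes[p, j] - eps
      gW[p, j] <- (cost_at(up) - cost_at(dn)) / (2 * eps)
    }
  }
  gO <- model$omega * 0
  for (i in seq_len(nrow(gO))) {
    for (j in seq_len(ncol(gO))) {
      up <- model; up$omega[i, j] <- up$omega[i, j] + eps
      dn <- model; dn$omega[i, j] <- dn$omega[i, j] - eps
      gO[i, j] <- (cost_at(up) - cost_at(dn)) / (2 * eps)
    }
  }
  list(prototypes = gW, omega = gO)
}
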