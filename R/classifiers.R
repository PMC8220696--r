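# Classifier backends for the evaluation harness: RBF-kernel SVM (e1071),
# Gini decision tree (rpart) and a linear hinge-loss classifier trained by
# stochastic gradient descent (Pegasos-style schedule, one-vs-rest for
# multiclass). Features are standardized with training statistics inside
# each backend so fold-level evaluation never touches test data.

.fit_classifier <- function(kind, X, y_codes, levels, seed = 1L,
                            hyperparameters = list()) {
  kind <- match.arg(kind, c("svm", "dt", "sgd"))
  std <- .standardize(X)
  yf <- factor(levels[y_codes], levels = levels)
  model <- switch(kind,
    svm = withr::with_seed(seed, {
      gamma <- hyperparameters$gamma %||% .median_heuristic_gamma(std$X)
      e1071::svm(x = std$X, y = yf, kernel = "radial", scale = FALSE,
                 gamma = gamma, cost = hyperparameters$cost %||% 1)
    }),
    dt = withr::with_seed(seed, {
      df <- as.data.frame(std$X)
      names(df) <- paste0("f", seq_len(ncol(std$X)))
      df$.y <- yf
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(cp = 0, xval = 0L,
                                                  maxdepth = 30L))
    }),
    sgd = .sgd_fit(std$X, y_codes, n_classes = length(levels), seed = seed,
                   hyperparameters = hyperparameters))
  structure(list(kind = kind, model = model, levels = levels,
                 center = std$center, scale = std$scale),
            class = "wgdipc_classifier")
}

.predict_classifier <- function(fit, X) {
  Xs <- .standardize(X, center = fit$center, scale = fit$scale)$X
  out <- switch(fit$kind,
    svm = as.character(predict(fit$model, Xs)),
    dt = {
      df <- as.data.frame(Xs)
      names(df) <- paste0("f", seq_len(ncol(Xs)))
      as.character(predict(fit$model, df, type = "class"))
    },
    sgd = {
      scores <- cbind(1, Xs) %*% fit$model$W
      fit$levels[max.col(scores, ties.method = "first")]
    })
  out
}

# RBF bandwidth by the median heuristic: gamma = 1 / median squared
# pairwise distance (computed on at most 200 rows). A data-driven width is
# much more robust than 1/p on sparse composition features.
.median_heuristic_gamma <- function(X) {
  if (nrow(X) > 200L) X <- X[seq(1L, nrow(X), length.out = 200L), , drop = FALSE]
  d2 <- stats::dist(X) ^ 2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) 1 / ncol(X) else 1 / med
}

# Pegasos SGD on the hinge loss with L2 regularization. Binary problems use
# a single +/-1 column; multiclass one column per class (one-vs-rest).
.sgd_fit <- function(X, y_codes, n_classes, seed = 1L,
                     hyperparameters = list()) {
  lambda <- hyperparameters$lambda %||% 1e-4
  epochs <- hyperparameters$epochs %||% 10L
  m <- nrow(X)
  p <- ncol(X)
  Xb <- cbind(1, X)
  targets <- if (n_classes == 2L) {
    matrix(ifelse(y_codes == 2L, 1, -1), ncol = 1L)
  } else {
    T <- matrix(-1, m, n_classes)
    T[cbind(seq_len(m), y_codes)] <- 1
    T
  }
  W <- matrix(0, p + 1L, ncol(targets))
  withr::with_seed(seed, {
    # start the schedule at t0 = 1/lambda so early steps are bounded
    t <- ceiling(1 / lambda)
    for (ep in seq_len(epochs)) {
      for (i in sample.int(m)) {
        t <- t + 1L
        eta <- 1 / (lambda * t)
        xi <- Xb[i, ]
        margins <- targets[i, ] * drop(crossprod(xi, W))
        W <- (1 - eta * lambda) * W
        viol <- margins < 1
        if (any(viol)) {
          W[, viol] <- W[, viol] +
            eta * xi %o% targets[i, viol]
        }
      }
    }
  })
  if (n_classes == 2L) W <- cbind(-W, W)  # scores for (level1, level2)
  list(W = W, lambda = lambda, epochs = epochs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
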