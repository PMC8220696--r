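#' Configuration for the Relief selector
#'
#' @param m sampling count: how many instances drive the weight updates.
#'   `NULL` (default) uses every sample once in a deterministic pass;
#'   otherwise `m` instances are drawn with the supplied seed.
#' @param k_neighbors nearest hits/misses per instance; must be smaller
#'   than the smallest class.
#' @param theta optional weight threshold for threshold-mode selection in
#'   [relief_select()].
#' @return a list of class `wgdipc_relief_config`.
#' @export
relief_config <- function(m = NULL, k_neighbors = 5L, theta = NULL) {
  stopifnot(is.null(m) || (is.numeric(m) && m >= 1),
            k_neighbors >= 1L)
  structure(list(m = if (is.null(m)) NULL else as.integer(m),
                 k_neighbors = as.integer(k_neighbors),
                 theta = theta),
            class = "wgdipc_relief_config")
}

#' Relief feature weights
#'
#' Instance-based feature weighting: for each sampled instance `R`, the `k`
#' nearest same-class neighbours (hits `H`) pull the weight of every
#' feature down by its mean normalized difference
#' `diff(A, R, H) = |R[A] - H[A]| / (max(A) - min(A))`, and the `k` nearest
#' other-class neighbours (misses `M`) push it up:
#' `W(A) <- W(A) - diff(A, R, H)/m + diff(A, R, M)/m`. With more than two
#' classes, misses are taken per class and weighted by the class prior
#' (ReliefF weighting). Distances are Euclidean on standardized features;
#' constant features have `diff = 0`. With averaged neighbour differences
#' every weight satisfies `|W(A)| <= 1`.
#'
#' @inheritParams lasso_select
#' @param config a [relief_config()].
#' @param seed integer seed; only consulted when `config$m` requests random
#'   sampling.
#' @return `relief_weights()`: a named numeric vector of per-feature
#'   weights.
#' @export
relief_weights <- function(data, config = relief_config(),
                           response = "label", seed = 1L) {
  prob <- .as_problem(data, response)
  if (is.null(prob$levels)) {
    abort("relief requires a categorical response (class labels)")
  }
  X <- prob$X
  y <- prob$y
  m_samples <- nrow(X)
  p <- ncol(X)
  k <- config$k_neighbors
  class_sizes <- tabulate(y)
  if (any(class_sizes <= k)) {
    small <- prob$levels[class_sizes <= k]
    abort(paste0("every class must have more than k_neighbors = ", k,
                 " members; too small: ", paste(small, collapse = ", ")))
  }
  # z-scored copy for distances, range-scaled copy for diff
  Xz <- .standardize(X)$X
  rng <- apply(X, 2L, function(v) diff(range(v)))
  ok <- rng > 0
  X01 <- X
  X01[, ok] <- sweep(sweep(X[, ok, drop = FALSE], 2L,
                           apply(X[, ok, drop = FALSE], 2L, min)),
                     2L, rng[ok], "/")
  X01[, !ok] <- 0  # constant feature: diff defined as 0

  D <- as.matrix(stats::dist(Xz))
  diag(D) <- Inf
  priors <- class_sizes / m_samples
  classes <- seq_along(prob$levels)
  idx_by_class <- lapply(classes, function(cl) which(y == cl))

  picks <- if (is.null(config$m)) {
    seq_len(m_samples)
  } else {
    withr::with_seed(seed,
      sample.int(m_samples, config$m, replace = config$m > m_samples))
  }
  m_eff <- length(picks)
  W <- numeric(p)
  for (i in picks) {
    same <- setdiff(idx_by_class[[y[i]]], i)
    hits <- same[order(D[i, same])][seq_len(k)]
    hit_term <- colMeans(abs(X01[hits, , drop = FALSE] -
                             rep(X01[i, ], each = k)))
    miss_term <- numeric(p)
    for (cl in classes[classes != y[i]]) {
      cand <- idx_by_class[[cl]]
      miss <- cand[order(D[i, cand])][seq_len(k)]
      w_cl <- priors[cl] / (1 - priors[y[i]])
      miss_term <- miss_term +
        w_cl * colMeans(abs(X01[miss, , drop = FALSE] -
                            rep(X01[i, ], each = k)))
    }
    W <- W + (miss_term - hit_term) / m_eff
  }
  setNames(W, prob$feature_names)
}

#' @rdname relief_weights
#' @inheritParams select_features
#' @param theta optional weight threshold; when given (or set in `config`),
#'   all features with `W >= theta` are returned instead of a top-`n` cut
#'   (and the result may be empty).
#' @return `relief_select()`: a `wgdipc_selection`; top-`n` by weight
#'   (ties by ascending index), or threshold mode when `theta` is set.
#' @export
relief_select <- function(data, n, config = relief_config(),
                          response = "label", seed = 1L, theta = NULL) {
  prob <- .as_problem(data, response)
  if (is.null(theta)) theta <- config$theta
  W <- relief_weights(data, config = config, response = response, seed = seed)
  if (!is.null(theta)) {
    selected <- which(W >= theta)
  } else {
    n <- .check_n_select(n, ncol(prob$X))
    selected <- .top_n_by_score(W, n)
  }
  new_selector_result("relief", selected, W, prob$feature_names,
                      diagnostics = list(k_neighbors = config$k_neighbors,
                                         m = length(prob$y), theta = theta))
}
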