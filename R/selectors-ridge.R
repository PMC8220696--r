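#' Configuration for the Ridge selector
#'
#' @param lambda_grid positive penalties searched; default 50 log-spaced
#'   values in `[1e-4, 1e4]`.
#' @param cv_folds folds for the cross-validated grid search.
#' @return a list of class `wgdipc_ridge_config`.
#' @export
ridge_config <- function(lambda_grid = 10 ^ seq(-4, 4, length.out = 50L),
                         cv_folds = 5L) {
  stopifnot(all(lambda_grid > 0), cv_folds >= 2L)
  structure(list(lambda_grid = sort(as.numeric(lambda_grid)),
                 cv_folds = as.integer(cv_folds)),
            class = "wgdipc_ridge_config")
}

# closed-form ridge coefficients b(lambda) = (X'X + lambda I)^{-1} X'Y for a
# whole lambda grid at once, via one eigendecomposition of X'X.
# Returns a p x ncol(Y) x length(lambdas) array.
.ridge_path <- function(X, Y, lambdas) {
  p <- ncol(X)
  E <- eigen(crossprod(X), symmetric = TRUE)
  XtY <- crossprod(X, Y)            # p x q
  VtXtY <- crossprod(E$vectors, XtY)
  out <- array(0, dim = c(p, ncol(Y), length(lambdas)))
  ev <- pmax(E$values, 0)
  for (l in seq_along(lambdas)) {
    out[, , l] <- E$vectors %*% (VtXtY / (ev + lambdas[l]))
  }
  out
}

# column-standardize with train statistics; constant columns become zeros
.standardize <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2L, sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  list(X = sweep(sweep(X, 2L, center), 2L, scale, "/"),
       center = center, scale = scale)
}

#' Ridge filter: grid-searched penalty, top coefficients by magnitude
#'
#' Computes the closed-form ridge solution
#' `b(lambda) = (X'X + lambda I)^{-1} X'Y` on standardized features, picks
#' the penalty minimizing cross-validated mean squared error over
#' `config$lambda_grid`, and returns the `n` features with largest absolute
#' coefficient (multiclass: max across one-vs-rest columns), ties broken by
#' ascending feature index.
#'
#' @inheritParams lasso_select
#' @param config a [ridge_config()].
#' @param seed integer seed for the CV fold assignment.
#' @return a `wgdipc_selection` with diagnostics `lambda` (the chosen
#'   penalty) and `cv` (a tibble of per-lambda CV mean squared errors).
#' @export
ridge_select <- function(data, n, config = ridge_config(),
                         response = "label", seed = 1L) {
  prob <- .as_problem(data, response)
  p <- ncol(prob$X)
  n <- .check_n_select(n, p)
  Y <- .response_matrix(prob)
  Yc <- sweep(Y, 2L, colMeans(Y))
  std <- .standardize(prob$X)
  m <- nrow(prob$X)
  lambdas <- config$lambda_grid

  folds <- withr::with_seed(seed, sample(rep_len(seq_len(config$cv_folds), m)))
  mse <- matrix(0, nrow = length(lambdas), ncol = config$cv_folds)
  for (f in seq_len(config$cv_folds)) {
    tr <- folds != f
    std_tr <- .standardize(prob$X[tr, , drop = FALSE])
    Ytr <- sweep(Y[tr, , drop = FALSE], 2L, colMeans(Y[tr, , drop = FALSE]))
    Yte <- sweep(Y[!tr, , drop = FALSE], 2L, colMeans(Y[tr, , drop = FALSE]))
    Xte <- .standardize(prob$X[!tr, , drop = FALSE],
                        center = std_tr$center, scale = std_tr$scale)$X
    path <- .ridge_path(std_tr$X, Ytr, lambdas)
    for (l in seq_along(lambdas)) {
      resid <- Yte - Xte %*% path[, , l, drop = TRUE]
      mse[l, f] <- mean(resid ^ 2)
    }
  }
  cv_mse <- rowMeans(mse)
  if (!any(is.finite(cv_mse))) {
    abort(paste0("ridge fit failed at every lambda in [",
                 min(lambdas), ", ", max(lambdas), "]"))
  }
  lambda_star <- lambdas[which.min(cv_mse)]
  B <- .ridge_path(std$X, Yc, lambda_star)[, , 1L, drop = TRUE]
  B <- matrix(B, nrow = p)
  scores <- apply(abs(B), 1L, max)
  new_selector_result("ridge", .top_n_by_score(scores, n), scores,
                      prob$feature_names,
                      diagnostics = list(lambda = lambda_star,
                                         cv = tibble(lambda = lambdas,
                                                     mse = cv_mse)))
}
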