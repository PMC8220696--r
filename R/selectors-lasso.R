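#' Configuration for the Lasso dichotomy selector
#'
#' The Lasso filter does not expose the selected-feature count directly, so
#' the budget constant `c` (mapped monotonically to the L1 penalty as
#' `lambda = 1/c`; larger `c` means a weaker penalty and more nonzero
#' coefficients) is tuned by bisection until the nonzero-coefficient count
#' falls in the band `[n, band_factor * n]`. If the bisection fails within
#' `max_bisect_iter` iterations the search interval is magnified by
#' `restart_scale` and the bisection restarts, up to `max_restarts` times;
#' exhausting the restarts is reported as non-convergence.
#'
#' @param initial_interval numeric length-2, the initial search interval
#'   for the budget constant `c`.
#' @param band_factor upper edge of the convergence band as a multiple of
#'   `n` (must be > 1).
#' @param max_bisect_iter maximum bisection iterations per attempt.
#' @param max_restarts maximum interval magnifications after failure.
#' @param restart_scale interval magnification factor.
#' @param on_nonconvergence `"error"` (default) raises an explicit
#'   non-convergence error; `"top_coef"` falls back to the top-`n`
#'   absolute coefficients at the last evaluated budget.
#' @return a list of class `wgdipc_lasso_config`.
#' @export
lasso_config <- function(initial_interval = c(0, 1e6),
                         band_factor = 1.05,
                         max_bisect_iter = 100L,
                         max_restarts = 10L,
                         restart_scale = 10,
                         on_nonconvergence = c("error", "top_coef")) {
  stopifnot(length(initial_interval) == 2L, initial_interval[1] >= 0,
            initial_interval[2] > initial_interval[1],
            band_factor > 1, max_bisect_iter >= 1, max_restarts >= 0,
            restart_scale > 1)
  structure(list(initial_interval = as.numeric(initial_interval),
                 band_factor = band_factor,
                 max_bisect_iter = as.integer(max_bisect_iter),
                 max_restarts = as.integer(max_restarts),
                 restart_scale = restart_scale,
                 on_nonconvergence = match.arg(on_nonconvergence)),
            class = "wgdipc_lasso_config")
}

#' Lasso filter: dichotomy search on the selection budget
#'
#' Fits L1-penalized regressions of the class indicator(s) on the features
#' and bisects the budget constant `c` (penalty `lambda = 1/c`) until the
#' number of selected variables — features that have entered the lasso path
#' at penalty `>= 1/c` — lies in `[n, band_factor * n]`; the `n` of them
#' with largest absolute coefficient at the converged budget are returned.
#' Multiclass responses are handled one-vs-rest with per-feature score
#' `max |coefficient|` across classes.
#'
#' @inheritParams select_features
#' @param config a [lasso_config()].
#' @param response name of the response column in `data`.
#' @return a `wgdipc_selection` with diagnostics `converged`, `c`,
#'   `lambda`, `iterations`, `restarts`, `count_pre_truncation` and the
#'   bisection `trace` (a tibble of evaluated budgets and counts).
#' @export
lasso_select <- function(data, n, config = lasso_config(),
                         response = "label", seed = NULL) {
  prob <- .as_problem(data, response)
  p <- ncol(prob$X)
  n <- .check_n_select(n, p)
  if (n == p) {
    return(new_selector_result(
      "lasso", seq_len(p), rep(1, p), prob$feature_names,
      diagnostics = list(converged = TRUE, c = NA_real_, lambda = NA_real_,
                         iterations = 0L, restarts = 0L,
                         count_pre_truncation = p, trace = tibble(
                           c = numeric(), count = integer()))))
  }
  Y <- .response_matrix(prob)
  fits <- lapply(seq_len(ncol(Y)), function(j) {
    # explicit lambda sequence: glmnet would otherwise stop the path early
    # once the deviance saturates, leaving large budgets unreachable
    lmax <- max(glmnet::glmnet(prob$X, Y[, j], family = "gaussian",
                               nlambda = 3L)$lambda)
    lamseq <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 500L))
    glmnet::glmnet(prob$X, Y[, j], family = "gaussian", standardize = TRUE,
                   lambda = lamseq)
  })
  # a feature counts as selected at budget c once it has entered the lasso
  # path at penalty >= 1/c (in any one-vs-rest column); this count is
  # monotone in c, matching the assumed positive budget/count correlation
  entry_lambda <- rep(-Inf, p)
  for (fit in fits) {
    beta <- abs(as.matrix(fit$beta))
    lam <- fit$lambda
    L <- length(lam)
    for (j in seq_len(p)) {
      hit <- which(beta[j, ] != 0)
      if (length(hit) == 0L) next
      h <- hit[1L]
      # the true entry point lies between the last zero knot and the first
      # nonzero knot; locate it by extrapolating the coefficient's initial
      # slope back to zero so entries spread out along the budget axis
      est <- if (h == 1L) {
        lam[1L]
      } else if (h < L && beta[j, h + 1L] > beta[j, h]) {
        slope <- (beta[j, h + 1L] - beta[j, h]) / (lam[h] - lam[h + 1L])
        min(max(lam[h] + beta[j, h] / slope, lam[h]), lam[h - 1L])
      } else {
        sqrt(lam[h - 1L] * lam[h])
      }
      entry_lambda[j] <- max(entry_lambda[j], est)
    }
  }
  coef_at <- function(lambda) {
    sapply(seq_along(fits), function(j) {
      as.numeric(glmnet::coef.glmnet(fits[[j]], s = lambda))[-1L]
    })
  }
  count_at <- function(lambda) sum(entry_lambda >= lambda)

  band_lo <- n
  band_hi <- config$band_factor * n
  interval <- config$initial_interval
  trace_c <- numeric(0)
  trace_count <- integer(0)
  converged <- FALSE
  total_iter <- 0L
  restarts <- 0L
  c_star <- NA_real_
  B_star <- NULL
  count_star <- NA_integer_

  repeat {
    lo <- interval[1]; hi <- interval[2]
    for (it in seq_len(config$max_bisect_iter)) {
      mid <- (lo + hi) / 2
      lam <- if (mid <= 0) Inf else 1 / mid
      cnt <- count_at(lam)
      total_iter <- total_iter + 1L
      trace_c <- c(trace_c, mid)
      trace_count <- c(trace_count, cnt)
      c_star <- mid; count_star <- cnt
      if (cnt >= band_lo && cnt <= band_hi) { converged <- TRUE; break }
      if (cnt < band_lo) lo <- mid else hi <- mid
    }
    if (converged || restarts >= config$max_restarts) break
    restarts <- restarts + 1L
    interval[2] <- interval[2] * config$restart_scale
  }

  diagnostics <- list(converged = converged, c = c_star,
                      lambda = if (is.na(c_star) || c_star <= 0) Inf else 1 / c_star,
                      iterations = total_iter, restarts = restarts,
                      count_pre_truncation = count_star,
                      trace = tibble(c = trace_c, count = trace_count))
  if (!converged && config$on_nonconvergence == "error") {
    abort(paste0(
      "lasso dichotomy did not converge: no budget c with selected count in [",
      band_lo, ", ", band_hi, "] after ", restarts,
      " restart(s); last count = ", count_star,
      ". Set on_nonconvergence = \"top_coef\" to fall back to the top-n ",
      "absolute coefficients at the last budget."))
  }
  lam_star <- if (is.na(c_star) || c_star <= 0) Inf else 1 / c_star
  B_star <- coef_at(lam_star)
  scores <- apply(abs(matrix(B_star, nrow = p)), 1L, max)
  active <- which(entry_lambda >= lam_star)
  selected <- if (length(active) >= n) {
    # rank within the selected (entered) set, ties by index
    act_sorted <- active[order(-scores[active], active)]
    sort(act_sorted[seq_len(n)])
  } else {
    .top_n_by_score(scores, n)
  }
  new_selector_result("lasso", selected, scores, prob$feature_names,
                      diagnostics = diagnostics)
}
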