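#' Configuration for the maximal-information-coefficient selector
#'
#' @param grid_exponent exponent of the grid-size cap: grids of `x` columns
#'   by `y` rows are searched subject to `x * y <= floor(m^grid_exponent)`
#'   where `m` is the sample count.
#' @param estimator `"mine"` (default): y-axis equipartition with dynamic
#'   programming optimization of the x-axis over clumps, both orientations;
#'   `"equipartition"`: equal-frequency binning of both axes (no cut
#'   optimization) — cheaper and coarser.
#' @param clumps_factor superclump cap for the `"mine"` estimator: at most
#'   `clumps_factor * x` candidate cut blocks per shape. `Inf` disables the
#'   cap (exact over clump boundaries, slower).
#' @return a list of class `wgdipc_mic_config`.
#' @export
mic_config <- function(grid_exponent = 0.6,
                       estimator = c("mine", "equipartition"),
                       clumps_factor = 5) {
  stopifnot(grid_exponent > 0, grid_exponent < 1, clumps_factor > 0)
  structure(list(grid_exponent = grid_exponent,
                 estimator = match.arg(estimator),
                 clumps_factor = clumps_factor),
            class = "wgdipc_mic_config")
}

#' Per-feature maximal information coefficient against the response
#'
#' For each feature, MIC is the maximum over admissible two-dimensional
#' grids (columns x rows, with `cols * rows <= floor(m^0.6)` by default) of
#' the grid's mutual information normalized by `log(min(cols, rows))`;
#' scores lie in `[0, 1]`. Features with fewer than two distinct values
#' score 0.
#'
#' @inheritParams lasso_select
#' @param config a [mic_config()].
#' @return `mic_scores()`: a named numeric vector of per-feature scores.
#' @export
mic_scores <- function(data, config = mic_config(), response = "label") {
  prob <- .as_problem(data, response)
  m <- nrow(prob$X)
  if (m < 8L) abort(paste0("MIC needs at least 8 samples (grid cap degenerate); got ", m))
  y <- as.numeric(prob$y)
  cfac <- if (is.finite(config$clumps_factor)) config$clumps_factor else -1
  scores <- if (config$estimator == "mine") {
    .cpp_mic_matrix(prob$X, y, alpha = config$grid_exponent, cfac = cfac)
  } else {
    apply(prob$X, 2L, .mic_equipartition, y = y,
          grid_exponent = config$grid_exponent)
  }
  n_distinct <- apply(prob$X, 2L, function(v) length(unique(v)))
  scores[n_distinct < 2L] <- 0
  setNames(as.numeric(scores), prob$feature_names)
}

#' @rdname mic_scores
#' @inheritParams select_features
#' @return `mic_select()`: a `wgdipc_selection` with the top-`n` features
#'   by MIC, ties broken by ascending index.
#' @export
mic_select <- function(data, n, config = mic_config(), response = "label") {
  prob <- .as_problem(data, response)
  n <- .check_n_select(n, ncol(prob$X))
  scores <- mic_scores(data, config = config, response = response)
  new_selector_result("mic", .top_n_by_score(scores, n), scores,
                      prob$feature_names,
                      diagnostics = list(estimator = config$estimator,
                                         grid_cap = floor(nrow(prob$X) ^
                                                          config$grid_exponent)))
}

# equal-frequency binning of both axes over all shapes x*y <= B; the plain
# estimator behind estimator = "equipartition"
.mic_equipartition <- function(x, y, grid_exponent = 0.6) {
  m <- length(x)
  B <- max(4L, floor(m ^ grid_exponent))
  best <- 0
  for (q in 2:max(2L, B %/% 2L)) {
    lmax <- B %/% q
    if (lmax < 2L) break
    ry <- .cpp_equipartition(y, q)
    for (l in 2:lmax) {
      rx <- .cpp_equipartition(x, l)
      tab <- table(rx, ry)
      px <- rowSums(tab) / m
      py <- colSums(tab) / m
      pj <- tab / m
      mi <- sum(pj[pj > 0] * log(pj[pj > 0] /
                                 outer(px, py)[as.matrix(pj) > 0]))
      val <- mi / log(min(l, q))
      if (is.finite(val) && val > best) best <- val
    }
  }
  min(max(best, 0), 1)
}
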