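#' LRMR-Ri: two-stage multi-regression ensemble feature selection
#'
#' Stage 1 runs the four single filters — Lasso (dichotomy budget search),
#' Ridge, MIC and Relief — each selecting `n` features. If the four
#' selected sets share a common (four-way) intersection, that intersection
#' is the optimal subset and stage 2 is skipped. Otherwise the four sets
#' are pooled into their union and Ridge re-selects
#' `min(n, |pooled|)` features from the pooled columns (stage 2).
#'
#' @inheritParams select_features
#' @param n target number of features per stage-1 filter (and for the
#'   stage-2 re-selection).
#' @param seed integer seed; split into per-selector streams so the whole
#'   ensemble is reproducible from one value.
#' @param lasso,ridge,mic,relief optional configuration objects for the
#'   stage-1 filters ([lasso_config()] etc.); the stage-2 Ridge reuses
#'   `ridge`.
#' @param response name of the response column in `data`.
#' @return a `wgdipc_ensemble` object: list with `stage1` (the four
#'   `wgdipc_selection`s), `intersection`, `pooled`, `stage2_used`,
#'   `final` (sorted feature indices), `feature_names` and `n`.
#' @examples
#' sims <- generate_sequences(sim_config(n_per_class = c(pos = 30, neg = 30)))
#' feats <- encode_features(sims)
#' ens <- lrmr_ri(feats, n = 20, seed = 1)
#' glance(ens)
#' @export
lrmr_ri <- function(data, n = 100L, seed = 1L,
                    lasso = lasso_config(), ridge = ridge_config(),
                    mic = mic_config(), relief = relief_config(),
                    response = "label") {
  prob <- .as_problem(data, response)
  n <- .check_n_select(n, ncol(prob$X))
  seeds <- (as.integer(seed) + c(1L, 2L, 3L, 4L) * 1000003L) %% 2147483647L
  run <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage-1 selector '", what, "' failed: ",
                   conditionMessage(e)))
    })
  }
  stage1 <- list(
    lasso = run("lasso", lasso_select(data, n, config = lasso,
                                      response = response)),
    ridge = run("ridge", ridge_select(data, n, config = ridge,
                                      response = response, seed = seeds[2])),
    mic = run("mic", mic_select(data, n, config = mic, response = response)),
    relief = run("relief", relief_select(data, n, config = relief,
                                         response = response,
                                         seed = seeds[4])))
  sets <- lapply(stage1, function(s) s$selected)
  combined <- .combine_stage1(sets)
  final <- combined$final
  if (combined$stage2_used) {
    if (length(combined$pooled) < 2L) {
      abort("pooled stage-1 selection has fewer than 2 features")
    }
    keep_cols <- prob$feature_names[combined$pooled]
    sub <- data[, c(intersect(c("id", response), names(data)), keep_cols)]
    n2 <- min(n, length(combined$pooled))
    stage2 <- ridge_select(sub, n2, config = ridge, response = response,
                           seed = seeds[2])
    final <- sort(combined$pooled[stage2$selected])
  }
  structure(
    list(stage1 = stage1,
         intersection = combined$intersection,
         pooled = combined$pooled,
         stage2_used = combined$stage2_used,
         final = final,
         feature_names = prob$feature_names,
         n = n, seed = as.integer(seed)),
    class = "wgdipc_ensemble")
}

# branch logic: four-way intersection of any size >= 1 wins; otherwise the
# pooled union goes to stage 2
.combine_stage1 <- function(sets) {
  stopifnot(length(sets) == 4L)
  intersection <- sort(Reduce(intersect, sets))
  pooled <- sort(Reduce(union, sets))
  if (length(intersection) > 0L) {
    list(intersection = intersection, pooled = pooled,
         stage2_used = FALSE, final = intersection)
  } else {
    list(intersection = integer(0), pooled = pooled,
         stage2_used = TRUE, final = integer(0))
  }
}

#' @exportS3Method base::print
print.wgdipc_ensemble <- function(x, ...) {
  cat("<wgdipc_ensemble> LRMR-Ri, n =", x$n, "\n")
  cat("  stage-1 sets:",
      paste(vapply(x$stage1, function(s) length(s$selected), integer(1)),
            collapse = "/"),
      "| intersection:", length(x$intersection),
      "| pooled:", length(x$pooled), "\n")
  cat("  branch:", if (x$stage2_used) "stage-2 ridge over pooled set"
      else "common subset (stage 2 skipped)",
      "| final:", length(x$final), "features\n")
  invisible(x)
}

#' Subset a feature table to selected columns
#'
#' @param data a feature table (id/label plus feature columns).
#' @param indices a sorted-or-not vector of feature indices (1-based,
#'   relative to the feature columns), or a `wgdipc_selection` /
#'   `wgdipc_ensemble` whose selection is used.
#' @param response name of the response column kept alongside the features.
#' @return the tibble restricted to `id`/response plus the selected feature
#'   columns, in index order.
#' @export
apply_selection <- function(data, indices, response = "label") {
  if (inherits(indices, "wgdipc_selection")) indices <- indices$selected
  if (inherits(indices, "wgdipc_ensemble")) indices <- indices$final
  feat_cols <- setdiff(names(data), c(response, "id"))
  feat_cols <- feat_cols[vapply(data[feat_cols], is.numeric, logical(1))]
  if (length(indices) == 0L) abort("empty selection: no feature indices")
  indices <- as.integer(indices)
  if (any(indices < 1L | indices > length(feat_cols))) {
    abort(paste0("feature index out of range [1, ", length(feat_cols), "]"))
  }
  keep <- c(intersect(c("id", response), names(data)), feat_cols[indices])
  out <- as_tibble(data[, keep])
  out
}
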