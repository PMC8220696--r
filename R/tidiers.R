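# broom-style tidiers for the package's result objects.

#' Tidy a single-filter selection
#'
#' @param x a `wgdipc_selection` from [lasso_select()], [ridge_select()],
#'   [mic_select()] or [relief_select()].
#' @param ... unused.
#' @return a tibble with one row per feature: `feature`, `score`, `rank`
#'   (by descending score, ties by index) and `selected`.
#' @export
tidy.wgdipc_selection <- function(x, ...) {
  ranks <- rank(-x$scores, ties.method = "first")
  tibble(feature = x$feature_names,
         score = unname(x$scores),
         rank = as.integer(ranks),
         selected = seq_along(x$scores) %in% x$selected)
}

#' @rdname tidy.wgdipc_selection
#' @return `glance()`: a one-row tibble of method-level diagnostics.
#' @export
glance.wgdipc_selection <- function(x, ...) {
  d <- x$diagnostics
  tibble(method = x$method,
         n_selected = length(x$selected),
         n_features = length(x$scores),
         converged = d$converged %||% TRUE,
         c = d$c %||% NA_real_,
         lambda = d$lambda %||% NA_real_,
         iterations = d$iterations %||% NA_integer_)
}

#' Tidy an LRMR-Ri ensemble result
#'
#' @param x a `wgdipc_ensemble` from [lrmr_ri()].
#' @param ... unused.
#' @return a tibble with one row per feature appearing in any stage-1
#'   selection: `feature`, `index`, per-method selection flags, `n_methods`
#'   (how many filters picked it) and `final`.
#' @export
tidy.wgdipc_ensemble <- function(x, ...) {
  idx <- x$pooled
  flags <- purrr::map_dfc(x$stage1, function(s) idx %in% s$selected)
  dplyr::bind_cols(
    tibble(feature = x$feature_names[idx], index = idx),
    flags,
    tibble(n_methods = rowSums(as.matrix(flags)),
           final = idx %in% x$final))
}

#' @rdname tidy.wgdipc_ensemble
#' @return `glance()`: one row with `n`, stage-1 set sizes, intersection
#'   and pooled sizes, the branch taken and the final size.
#' @export
glance.wgdipc_ensemble <- function(x, ...) {
  tibble(n = x$n,
         intersection_size = length(x$intersection),
         pooled_size = length(x$pooled),
         stage2_used = x$stage2_used,
         final_size = length(x$final),
         seed = x$seed)
}

#' Tidy a cross-validation report
#'
#' @param x a `wgdipc_cv` from [cross_validate()].
#' @param ... unused.
#' @return per-fold metrics, one row per fold.
#' @export
tidy.wgdipc_cv <- function(x, ...) x$per_fold

#' @rdname tidy.wgdipc_cv
#' @return `glance()`: the fold-averaged metrics with run metadata.
#' @export
glance.wgdipc_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble(classifier = x$classifier,
           selector = x$selector %||% "none",
           folds = x$folds, seed = x$seed),
    x$mean)
}

#' Tidy a multiclass report
#'
#' @param x a `wgdipc_multiclass` from [multiclass_report()].
#' @param ... unused.
#' @return the per-class metric tibble.
#' @export
tidy.wgdipc_multiclass <- function(x, ...) x$per_class

#' @rdname tidy.wgdipc_multiclass
#' @export
glance.wgdipc_multiclass <- function(x, ...) {
  tibble(n_classes = length(x$levels), acc = x$acc, mcc = x$mcc,
         mcc_macro = x$mcc_macro)
}
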