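# Shared plumbing for the four single filters and the ensemble.

# Build a selection problem from a feature table. `data` is a data frame
# with a response column (default "label") and numeric feature columns
# (an `id` column, if present, is carried along but not used as a feature).
# A character/factor response becomes integer class codes in first-seen
# order; a numeric response is used as a plain regression target.
.as_problem <- function(data, response = "label") {
  if (!is.data.frame(data)) abort("`data` must be a data frame")
  if (!response %in% names(data)) {
    abort(paste0("`data` has no response column '", response, "'"))
  }
  y_raw <- data[[response]]
  feat_cols <- setdiff(names(data), c(response, "id"))
  numeric_cols <- feat_cols[vapply(data[feat_cols], is.numeric, logical(1))]
  if (length(numeric_cols) < 1L) abort("`data` has no numeric feature columns")
  X <- as.matrix(data[numeric_cols])
  if (anyNA(X)) abort("feature matrix contains missing values")
  storage.mode(X) <- "double"
  if (is.numeric(y_raw)) {
    if (anyNA(y_raw)) abort("response contains missing values")
    y <- as.numeric(y_raw)
    levels <- NULL
    if (length(unique(y)) < 2L) abort("response must take at least 2 distinct values")
  } else {
    y_chr <- as.character(y_raw)
    if (anyNA(y_chr)) abort("response contains missing values")
    levels <- unique(y_chr)
    if (length(levels) < 2L) abort("response must have at least 2 distinct classes")
    y <- match(y_chr, levels)
  }
  list(X = X, y = y, levels = levels, feature_names = colnames(X))
}

# Response matrix for the penalized regressions: numeric target as a single
# column; binary classes as one 0/1 column; >=3 classes as one-vs-rest
# indicator columns (an integer coding would impose an arbitrary ordering).
.response_matrix <- function(prob) {
  if (is.null(prob$levels)) return(matrix(prob$y, ncol = 1L))
  k <- length(prob$levels)
  if (k == 2L) return(matrix(as.numeric(prob$y == 2L), ncol = 1L))
  Y <- matrix(0, nrow = length(prob$y), ncol = k)
  Y[cbind(seq_along(prob$y), prob$y)] <- 1
  Y
}

.check_n_select <- function(n, p) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n)) {
    abort("`n` must be a single positive integer")
  }
  if (n > p) abort(paste0("`n` (", n, ") exceeds the number of features (", p, ")"))
  as.integer(n)
}

# top-n feature indices by score, ties broken by ascending index
.top_n_by_score <- function(scores, n) {
  ord <- order(-scores, seq_along(scores))
  sort(ord[seq_len(n)])
}

new_selector_result <- function(method, selected, scores, feature_names,
                                diagnostics = list()) {
  structure(
    list(method = method,
         selected = as.integer(selected),
         scores = setNames(as.numeric(scores), feature_names),
         feature_names = feature_names,
         diagnostics = diagnostics),
    class = "wgdipc_selection")
}

#' @exportS3Method base::print
print.wgdipc_selection <- function(x, ...) {
  cat("<wgdipc_selection> method =", x$method,
      "| selected", length(x$selected), "of", length(x$scores), "features\n")
  top <- utils::head(x$feature_names[x$selected], 10L)
  cat("  first selected:", paste(top, collapse = " "),
      if (length(x$selected) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Run one feature-selection filter (or the ensemble) on a feature table
#'
#' Tidy front end dispatching to [lasso_select()], [ridge_select()],
#' [mic_select()], [relief_select()] or [lrmr_ri()].
#'
#' @param data a feature table (e.g. from [encode_features()]): a data
#'   frame with a `label` column and numeric feature columns.
#' @param method one of `"lasso"`, `"ridge"`, `"mic"`, `"relief"`,
#'   `"lrmr_ri"`.
#' @param n number of features each filter selects.
#' @param seed integer seed controlling any stochastic component.
#' @param ... passed to the method-specific function (configuration
#'   objects, `response`, ...).
#' @return a `wgdipc_selection` (or, for `"lrmr_ri"`, a `wgdipc_ensemble`)
#'   object; see [tidy()] and [glance()] methods.
#' @export
select_features <- function(data, method = c("lrmr_ri", "lasso", "ridge",
                                             "mic", "relief"),
                            n = 100L, seed = 1L, ...) {
  method <- match.arg(method)
  switch(method,
    lasso  = lasso_select(data, n = n, ...),
    ridge  = ridge_select(data, n = n, seed = seed, ...),
    mic    = mic_select(data, n = n, ...),
    relief = relief_select(data, n = n, seed = seed, ...),
    lrmr_ri = lrmr_ri(data, n = n, seed = seed, ...))
}
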