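#' Confusion counts for a binary (or one-vs-rest) contrast
#'
#' @param y_true,y_pred vectors of class labels of equal length.
#' @param positive the label treated as the positive class.
#' @return a named integer vector `c(tp, tn, fp, fn)`.
#' @examples
#' confusion_counts(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 1, 0, 0), positive = 1)
#' @export
confusion_counts <- function(y_true, y_pred, positive) {
  if (length(y_true) != length(y_pred)) abort("y_true and y_pred lengths differ")
  if (length(y_true) < 1L) abort("need at least one sample")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  unseen <- setdiff(unique(y_pred), unique(y_true))
  if (length(unseen) > 0L) {
    abort(paste0("label(s) in y_pred never occur in y_true: ",
                 paste(unseen, collapse = ", ")))
  }
  pos <- as.character(positive)
  tp <- sum(y_true == pos & y_pred == pos)
  tn <- sum(y_true != pos & y_pred != pos)
  fp <- sum(y_true != pos & y_pred == pos)
  fn <- sum(y_true == pos & y_pred != pos)
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

#' The five evaluation metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, recall `TP/(TP+FN)`, precision
#' `TP/(TP+FP)`, F-measure `2*PE*RE/(PE+RE)` and the Matthews correlation
#' coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TN+FN)(TP+FN)(TN+FP))`.
#' Zero denominators follow the usual conventions: precision/recall are 0
#' when their denominator is 0, F is 0 when `PE + RE = 0`, and MCC is 0
#' when any factor under the square root is 0 (e.g. a class never
#' predicted).
#'
#' @param counts a named vector/list with elements `tp`, `tn`, `fp`, `fn`
#'   (as returned by [confusion_counts()]).
#' @return a one-row tibble with columns `acc`, `recall`, `precision`,
#'   `f_measure`, `mcc`.
#' @examples
#' metric_set(c(tp = 3, tn = 2, fp = 1, fn = 0))
#' @export
metric_set <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); tn <- as.numeric(counts[["tn"]])
  fp <- as.numeric(counts[["fp"]]); fn <- as.numeric(counts[["fn"]])
  total <- tp + tn + fp + fn
  if (total <= 0) abort("confusion counts sum to zero")
  acc <- (tp + tn) / total
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  denom <- (tp + fp) * (tn + fn) * (tp + fn) * (tn + fp)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  tibble(acc = acc, recall = recall, precision = precision,
         f_measure = f, mcc = mcc)
}

#' Per-class and overall metrics for a multiclass prediction
#'
#' Per-class precision/recall/F come from one-vs-rest confusion counts; a
#' class never predicted and without true positives reports 0 for all
#' three. Overall accuracy is the pooled accuracy, and the overall MCC is
#' the generalized (multi-category) Matthews correlation computed from the
#' full confusion matrix, which reduces exactly to the binary MCC for two
#' classes. `mcc_macro` (the mean of per-class one-vs-rest MCCs) is
#' reported alongside as an alternative summary.
#'
#' @inheritParams confusion_counts
#' @param levels optional class ordering; defaults to first-seen order in
#'   `y_true`.
#' @return a list of class `wgdipc_multiclass` with elements `per_class`
#'   (tibble: class, n, precision, recall, f_measure, mcc), `acc`, `mcc`
#'   and `mcc_macro`.
#' @export
multiclass_report <- function(y_true, y_pred, levels = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (is.null(levels)) levels <- unique(y_true)
  if (length(levels) < 2L) abort("need at least 2 classes")
  per <- purrr::map_dfr(levels, function(cl) {
    m <- metric_set(confusion_counts(y_true, y_pred, positive = cl))
    dplyr::bind_cols(tibble(class = cl, n = sum(y_true == cl)), m)
  })
  per <- dplyr::select(per, "class", "n", "precision", "recall",
                       "f_measure", "mcc")
  structure(list(per_class = per,
                 acc = mean(y_true == y_pred),
                 mcc = .multiclass_mcc(y_true, y_pred, levels),
                 mcc_macro = mean(per$mcc),
                 levels = levels),
            class = "wgdipc_multiclass")
}

# generalized (R_K) Matthews correlation from the full confusion matrix
.multiclass_mcc <- function(y_true, y_pred, levels) {
  C <- table(factor(y_true, levels = levels), factor(y_pred, levels = levels))
  C <- matrix(as.numeric(C), nrow = length(levels))
  s <- sum(C)
  c_corr <- sum(diag(C))
  t_k <- rowSums(C)   # true counts per class
  p_k <- colSums(C)   # predicted counts per class
  num <- c_corr * s - sum(t_k * p_k)
  den <- sqrt(s ^ 2 - sum(p_k ^ 2)) * sqrt(s ^ 2 - sum(t_k ^ 2))
  if (den == 0) 0 else num / den
}

#' @exportS3Method base::print
print.wgdipc_multiclass <- function(x, ...) {
  cat("<wgdipc_multiclass>", length(x$levels), "classes | ACC",
      sprintf("%.4f", x$acc), "| MCC", sprintf("%.4f", x$mcc), "\n")
  print(x$per_class)
  invisible(x)
}

# stratified fold assignment: shuffle within class, deal folds round-robin
.stratified_folds <- function(y, folds, seed) {
  sizes <- table(y)
  if (any(sizes < folds)) {
    abort(paste0("class(es) smaller than the fold count (", folds, "): ",
                 paste(names(sizes)[sizes < folds], collapse = ", ")))
  }
  assignment <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

#' Cross-validated training and evaluation
#'
#' Stratified k-fold cross-validation of one classifier on a feature table,
#' optionally with per-fold feature selection. By default any selector is
#' fitted on each fold's training split only and applied to its test split
#' (leakage-safe); `paper_mode = TRUE` instead selects once on the full
#' matrix before splitting. Fold metrics are averaged arithmetically.
#'
#' @param data a feature table (e.g. from [encode_features()]): `label`
#'   column plus numeric feature columns.
#' @param classifier `"svm"` (RBF kernel), `"dt"` (Gini decision tree) or
#'   `"sgd"` (linear hinge-loss SGD).
#' @param selector `NULL` for no selection, or one of `"lasso"`, `"ridge"`,
#'   `"mic"`, `"relief"`, `"lrmr_ri"`.
#' @param n_select features per filter when `selector` is set.
#' @param folds number of folds.
#' @param seed integer seed driving fold assignment, selector streams and
#'   classifier randomness.
#' @param positive positive-class label for binary metrics; default the
#'   first-seen label.
#' @param paper_mode if `TRUE`, run the selector once on the full data
#'   before cross-validation instead of per fold.
#' @param hyperparameters named list passed to the classifier backend.
#' @return a `wgdipc_cv` object: `per_fold` (tibble of fold metrics),
#'   `mean` (one-row tibble), `per_class` (multiclass only: per-class
#'   metrics averaged over folds), `fold_assignment`, `classifier`,
#'   `selector`, `seed`.
#' @examples
#' sims <- generate_sequences(sim_config(n_per_class = c(pos = 25, neg = 25)))
#' feats <- encode_features(sims)
#' cv <- cross_validate(feats, classifier = "dt", seed = 7)
#' glance(cv)
#' @export
cross_validate <- function(data, classifier = c("svm", "dt", "sgd"),
                           selector = NULL, n_select = 100L, folds = 5L,
                           seed = 1L, positive = NULL, paper_mode = FALSE,
                           hyperparameters = list()) {
  classifier <- match.arg(classifier)
  prob <- .as_problem(data, "label")
  if (is.null(prob$levels)) abort("cross_validate needs categorical labels")
  levels <- prob$levels
  if (is.null(positive)) positive <- levels[1]
  binary <- length(levels) == 2L
  assignment <- .stratified_folds(prob$y, folds, seed)

  if (!is.null(selector) && paper_mode) {
    sel <- select_features(data, method = selector, n = n_select,
                           seed = seed)
    data <- apply_selection(data, sel)
  }

  per_fold <- vector("list", folds)
  per_class_folds <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr_idx <- which(assignment != f)
    te_idx <- which(assignment == f)
    train <- data[tr_idx, , drop = FALSE]
    test <- data[te_idx, , drop = FALSE]
    if (!is.null(selector) && !paper_mode) {
      fold_seed <- (as.integer(seed) + f * 7919L) %% 2147483647L
      sel <- select_features(train, method = selector, n = n_select,
                             seed = fold_seed)
      train <- apply_selection(train, sel)
      test <- apply_selection(test, sel)
    }
    ptr <- .as_problem(train, "label")
    Xtr <- ptr$X
    ytr <- match(as.character(train$label), levels)
    Xte <- as.matrix(test[, colnames(Xtr), drop = FALSE])
    fit <- .fit_classifier(classifier, Xtr, ytr, levels,
                           seed = (as.integer(seed) + f) %% 2147483647L,
                           hyperparameters = hyperparameters)
    pred <- .predict_classifier(fit, Xte)
    truth <- as.character(test$label)
    if (binary) {
      m <- metric_set(confusion_counts(truth, pred, positive = positive))
      per_fold[[f]] <- dplyr::bind_cols(tibble(fold = f), m)
    } else {
      rep_f <- multiclass_report(truth, pred, levels = levels)
      per_fold[[f]] <- tibble(fold = f, acc = rep_f$acc, mcc = rep_f$mcc,
                              precision = mean(rep_f$per_class$precision),
                              recall = mean(rep_f$per_class$recall),
                              f_measure = mean(rep_f$per_class$f_measure))
      per_class_folds[[f]] <- dplyr::mutate(rep_f$per_class, fold = f)
    }
  }
  per_fold <- dplyr::bind_rows(per_fold)
  mean_row <- dplyr::summarise(per_fold,
                               dplyr::across(-"fold", ~ mean(.x)))
  per_class <- if (!binary) {
    dplyr::summarise(
      dplyr::group_by(dplyr::bind_rows(per_class_folds), .data$class),
      n = sum(.data$n),
      dplyr::across(c("precision", "recall", "f_measure", "mcc"),
                    ~ mean(.x)),
      .groups = "drop")
  } else NULL
  structure(list(per_fold = per_fold, mean = mean_row,
                 per_class = per_class,
                 fold_assignment = tibble(
                   id = if ("id" %in% names(data)) data$id
                        else as.character(seq_len(nrow(data))),
                   fold = assignment),
                 classifier = classifier, selector = selector,
                 positive = positive, folds = folds,
                 seed = as.integer(seed)),
            class = "wgdipc_cv")
}

#' @exportS3Method base::print
print.wgdipc_cv <- function(x, ...) {
  cat("<wgdipc_cv>", x$folds, "folds |", x$classifier,
      if (!is.null(x$selector)) paste0("+ ", x$selector) else "", "\n")
  print(x$mean)
  invisible(x)
}

#' Fusion-coefficient sweep
#'
#' Re-encodes the sequences at each fusion coefficient `alpha` and
#' cross-validates each classifier, tabulating the mean accuracy (and MCC)
#' per `(alpha, classifier)` cell — the experiment used to choose the
#' fusion coefficient.
#'
#' @param records tibble with `id`, `sequence` (and optionally `label`).
#' @param labels label table or named vector (see [encode_features()]);
#'   `NULL` if `records` carries a `label` column.
#' @param alphas fusion coefficients to evaluate.
#' @param classifiers classifier kinds to evaluate.
#' @param selector,n_select optional selection inside each CV run.
#' @param folds,seed cross-validation controls.
#' @return a tibble of class `wgdipc_sweep` with columns `alpha`,
#'   `classifier`, `acc`, `mcc` (one row per cell, alphas ascending within
#'   classifier).
#' @export
alpha_sweep <- function(records, labels = NULL, alphas = seq(0, 1, by = 0.1),
                        classifiers = c("svm", "dt", "sgd"),
                        selector = NULL, n_select = 100L,
                        folds = 5L, seed = 1L) {
  stopifnot(all(alphas >= 0 & alphas <= 1))
  alphas <- sort(alphas)
  rows <- purrr::map_dfr(alphas, function(a) {
    feats <- encode_features(records, labels, alpha = a)
    purrr::map_dfr(classifiers, function(clf) {
      cv <- cross_validate(feats, classifier = clf, selector = selector,
                           n_select = n_select, folds = folds, seed = seed)
      tibble(alpha = a, classifier = clf,
             acc = cv$mean$acc, mcc = cv$mean$mcc)
    })
  })
  rows <- dplyr::arrange(rows, .data$classifier, .data$alpha)
  class(rows) <- c("wgdipc_sweep", class(rows))
  rows
}
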