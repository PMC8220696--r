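test_that("confusion counts are exact and symmetric in the class roles", {
  cc <- confusion_counts(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 1, 0, 0), positive = 1)
  expect_identical(cc, c(tp = 3L, tn = 2L, fp = 1L, fn = 0L))
  ident <- confusion_counts(c(1, 0, 1), c(1, 0, 1), positive = 1)
  expect_identical(ident[c("fp", "fn")], c(fp = 0L, fn = 0L))
  flipped <- confusion_counts(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 1, 0, 0),
                              positive = 0)
  expect_identical(unname(flipped), unname(cc[c("tn", "tp", "fn", "fp")]))
  expect_error(confusion_counts(c(1, 0), c(1, 2), positive = 1), "never occur")
})

test_that("the metric formulas reproduce the hand-worked confusion table", {
  m <- metric_set(c(tp = 3, tn = 2, fp = 1, fn = 0))
  expect_equal(m$acc, 5 / 6)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f_measure, 6 / 7)
  expect_equal(m$mcc, 6 / sqrt(72))
  perfect <- metric_set(c(tp = 10, tn = 5, fp = 0, fn = 0))
  expect_equal(unname(unlist(perfect)), rep(1, 5))
  # all-one-class prediction on mixed truth: MCC 0 by convention
  onesided <- metric_set(confusion_counts(c(1, 1, 0), c(1, 1, 1), positive = 1))
  expect_equal(onesided$mcc, 0)
  expect_equal(onesided$precision, 2 / 3)
  # never-predicted positive class: precision, recall, F all 0
  absent <- metric_set(c(tp = 0, tn = 4, fp = 0, fn = 2))
  expect_equal(c(absent$precision, absent$recall, absent$f_measure, absent$mcc),
               rep(0, 4))
})

test_that("metrics agree with the reconstructed-vector oracle on random
           confusion tables", {
  withr::with_seed(77, {
    for (i in 1:300) {
      counts <- rmultinom(1, size = sample(4:200, 1), prob = runif(4, 0.05, 1))
      tp <- counts[1]; tn <- counts[2]; fp <- counts[3]; fn <- counts[4]
      got <- metric_set(c(tp = tp, tn = tn, fp = fp, fn = fn))
      want <- oracle_metrics(tp, tn, fp, fn)
      expect_equal(got$acc, want$acc)
      expect_equal(got$recall, want$recall)
      expect_equal(got$precision, want$precision)
      expect_equal(got$f_measure, want$f_measure)
      expect_equal(got$mcc, want$mcc, tolerance = 1e-12)
    }
  })
})

test_that("multiclass reporting handles perfect, absent-class and binary
           reduction cases", {
  y <- rep(c("a", "b", "c"), each = 4)
  rep_perfect <- multiclass_report(y, y)
  expect_equal(rep_perfect$acc, 1)
  expect_equal(rep_perfect$mcc, 1)
  expect_true(all(unlist(rep_perfect$per_class[, c("precision", "recall",
                                                   "f_measure")]) == 1))
  # class "c" never predicted -> its precision/recall/F are all 0
  pred <- c(rep("a", 4), rep("b", 4), rep("a", 2), rep("b", 2))
  rep_absent <- multiclass_report(y, pred)
  row_c <- rep_absent$per_class[rep_absent$per_class$class == "c", ]
  expect_equal(unlist(row_c[, c("precision", "recall", "f_measure")]),
               c(precision = 0, recall = 0, f_measure = 0))
  # binary input: generalized MCC equals the binary formula
  withr::with_seed(5, {
    yt <- sample(c("p", "n"), 60, replace = TRUE)
    yp <- ifelse(runif(60) < 0.3, sample(c("p", "n"), 60, TRUE), yt)
  })
  rep_bin <- multiclass_report(yt, yp)
  m_bin <- metric_set(confusion_counts(yt, yp, positive = "p"))
  expect_equal(rep_bin$mcc, m_bin$mcc, tolerance = 1e-12)
  expect_equal(rep_bin$acc, m_bin$acc)
})

test_that("cross-validation folds are stratified, disjoint, covering and
           seed-stable", {
  cfg <- sim_config(n_per_class = c(pos = 33, neg = 27), seed = 9)
  feats <- encode_features(generate_sequences(cfg))
  cv1 <- cross_validate(feats, classifier = "dt", seed = 101)
  cv2 <- cross_validate(feats, classifier = "dt", seed = 101)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_identical(cv1$per_fold, cv2$per_fold)
  folds <- cv1$fold_assignment$fold
  expect_setequal(folds, 1:5)
  expect_length(folds, nrow(feats))
  # per-fold class proportions within one sample of the global split
  for (f in 1:5) {
    in_fold <- feats$label[folds == f]
    expect_lte(abs(sum(in_fold == "pos") - 33 / 5), 1)
    expect_lte(abs(sum(in_fold == "neg") - 27 / 5), 1)
  }
  expect_error(cross_validate(feats[c(1:3, 34:40), ], classifier = "dt"),
               "smaller than the fold count")
})

test_that("well-separated classes are learnt by all three classifiers", {
  # strong enrichment on three pairs per class: per-feature class gaps of
  # many standard deviations, i.e. an essentially separable problem
  cfg <- sim_config(n_per_class = c(pos = 40, neg = 40),
                    planted = tibble::tibble(
                      class = rep(c("pos", "neg"), each = 3),
                      pair = c("AC", "DE", "FG", "KL", "VW", "MN"),
                      k = rep(c(0L, 1L, 0L), 2), rho = 40),
                    seed = 13)
  feats <- encode_features(generate_sequences(cfg))
  for (clf in c("svm", "dt", "sgd")) {
    cv <- cross_validate(feats, classifier = clf, seed = 3)
    expect_gte(cv$mean$acc, 0.95)
  }
})

test_that("the alpha sweep covers the grid in order", {
  cfg <- sim_config(n_per_class = c(pos = 15, neg = 15),
                    length_range = c(30L, 50L), seed = 37)
  sims <- generate_sequences(cfg)
  sw <- alpha_sweep(sims, alphas = seq(0, 1, by = 0.1), classifiers = "dt",
                    folds = 3L, seed = 2)
  expect_equal(nrow(sw), 11L)
  expect_equal(sw$alpha, seq(0, 1, by = 0.1))
  expect_true(all(sw$classifier == "dt"))
  expect_true(all(sw$acc >= 0 & sw$acc <= 1))
  sw2 <- alpha_sweep(sims, alphas = c(0.4, 0), classifiers = c("dt", "sgd"),
                     folds = 3L, seed = 2)
  expect_equal(nrow(sw2), 4L)
  expect_true(all(diff(sw2$alpha[sw2$classifier == "dt"]) > 0))
})

test_that("multiclass cross-validation reports per-class metrics and zeros
           for unlearnable tiny classes", {
  cfg <- sim_config_multiclass(scale = 40, seed = 3)
  expect_equal(names(cfg$n_per_class)[c(1, 5)], c("type1", "multipass"))
  feats <- encode_features(generate_sequences(cfg))
  cv <- cross_validate(feats, classifier = "dt", selector = "ridge",
                       n_select = 50, seed = 4)
  expect_equal(nrow(cv$per_class), 8L)
  expect_true(all(c("acc", "mcc") %in% names(cv$mean)))
  expect_gte(cv$mean$acc, 0.4) # dominated by the large class
  # at one-fortieth scale the six-member classes are essentially
  # unlearnable: at least one reports the zero-metric phenomenon
  tiny <- cv$per_class[cv$per_class$n <= 10, ]
  expect_true(any(tiny$precision == 0 & tiny$recall == 0 &
                    tiny$f_measure == 0))
})

test_that("per-fold selection keeps test folds out of the selector", {
  cfg <- sim_config(n_per_class = c(pos = 30, neg = 30), seed = 53)
  feats <- encode_features(generate_sequences(cfg))
  cv <- cross_validate(feats, classifier = "dt", selector = "ridge",
                       n_select = 30, seed = 11)
  expect_s3_class(cv, "wgdipc_cv")
  expect_equal(nrow(cv$per_fold), 5L)
  cvp <- cross_validate(feats, classifier = "dt", selector = "ridge",
                        n_select = 30, seed = 11, paper_mode = TRUE)
  expect_equal(nrow(cvp$per_fold), 5L)
})
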