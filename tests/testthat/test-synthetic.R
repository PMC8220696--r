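test_that("generation is reproducible, length-bounded and alphabet-valid", {
  cfg <- sim_config(n_per_class = c(pos = 20, neg = 15),
                    length_range = c(40L, 80L), seed = 12)
  s1 <- generate_sequences(cfg)
  s2 <- generate_sequences(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 35L)
  expect_equal(as.vector(table(s1$label)[c("pos", "neg")]), c(20L, 15L))
  lens <- nchar(s1$sequence)
  expect_true(all(lens >= 40 & lens <= 80))
  expect_identical(validate_records(s1), s1[, c("id", "sequence")])
})

test_that("without enrichment the mean dipeptide composition is uniform", {
  cfg <- sim_config(n_per_class = c(bg = 400),
                    length_range = c(150L, 150L),
                    planted = tibble::tibble(class = character(),
                                             pair = character(),
                                             k = integer(), rho = numeric()),
                    seed = 31)
  sims <- generate_sequences(cfg)
  feats <- encode_features(sims, alpha = 1)
  means <- colMeans(as.matrix(feats[, -(1:2)]))
  # each composition entry is an average of 149 indicators with p = 1/400;
  # the standard error of the mean over 400 sequences
  se <- sqrt((1 / 400) * (1 - 1 / 400) / 149) / sqrt(400)
  expect_lt(abs(means[["AC"]] - 1 / 400), 3 * se)
  # family-wise bound over all 400 composition means
  expect_true(all(abs(means - 1 / 400) < 6 * se))
})

test_that("a planted pair separates the class means by many standard errors", {
  cfg <- sim_config(n_per_class = c(pos = 200, neg = 200),
                    planted = tibble::tibble(class = "pos", pair = "AC",
                                             k = 0L, rho = 10),
                    seed = 57)
  feats <- encode_features(generate_sequences(cfg), alpha = 1)
  ac <- feats[["AC"]]
  lab <- feats$label
  gap <- mean(ac[lab == "pos"]) - mean(ac[lab == "neg"])
  pooled_se <- sqrt(var(ac[lab == "pos"]) / 200 + var(ac[lab == "neg"]) / 200)
  expect_gte(gap / pooled_se, 5)
})

test_that("planted truth maps pairs to canonical indices regardless of gap", {
  cfg <- sim_config(n_per_class = c(a = 5, b = 5),
                    planted = tibble::tibble(class = c("a", "b"),
                                             pair = c("AC", "AC"),
                                             k = c(0L, 1L), rho = c(5, 5)),
                    seed = 1)
  tr <- planted_truth(cfg)
  expect_equal(tr$index, rep(dipeptide_index("AC"), 2))
  empty <- sim_config(n_per_class = c(a = 5, b = 5),
                      planted = tibble::tibble(class = character(),
                                               pair = character(),
                                               k = integer(), rho = numeric()),
                      seed = 1)
  expect_equal(nrow(planted_truth(empty)), 0L)
})

test_that("infeasible plantings and malformed configurations are rejected", {
  expect_error(sim_config(n_per_class = c(a = 5, b = 5),
                          planted = tibble::tibble(class = "a", pair = "AC",
                                                   k = 0L, rho = 500)),
               "infeasible")
  expect_error(sim_config(n_per_class = c(a = 5, b = 5),
                          planted = tibble::tibble(class = "a", pair = "AC",
                                                   k = 60L, rho = 2)),
               "gap k too large")
  expect_error(sim_config(n_per_class = c(a = 5), background = rep(1, 20)),
               "sum to 1")
  expect_error(sim_config(n_per_class = c(a = 5, b = 5),
                          planted = tibble::tibble(class = "zz", pair = "AC",
                                                   k = 0L, rho = 2)),
               "among the configured")
})

test_that("selector recovery is nondecreasing in the enrichment factor", {
  recovery <- vapply(c(1, 2, 5, 10), function(rho) {
    hits <- 0
    for (seed in 1:20) {
      cfg <- sim_config(n_per_class = c(pos = 40, neg = 40),
                        planted = tibble::tibble(
                          class = c("pos", "neg"), pair = c("AC", "KL"),
                          k = c(0L, 0L), rho = rho),
                        seed = 60 + seed)
      feats <- encode_features(generate_sequences(cfg))
      truth <- unique(planted_truth(cfg)$index)
      sel <- ridge_select(feats, n = 20, seed = seed)
      hits <- hits + mean(truth %in% sel$selected)
    }
    hits / 20
  }, numeric(1))
  expect_true(all(diff(recovery) >= 0))
  expect_gte(recovery[4], 0.95)
})
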