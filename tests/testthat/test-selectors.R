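# shared fixture: a small planted classification problem
planted_problem <- function(n_per_class = 60, seed = 5, rho = 10) {
  cfg <- sim_config(n_per_class = c(pos = n_per_class, neg = n_per_class),
                    planted = tibble::tibble(
                      class = c("pos", "pos", "neg", "neg"),
                      pair = c("AC", "DE", "KL", "VW"),
                      k = c(0L, 1L, 0L, 1L), rho = rho),
                    seed = seed)
  list(feats = encode_features(generate_sequences(cfg)),
       truth = sort(unique(planted_truth(cfg)$index)))
}

test_that("every selector returns exactly n distinct in-range indices,
           deterministically", {
  pp <- planted_problem(n_per_class = 30, seed = 17)
  for (method in c("lasso", "ridge", "mic", "relief")) {
    r1 <- select_features(pp$feats, method = method, n = 25, seed = 3)
    r2 <- select_features(pp$feats, method = method, n = 25, seed = 3)
    expect_length(r1$selected, 25L)
    expect_equal(anyDuplicated(r1$selected), 0L)
    expect_true(all(r1$selected >= 1 & r1$selected <= 400))
    expect_identical(r1$selected, r2$selected)
    expect_identical(r1$scores, r2$scores)
  }
})

test_that("n equal to the feature count returns all features", {
  pp <- planted_problem(n_per_class = 20, seed = 23)
  for (method in c("lasso", "ridge", "mic", "relief")) {
    r <- select_features(pp$feats, method = method, n = 400, seed = 1)
    expect_identical(r$selected, 1:400)
  }
  expect_true(glance(lasso_select(pp$feats, n = 400))$converged)
})

test_that("lasso bisection converges inside the band and its trace is
           monotone in the budget", {
  d <- planted_regression(m = 120, p = 200, n_signal = 5, seed = 31)
  r <- lasso_select(d, n = 40)
  g <- glance(r)
  expect_true(g$converged)
  cnt <- r$diagnostics$count_pre_truncation
  expect_gte(cnt, 40)
  expect_lte(cnt, 40 * 1.05)
  tr <- dplyr::arrange(r$diagnostics$trace, c)
  expect_true(all(diff(tr$count) >= 0))
})

test_that("lasso recovers planted regression features and honours the
           non-convergence contract", {
  d <- planted_regression(m = 150, p = 300, n_signal = 5, seed = 7)
  r <- lasso_select(d, n = 5)
  expect_setequal(r$selected, 1:5)
  # an impossible band: more features demanded than samples can support
  d2 <- planted_regression(m = 20, p = 60, n_signal = 2, seed = 8)
  expect_error(lasso_select(d2, n = 55), "did not converge")
  r2 <- lasso_select(d2, n = 55,
                     config = lasso_config(on_nonconvergence = "top_coef"))
  expect_length(r2$selected, 55L)
  expect_false(glance(r2)$converged)
})

test_that("ridge matches the closed-form coefficients and ranks by
           magnitude", {
  withr::with_seed(11, {
    X <- matrix(rnorm(40), 10, 4)
    Xs <- scale(X)
    y <- Xs[, 3] # y is exactly one standardized column
  })
  d <- dplyr::bind_cols(tibble::tibble(label = as.numeric(y)),
                        tibble::as_tibble(as.data.frame(X)))
  r <- ridge_select(d, n = 1, seed = 2)
  expect_identical(r$selected, 3L)
  # closed form at the selected penalty on the standardized problem
  lam <- r$diagnostics$lambda
  b <- solve(crossprod(Xs) + lam * diag(4), crossprod(Xs, y - mean(y)))
  expect_equal(unname(r$scores), abs(drop(b)), tolerance = 1e-8)
})

test_that("a constant feature gets (near) zero ridge weight and ranks last", {
  withr::with_seed(12, {
    X <- cbind(rnorm(50), rnorm(50), rep(1, 50))
    y <- X[, 1] + rnorm(50, sd = 0.1)
  })
  d <- dplyr::bind_cols(tibble::tibble(label = y),
                        tibble::as_tibble(as.data.frame(X)))
  r <- ridge_select(d, n = 3, seed = 1)
  expect_equal(unname(r$scores[3]), 0, tolerance = 1e-10)
  expect_equal(unname(which.min(r$scores)), 3L)
})

test_that("mic scores a deterministic relationship near 1 and matches the
           brute-force grid enumeration oracle", {
  withr::with_seed(21, {
    x <- runif(200)
    d <- tibble::tibble(label = as.numeric(x > 0.5), f1 = x,
                        f2 = runif(200), f3 = x)
  })
  s <- mic_scores(d)
  expect_gte(s[["f1"]], 0.9)
  expect_lt(s[["f2"]], s[["f1"]])
  expect_identical(s[["f1"]], s[["f3"]])  # duplicated columns, same score
  expect_true(all(s >= 0 & s <= 1))
  # exact agreement with exhaustive cut enumeration on small problems
  withr::with_seed(22, {
    for (i in 1:15) {
      m <- sample(8:14, 1)
      x <- round(runif(m), 1)
      y <- sample(0:1, m, replace = TRUE)
      got <- wgdipc:::.cpp_mic(x, y, 0.6, -1)
      expect_equal(got, oracle_mic(x, y), tolerance = 1e-12)
    }
  })
})

test_that("mic separates dependent from independent features across seeds", {
  hits <- 0L
  for (seed in 1:100) {
    withr::with_seed(seed, {
      x <- runif(200)
      d <- tibble::tibble(label = as.numeric(x > 0.5), dep = x, ind = runif(200))
    })
    s <- mic_scores(d)
    if (s[["dep"]] > s[["ind"]]) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("mic selection is equivariant under column permutation", {
  pp <- planted_problem(n_per_class = 20, seed = 29)
  r <- mic_select(pp$feats, n = 10)
  perm <- withr::with_seed(1, sample(400))
  permuted <- pp$feats[, c(1, 2, 2 + perm)]
  r2 <- mic_select(permuted, n = 10)
  expect_setequal(match(r$feature_names[r$selected],
                        r2$feature_names[r2$selected]),
                  seq_len(10))
  expect_error(mic_scores(pp$feats[c(1:3, 21:23), ]), "at least 8")
})

test_that("relief diff branches behave per definition and weights match the
           brute-force oracle", {
  # discrete 0/1 features: diff is 0 on agreement, 1 on disagreement;
  # continuous: |R - H| / range. Constructed 40-sample set, one feature
  # perfectly separating the classes.
  withr::with_seed(41, {
    y <- rep(c("a", "b"), each = 20)
    sep <- ifelse(y == "a", 0, 1) # discrete, perfectly separating
    noise <- runif(40)
    cont <- c(0.25, 0.5, runif(38)) # hand-traceable continuous values
  })
  X <- cbind(sep = sep, noise = noise, cont = cont)
  d <- dplyr::bind_cols(tibble::tibble(label = y),
                        tibble::as_tibble(as.data.frame(X)))
  W <- relief_weights(d, relief_config(k_neighbors = 1L))
  Wo <- oracle_relief(X, y)
  expect_equal(unname(W), Wo, tolerance = 1e-10)
  expect_equal(unname(W[1]), 1) # hit diff always 0, miss diff always 1
  expect_equal(unname(which.max(W)), 1L)
  expect_lte(max(abs(W)), 1 + 1e-12)
  # continuous diff arithmetic: |0.5 - 0.25| / range
  rng <- diff(range(cont))
  expect_equal(abs(cont[2] - cont[1]) / rng, 0.25 / rng)
})

test_that("relief respects class-size preconditions and the theta mode", {
  pp <- planted_problem(n_per_class = 25, seed = 43)
  expect_error(relief_weights(pp$feats, relief_config(k_neighbors = 25L)),
               "more than k_neighbors")
  W <- relief_weights(pp$feats, relief_config(k_neighbors = 3L))
  expect_lte(max(abs(W)), 1 + 1e-12)
  r <- relief_select(pp$feats, n = 5, config = relief_config(k_neighbors = 3L),
                     theta = max(W) + 1)
  expect_length(r$selected, 0L)
  r2 <- relief_select(pp$feats, n = 5, config = relief_config(k_neighbors = 3L),
                      theta = min(W))
  expect_length(r2$selected, 400L)
})

test_that("all four selectors place planted features in a generous top set",
{
  pp <- planted_problem(n_per_class = 60, seed = 47)
  for (method in c("lasso", "ridge", "mic", "relief")) {
    r <- select_features(pp$feats, method = method, n = 50, seed = 13)
    expect_true(all(pp$truth %in% r$selected),
                label = paste0(method, " recovered planted features"))
  }
})

test_that("selectors accept numeric responses and reject degenerate input", {
  d <- planted_regression(m = 50, p = 20, n_signal = 2, seed = 3)
  expect_s3_class(ridge_select(d, n = 5, seed = 1), "wgdipc_selection")
  expect_error(select_features(d, "relief", n = 5), "categorical")
  d_bad <- d
  d_bad$label <- 1
  expect_error(ridge_select(d_bad, n = 2), "distinct")
  expect_error(ridge_select(d, n = 0), "positive integer")
  expect_error(ridge_select(d, n = 21), "exceeds")
})
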