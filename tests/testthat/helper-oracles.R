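# Independent oracles and fixture builders. Everything here deliberately
# avoids the package's own computation paths: sliding-window dictionaries,
# direct formula evaluation on reconstructed vectors, explicit loops.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_sequence <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# dictionary-based gapped-pair frequencies: slide a window, tally pairs
oracle_pair_freq <- function(sequence, k) {
  n <- nchar(sequence)
  stopifnot(n >= k + 2)
  tally <- new.env(parent = emptyenv())
  for (j in seq_len(n - 1 - k)) {
    pair <- paste0(substr(sequence, j, j), substr(sequence, j + 1 + k, j + 1 + k))
    tally[[pair]] <- (tally[[pair]] %||% 0) + 1
  }
  out <- setNames(numeric(400), dipeptide_names())
  for (pair in ls(tally)) out[pair] <- tally[[pair]] / (n - k - 1)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# metric oracle: rebuild label vectors from the four counts and evaluate
# accuracy/recall/precision by proportions, MCC as the Pearson correlation
# of the 0/1 truth and prediction vectors, F as the harmonic mean
oracle_metrics <- function(tp, tn, fp, fn) {
  truth <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
  pred <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
  acc <- mean(truth == pred)
  recall <- if (sum(truth) > 0) mean(pred[truth == 1]) else 0
  precision <- if (sum(pred) > 0) mean(truth[pred == 1]) else 0
  f <- if (precision + recall > 0) 2 / (1 / precision + 1 / recall) else 0
  mcc <- if (var(truth) > 0 && var(pred) > 0) cor(truth, pred) else 0
  list(acc = acc, recall = recall, precision = precision,
       f_measure = f, mcc = mcc)
}

# plain Relief with m = all samples and k = 1, written as explicit loops;
# range-normalized diff, Euclidean distance on z-scored features
oracle_relief <- function(X, y) {
  m <- nrow(X); p <- ncol(X)
  Z <- scale(X); Z[is.nan(Z)] <- 0
  rng <- apply(X, 2, function(v) diff(range(v)))
  W <- numeric(p)
  for (i in seq_len(m)) {
    d <- sqrt(rowSums((Z - matrix(Z[i, ], m, p, byrow = TRUE)) ^ 2))
    d[i] <- Inf
    hit <- which(y == y[i] & d == min(d[y == y[i] & seq_len(m) != i]))[1]
    miss <- which(y != y[i] & d == min(d[y != y[i]]))[1]
    for (a in seq_len(p)) {
      dh <- if (rng[a] > 0) abs(X[i, a] - X[hit, a]) / rng[a] else 0
      dm <- if (rng[a] > 0) abs(X[i, a] - X[miss, a]) / rng[a] else 0
      W[a] <- W[a] - dh / m + dm / m
    }
  }
  W
}

# brute-force MIC: same y-axis equipartition, x-axis cut points enumerated
# exhaustively over every inter-point position, both orientations
oracle_mic <- function(x, y, alpha = 0.6) {
  m <- length(x)
  B <- max(4, floor(m ^ alpha))
  best <- 0
  for (orient in 1:2) {
    xv <- if (orient == 1) x else y
    yv <- if (orient == 1) y else x
    ord <- order(xv)
    xs <- xv[ord]
    for (q in 2:max(2, B %/% 2)) {
      lmax <- B %/% q
      if (lmax < 2) break
      ry <- wgdipc:::.cpp_equipartition(yv, q)[ord]
      pr <- tabulate(ry + 1, q) / m
      hq <- -sum(ifelse(pr > 0, pr * log(pr), 0))
      cuts <- which(diff(xs) != 0)
      for (l in 2:lmax) {
        if (length(cuts) < l - 1) next
        for (cmb in utils::combn(length(cuts), l - 1, simplify = FALSE)) {
          bnd <- c(0, cuts[cmb], m)
          J <- 0
          for (a in seq_len(l)) {
            cr <- tabulate(ry[(bnd[a] + 1):bnd[a + 1]] + 1, q)
            ctot <- sum(cr)
            J <- J + sum(ifelse(cr > 0, cr * log(cr), 0)) - ctot * log(ctot)
          }
          val <- (hq + J / m) / log(min(l, q))
          if (val > best) best <- val
        }
      }
    }
  }
  min(best, 1)
}

# small labeled regression problem with planted predictive features
planted_regression <- function(m = 200, p = 400, n_signal = 5, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(m * p), m, p, dimnames = list(NULL, paste0("V", 1:p)))
    beta <- numeric(p)
    beta[seq_len(n_signal)] <- 3
    y <- drop(X %*% beta) + rnorm(m, sd = 0.5)
  })
  dplyr::bind_cols(tibble::tibble(label = y),
                   tibble::as_tibble(X, .name_repair = "minimal"))
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}
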