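#' Configure the planted-signal sequence generator
#'
#' Describes a synthetic labeled protein-sequence set: per-class sample
#' counts, a length range, a background residue distribution, and a set of
#' planted class-discriminative residue pairs. Sequences are drawn
#' residue-by-residue from the background; for each planted
#' `(pair, gap k, enrichment rho)` of a record's class, whole pairs are
#' then Bernoulli-inserted at gap `k` so that the pair's expected
#' composition rises by a factor of about `rho` relative to background —
#' an analytically computable enrichment that makes the planted features a
#' usable ground truth for selector-recovery tests.
#'
#' The defaults mirror the shape of the binary antifreeze-protein benchmark
#' (positive/negative classes at roughly a 480:374 ratio, scaled down to
#' 120/94) with sequence lengths 50-100 and two planted pairs per class at
#' enrichment 10. [sim_config_multiclass()] mirrors the 8-class membrane
#' benchmark at 1/10 scale, retaining its two tiny classes.
#'
#' @param n_per_class named (or unnamed) integer vector of per-class
#'   sequence counts; names become class labels (`class1..K` otherwise).
#' @param length_range integer `c(min, max)` sequence lengths, `min >= 3`.
#' @param planted a data frame with columns `class`, `pair`, `k`, `rho`
#'   (enrichment factor `>= 1`), or `NULL` for no planted signal.
#' @param background length-20 residue probability vector (canonical
#'   order); default uniform.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return a list of class `wgdipc_sim_config`.
#' @examples
#' cfg <- sim_config(n_per_class = c(pos = 10, neg = 10), seed = 42)
#' generate_sequences(cfg)
#' @export
sim_config <- function(n_per_class = c(pos = 120L, neg = 94L),
                       length_range = c(50L, 100L),
                       planted = NULL,
                       background = rep(1 / 20, 20L),
                       seed = 1L) {
  stopifnot(length(n_per_class) >= 1L, all(n_per_class >= 1L),
            length(length_range) == 2L, length_range[1] >= 3L,
            length_range[2] >= length_range[1],
            length(background) == 20L, all(background >= 0))
  if (abs(sum(background) - 1) > 1e-9) abort("background must sum to 1")
  classes <- names(n_per_class)
  if (is.null(classes)) classes <- paste0("class", seq_along(n_per_class))
  if (is.null(planted)) {
    planted <- .default_planted(classes)
  }
  planted <- as_tibble(planted)
  stopifnot(all(c("class", "pair", "k", "rho") %in% names(planted)))
  if (nrow(planted) > 0L) {
    if (!all(planted$class %in% classes)) {
      abort("planted classes must be among the configured class labels")
    }
    if (any(planted$rho < 1)) abort("enrichment rho must be >= 1")
    dipeptide_index(planted$pair)  # validates pairs
    if (any(planted$k + 2L > length_range[1])) {
      abort("planted gap k too large for the minimum sequence length")
    }
    codes <- do.call(rbind, strsplit(toupper(planted$pair), ""))
    pa <- background[match(codes[, 1], .AA)]
    pb <- background[match(codes[, 2], .AA)]
    if (any((planted$rho - 1) * pa * pb >= 1)) {
      abort("infeasible planting: expected insertions exceed available slots")
    }
  }
  structure(list(n_per_class = setNames(as.integer(n_per_class), classes),
                 length_range = as.integer(length_range),
                 planted = planted,
                 background = as.numeric(background),
                 seed = as.integer(seed)),
            class = "wgdipc_sim_config")
}

# two planted pairs per class at enrichment 10, distinct across classes
.default_planted <- function(classes) {
  pool <- c("AC", "DE", "KL", "VW", "FG", "HI", "MN", "PQ",
            "RS", "TY", "CA", "ED", "LK", "WV", "GF", "IH")
  k_cycle <- c(0L, 1L)
  rows <- purrr::map_dfr(seq_along(classes), function(i) {
    pairs <- pool[((i - 1) * 2) %% length(pool) + 1:2]
    tibble(class = classes[i], pair = pairs, k = k_cycle, rho = 10)
  })
  rows
}

#' @rdname sim_config
#' @param scale divisor applied to the 8-class benchmark counts (default
#'   10); tiny classes keep at least 6 members.
#' @export
sim_config_multiclass <- function(scale = 10, length_range = c(50L, 100L),
                                  seed = 1L) {
  base <- c(type1 = 1054, type2 = 390, type3 = 30, type4 = 56,
            multipass = 4581, lipid_anchor = 189, gpi_anchor = 228,
            peripheral = 1054)
  n <- setNames(pmax(6L, as.integer(round(base / scale))), names(base))
  sim_config(n_per_class = n, length_range = length_range, seed = seed)
}

#' Generate a labeled synthetic sequence set
#'
#' @param cfg a [sim_config()].
#' @return a tibble with columns `id`, `sequence`, `label` (one row per
#'   sequence, classes in configuration order), suitable for
#'   [encode_features()] directly.
#' @export
generate_sequences <- function(cfg) {
  stopifnot(inherits(cfg, "wgdipc_sim_config"))
  classes <- names(cfg$n_per_class)
  withr::with_seed(cfg$seed, {
    out <- purrr::map_dfr(seq_along(classes), function(ci) {
      cl <- classes[ci]
      n_i <- cfg$n_per_class[ci]
      plants <- cfg$planted[cfg$planted$class == cl, , drop = FALSE]
      seqs <- character(n_i)
      for (s in seq_len(n_i)) {
        L <- cfg$length_range[1] +
          sample.int(cfg$length_range[2] - cfg$length_range[1] + 1L, 1L) - 1L
        res <- sample(.AA, L, replace = TRUE, prob = cfg$background)
        if (nrow(plants) > 0L) {
          for (r in seq_len(nrow(plants))) {
            k <- plants$k[r]
            ab <- strsplit(plants$pair[r], "")[[1]]
            pa <- cfg$background[match(ab[1], .AA)]
            pb <- cfg$background[match(ab[2], .AA)]
            slots <- L - k - 1L
            ins <- which(stats::runif(slots) < (plants$rho[r] - 1) * pa * pb)
            for (j in ins) {
              res[j] <- ab[1]
              res[j + 1L + k] <- ab[2]
            }
          }
        }
        seqs[s] <- paste(res, collapse = "")
      }
      tibble(id = sprintf("%s_%04d", cl, seq_len(n_i)),
             sequence = seqs, label = cl)
    })
  })
  out
}

#' Canonical feature indices of the planted pairs
#'
#' Maps each planted `(pair, k)` of a configuration to its column index in
#' the 400-dimensional feature space (gapped pairs share the same
#' 400-name space as adjacent pairs), giving the ground truth for
#' selector-recovery experiments.
#'
#' @param cfg a [sim_config()].
#' @return a tibble with columns `class`, `pair`, `k`, `feature`
#'   (dipeptide name) and `index` (1-400).
#' @export
planted_truth <- function(cfg) {
  stopifnot(inherits(cfg, "wgdipc_sim_config"))
  if (nrow(cfg$planted) == 0L) {
    return(tibble(class = character(), pair = character(), k = integer(),
                  feature = character(), index = integer()))
  }
  idx <- dipeptide_index(cfg$planted$pair)
  tibble(class = cfg$planted$class, pair = cfg$planted$pair,
         k = as.integer(cfg$planted$k),
         feature = .DIPEPTIDES[idx], index = idx)
}
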