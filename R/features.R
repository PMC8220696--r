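#' Count ordered residue pairs at a fixed gap
#'
#' Tallies the 400 ordered dipeptides formed by residue pairs
#' `(q_j, q_{j+1+k})` — i.e. pairs separated by `k` intervening residues —
#' over a single sequence. A sequence of length `n` contributes exactly
#' `n - k - 1` pairs.
#'
#' @param sequence a single amino-acid string over the canonical alphabet.
#' @param k gap size (number of intervening residues); `k = 0` counts
#'   adjacent pairs.
#' @param id optional record id used in error messages.
#' @return a named integer vector of length 400 (canonical dipeptide order)
#'   with attribute `n_pairs`.
#' @examples
#' counts <- count_pairs("ACDE", k = 1)
#' counts[counts > 0]
#' @export
count_pairs <- function(sequence, k = 0L, id = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  k <- .check_gap(k)
  n <- nchar(sequence)
  if (n < k + 2L) {
    who <- if (is.null(id)) "sequence" else paste0("record '", id, "'")
    abort(paste0(who, " too short for gap k = ", k,
                 ": length ", n, " < ", k + 2L))
  }
  codes <- .aa_codes(sequence, id)
  first <- codes[seq_len(n - k - 1L)]
  second <- codes[seq.int(2L + k, n)]
  counts <- tabulate(20L * (first - 1L) + second, nbins = 400L)
  structure(setNames(as.integer(counts), .DIPEPTIDES), n_pairs = n - k - 1L)
}

#' Dipeptide-composition feature encodings
#'
#' `dipc()` is the classical dipeptide composition: the frequency
#' `f(i) / (n - 1)` of each of the 400 ordered adjacent residue pairs.
#' `gdipc()` generalizes it to pairs separated by a gap of `k` residues,
#' normalized by `n - k - 1`; `gdipc(x, 0)` is identical to `dipc(x)`.
#' `w_gdipc()` is the two-term weighted fusion
#' `alpha * DipC + (1 - alpha) * GDipC(1)` and `w_gdipc_general()` the
#' general convex combination `sum_k alpha_k * GDipC(k)` with strictly
#' decreasing non-negative weights summing to one. All encodings are
#' 400-dimensional and sum to one for any valid sequence.
#'
#' @param sequence a single amino-acid string over the canonical alphabet.
#' @param k gap size (`k = 0` for adjacent pairs).
#' @param alpha fusion coefficient in \[0, 1\]: the weight of the adjacent
#'   (gap 0) composition.
#' @param weights numeric vector `(alpha_0, ..., alpha_d)` applied to gaps
#'   `0..d`; must be non-negative, strictly decreasing and sum to 1.
#' @param id optional record id used in error messages.
#' @return a named numeric vector of length 400 in canonical dipeptide
#'   order.
#' @examples
#' v <- w_gdipc("ACDE", alpha = 0.8)
#' v[v > 0]
#' sum(v)
#' @export
dipc <- function(sequence, id = NULL) {
  gdipc(sequence, k = 0L, id = id)
}

#' @rdname dipc
#' @export
gdipc <- function(sequence, k = 0L, id = NULL) {
  counts <- count_pairs(sequence, k = k, id = id)
  v <- as.numeric(counts) / attr(counts, "n_pairs")
  setNames(v, .DIPEPTIDES)
}

#' @rdname dipc
#' @export
w_gdipc <- function(sequence, alpha = 0.8, id = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    abort("`alpha` must be a single number in [0, 1]")
  }
  .check_min_length(sequence, 3L, id)
  if (alpha == 1) return(dipc(sequence, id = id))
  if (alpha == 0) return(gdipc(sequence, k = 1L, id = id))
  alpha * dipc(sequence, id = id) + (1 - alpha) * gdipc(sequence, 1L, id = id)
}

#' @rdname dipc
#' @export
w_gdipc_general <- function(sequence, weights, id = NULL) {
  .check_fusion_weights(weights)
  d <- length(weights) - 1L
  .check_min_length(sequence, d + 2L, id)
  v <- numeric(400L)
  for (k in 0:d) v <- v + weights[k + 1L] * gdipc(sequence, k, id = id)
  setNames(v, .DIPEPTIDES)
}

#' Encode a set of sequences as a W-GDipC feature matrix
#'
#' Applies [w_gdipc()] (or, when `weights` is given, [w_gdipc_general()])
#' to every record and joins class labels by id, producing the tabular
#' dataset consumed by the selectors and the evaluation harness: one row per
#' sequence, an `id` and a `label` column, and 400 feature columns named
#' `AA, AC, ..., YY`.
#'
#' @param records a tibble with columns `id` and `sequence`; a `label`
#'   column, if present, is used when `labels` is `NULL`.
#' @param labels `NULL`, a tibble with columns `id` and `label`, or a named
#'   character vector mapping id to label. Every record must have a label.
#' @param alpha fusion coefficient (weight of the adjacent-pair
#'   composition); ignored when `weights` is supplied.
#' @param weights optional general fusion weights, see [w_gdipc_general()].
#' @return a tibble with columns `id`, `label` and the 400 dipeptide
#'   features, carrying class `wgdipc_features`. The first-seen order of
#'   labels (stored in `attr(, "label_levels")`) defines the integer class
#'   codes used downstream.
#' @examples
#' sims <- generate_sequences(sim_config(n_per_class = c(pos = 5, neg = 5)))
#' feats <- encode_features(sims, alpha = 0.8)
#' dim(feats)
#' @export
encode_features <- function(records, labels = NULL, alpha = 0.8, weights = NULL) {
  has_label_col <- is.data.frame(records) && "label" %in% names(records)
  recs <- .check_records(records)
  if (is.null(labels)) {
    if (!has_label_col) abort("no `labels` given and `records` has no label column")
    lab_tbl <- tibble(id = records$id, label = as.character(records$label))
  } else if (is.data.frame(labels)) {
    lab_tbl <- tibble(id = as.character(labels$id), label = as.character(labels$label))
  } else {
    lab_tbl <- tibble(id = names(labels), label = as.character(unname(labels)))
  }
  dup <- unique(lab_tbl$id[duplicated(lab_tbl$id)])
  if (length(dup) > 0L) abort(paste0("duplicate id(s) in labels: ", paste(dup, collapse = ", ")))
  lab <- lab_tbl$label[match(recs$id, lab_tbl$id)]
  if (anyNA(lab)) {
    abort(paste0("no label for record(s): ",
                 paste(recs$id[is.na(lab)], collapse = ", ")))
  }
  extra <- setdiff(lab_tbl$id, recs$id)
  if (length(extra) > 0L) {
    abort(paste0("label id(s) absent from records: ", paste(extra, collapse = ", ")))
  }
  enc <- function(s, id) {
    if (is.null(weights)) w_gdipc(s, alpha = alpha, id = id)
    else w_gdipc_general(s, weights, id = id)
  }
  mat <- matrix(0, nrow = nrow(recs), ncol = 400L,
                dimnames = list(NULL, .DIPEPTIDES))
  for (i in seq_len(nrow(recs))) mat[i, ] <- enc(recs$sequence[i], recs$id[i])
  out <- dplyr::bind_cols(tibble(id = recs$id, label = lab), as_tibble(mat))
  class(out) <- c("wgdipc_features", class(out))
  attr(out, "label_levels") <- unique(lab)
  attr(out, "alpha") <- if (is.null(weights)) alpha else NA_real_
  attr(out, "weights") <- weights
  out
}

.check_gap <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k != floor(k)) {
    abort("`k` must be a single non-negative integer")
  }
  as.integer(k)
}

.check_min_length <- function(sequence, min_len, id = NULL) {
  n <- nchar(sequence)
  if (n < min_len) {
    who <- if (is.null(id)) "sequence" else paste0("record '", id, "'")
    abort(paste0(who, " too short: length ", n, " < ", min_len))
  }
  invisible(n)
}

.check_fusion_weights <- function(weights) {
  if (!is.numeric(weights) || length(weights) < 1L || anyNA(weights)) {
    abort("`weights` must be a non-empty numeric vector")
  }
  if (any(weights < 0)) abort("fusion weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-12) abort("fusion weights must sum to 1")
  if (length(weights) > 1L && any(diff(weights) >= 0)) {
    abort("fusion weights must be strictly decreasing (alpha_k > alpha_{k+1})")
  }
  invisible(weights)
}
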