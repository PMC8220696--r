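# Canonical residue and dipeptide orderings. All feature indices in the
# package derive from these two constants; changing them would silently
# re-map every encoded dataset, so they are fixed.

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# 400 ordered dipeptides, row-major in the first residue:
# index(ab) = 20 * (idx(a) - 1) + idx(b), i.e. AA, AC, AD, ..., YW, YY.
.DIPEPTIDES <- as.vector(t(outer(.AA, .AA, paste0)))

# byte -> residue index lookup (0 for non-canonical characters)
.AA_CODE <- local({
  z <- integer(256)
  z[utf8ToInt(paste(.AA, collapse = ""))] <- seq_along(.AA)
  z
})

#' Canonical amino-acid and dipeptide orderings
#'
#' The package fixes the 20 standard residues in alphabetical one-letter
#' order (`ACDEFGHIKLMNPQRSTVWY`) and indexes the 400 ordered dipeptides as
#' `20 * (idx(first) - 1) + idx(second)`, giving the column order
#' `AA, AC, AD, ..., YY` used by every feature matrix.
#'
#' @return `aa_alphabet()` returns the 20 residue letters;
#'   `dipeptide_names()` the 400 dipeptide strings in canonical order;
#'   `dipeptide_index()` the integer index (1-400) of each dipeptide in
#'   `pair`.
#' @param pair character vector of two-letter dipeptides (e.g. `"AC"`).
#' @examples
#' dipeptide_index(c("AA", "AC", "YY"))
#' @export
aa_alphabet <- function() .AA

#' @rdname aa_alphabet
#' @export
dipeptide_names <- function() .DIPEPTIDES

#' @rdname aa_alphabet
#' @export
dipeptide_index <- function(pair) {
  i <- match(toupper(pair), .DIPEPTIDES)
  if (anyNA(i)) {
    abort(paste0("not a canonical dipeptide: ",
                 paste(pair[is.na(i)], collapse = ", ")))
  }
  i
}

# residue index vector for one sequence; errors on non-canonical characters
.aa_codes <- function(sequence, id = NULL) {
  codes <- .AA_CODE[utf8ToInt(sequence)]
  if (any(codes == 0L)) {
    bad <- unique(strsplit(sequence, "")[[1]][codes == 0L])
    who <- if (is.null(id)) "sequence" else paste0("record '", id, "'")
    abort(paste0(who, " contains non-standard residue(s): ",
                 paste(bad, collapse = ", ")))
  }
  codes
}
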