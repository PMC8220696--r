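#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a tibble of protein
#' records. Header lines are taken up to the first whitespace as the record
#' id; wrapped sequence bodies are concatenated. Sequences are returned
#' verbatim (no case folding, no alphabet policy) — see
#' [validate_records()].
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id` and `sequence`, one row per FASTA
#'   entry, in file order.
#' @seealso [write_fasta()], [validate_records()]
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACDE", ">b", "MKV"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) abort(paste0("empty FASTA file: ", path))
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(paste0("malformed FASTA: line ", first,
                 " precedes any '>' header in ", path))
  }
  set <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(set) == 0L)) {
    bad <- names(set)[Biostrings::width(set) == 0L]
    abort(paste0("empty sequence body under header(s): ",
                 paste(bad, collapse = ", ")))
  }
  ids <- sub("\\s.*$", "", names(set))
  tibble(id = ids, sequence = as.character(unname(set)))
}

#' Write protein records to a FASTA file
#'
#' @param records a tibble with columns `id` and `sequence` (as returned by
#'   [read_fasta()] or [generate_sequences()]).
#' @param path output file path.
#' @param width line width for wrapping sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  records <- .check_records(records)
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Validate record sequences against the canonical amino-acid alphabet
#'
#' Case-folds sequences to upper case and applies one of two policies for
#' characters outside `ACDEFGHIKLMNPQRSTVWY`: `"strict"` (the default)
#' raises an error naming the record and the offending characters;
#' `"drop_nonstandard"` removes them and emits one warning with the total
#' count removed.
#'
#' @param records a tibble with columns `id` and `sequence`.
#' @param policy `"strict"` or `"drop_nonstandard"`.
#' @return the validated tibble (sequences upper-cased, and filtered under
#'   `drop_nonstandard`). Records left empty after dropping are removed with
#'   a warning.
#' @examples
#' recs <- tibble::tibble(id = "a", sequence = "acde")
#' validate_records(recs)
#' @export
validate_records <- function(records, policy = c("strict", "drop_nonstandard")) {
  policy <- match.arg(policy)
  records <- .check_records(records)
  seqs <- toupper(records$sequence)
  bad <- gsub(paste0("[", paste(.AA, collapse = ""), "]"), "", seqs)
  has_bad <- nzchar(bad)
  if (any(has_bad)) {
    if (policy == "strict") {
      i <- which(has_bad)[1]
      abort(paste0(
        "record '", records$id[i], "' contains non-standard residue(s): ",
        paste(unique(strsplit(bad[i], "")[[1]]), collapse = ", "),
        " (policy = strict)"))
    }
    n_removed <- sum(nchar(bad))
    seqs[has_bad] <- vapply(seqs[has_bad], function(s) {
      chs <- strsplit(s, "")[[1]]
      paste(chs[chs %in% .AA], collapse = "")
    }, character(1))
    warn(paste0("dropped ", n_removed, " non-standard residue(s) from ",
                sum(has_bad), " record(s)"))
  }
  out <- tibble(id = records$id, sequence = seqs)
  empty <- !nzchar(out$sequence)
  if (any(empty)) {
    warn(paste0("removed ", sum(empty),
                " record(s) left empty after dropping residues: ",
                paste(out$id[empty], collapse = ", ")))
    out <- out[!empty, , drop = FALSE]
  }
  out
}

#' Read a two-column id/label table
#'
#' Reads a headerless delimited text file whose first column is the sequence
#' id and second column the class label. The delimiter is sniffed (tab,
#' comma or semicolon) unless given. Labels are kept as opaque strings;
#' integer class codes are assigned downstream in first-seen order.
#'
#' @param path path to the label table.
#' @param delim field delimiter, or `NULL` to sniff.
#' @return a tibble with columns `id` and `label`.
#' @export
read_labels <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) ","
             else if (grepl(";", first)) ";" else "\t"
  }
  tab <- readr::read_delim(path, delim = delim, col_names = FALSE,
                           comment = "#", col_types = readr::cols(.default = "c"),
                           trim_ws = TRUE, progress = FALSE)
  if (ncol(tab) < 2L) abort("label table must have at least two columns (id, label)")
  out <- tibble(id = tab[[1]], label = tab[[2]])
  dup <- unique(out$id[duplicated(out$id)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate id(s) in label table: ", paste(dup, collapse = ", ")))
  }
  out
}

.check_records <- function(records) {
  if (!is.data.frame(records) || !all(c("id", "sequence") %in% names(records))) {
    abort("`records` must be a data frame with columns `id` and `sequence`")
  }
  as_tibble(records[, c("id", "sequence")])
}
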