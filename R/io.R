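#' Read a sequence set from FASTA or plain text
#'
#' FASTA files (first non-blank character `>`) are parsed with Biostrings;
#' plain files are read one sequence per line (ids `seq1`, `seq2`, ...).
#' Sequences are uppercased; the gap character inside an input sequence is
#' an error (gaps belong to alignments, not sequences).
#'
#' @param path Input file.
#' @param alphabet Optional declared [alphabet()]; inferred when omitted.
#' @param format `"auto"` (default), `"fasta"` or `"plain"`.
#' @return A [seq_set()].
#' @export
read_sequences <- function(path, alphabet = NULL, format = c("auto", "fasta", "plain")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("Empty sequence file.")
  if (format == "auto") {
    format <- if (startsWith(trimws(lines[1]), ">")) "fasta" else "plain"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    seqs <- as.character(ss)
  } else {
    ids <- paste0("seq", seq_along(lines))
    seqs <- trimws(lines)
  }
  seq_set(tibble(id = ids, seq = seqs), alphabet = alphabet)
}

#' Read a multiple alignment from aligned FASTA
#'
#' Rows must have equal length; gaps are allowed (and typographic dashes
#' normalized). The rows are scored exactly as given — all-gap columns are
#' *not* dropped automatically; use [normalize_alignment()] for the
#' canonical form.
#'
#' @param path Aligned FASTA file.
#' @param alphabet Optional declared [alphabet()].
#' @return An [as_alignment()]; its source set is available through
#'   [alignment_source()].
#' @export
read_aligned <- function(path, alphabet = NULL) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) abort("Empty alignment file.")
  ids <- sub("\\s.*$", "", names(ss))
  as_alignment(setNames(as.character(ss), ids), alphabet = alphabet)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln An [as_alignment()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned <- function(aln, path) {
  aln <- as_alignment(aln)
  ss <- Biostrings::BStringSet(setNames(aln$aligned, aln$id))
  Biostrings::writeXStringSet(ss, path, width = 20000L)
  invisible(path)
}
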