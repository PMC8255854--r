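#' Build an alignment from aligned rows
#'
#' An alignment of a sequence set is a k-by-l character matrix over the
#' alphabet plus the gap character: every row, once its gaps are removed,
#' equals its source sequence exactly. It is held as a tibble with columns
#' `id` and `aligned`.
#'
#' @param x Aligned rows: a character vector (optionally named), a data
#'   frame with columns `id` and `aligned`, or a character matrix with one
#'   row per sequence.
#' @param source Optional [seq_set()] the rows must de-gap to; when omitted
#'   the source is derived by removing gaps.
#' @param alphabet Optional [alphabet()] declaration.
#' @return A tibble of class `"msa_alignment"` with columns `id`,
#'   `aligned`, and attributes `alphabet` and `n_col`.
#' @examples
#' as_alignment(c("CCG-", "GCG-", "-CGC"))
#' @export
as_alignment <- function(x, source = NULL, alphabet = NULL) {
  if (inherits(x, "msa_alignment") && is.null(source) && is.null(alphabet)) {
    return(x)
  }
  if (is.matrix(x) && is.character(x)) {
    x <- apply(x, 1, paste, collapse = "")
  }
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    x <- tibble(id = ids, aligned = unname(x))
  }
  if (!is.data.frame(x)) {
    abort("`x` must be aligned rows: character vector, matrix or data frame.")
  }
  x <- as_tibble(x)
  if (!"aligned" %in% names(x)) abort("`x` must have an `aligned` column.")
  if (!"id" %in% names(x)) x$id <- paste0("seq", seq_len(nrow(x)))
  x <- x[c("id", "aligned")]
  x$id <- as.character(x$id)
  x$aligned <- toupper(normalize_gaps(as.character(x$aligned)))
  if (nrow(x) == 0) abort("An alignment needs at least one row.")
  if (anyDuplicated(x$id)) abort("Alignment row ids must be unique.")
  lens <- nchar(x$aligned)
  if (length(unique(lens)) != 1) {
    abort("All aligned rows must have the same length.")
  }
  degapped <- gsub(gap_char(), "", x$aligned, fixed = TRUE)
  if (any(nchar(degapped) == 0)) {
    abort("An aligned row may not consist solely of gaps (its source sequence would be empty).")
  }
  if (!is.null(source)) {
    source <- seq_set(source)
    if (nrow(source) != nrow(x) || !identical(degapped, source$seq)) {
      abort("Aligned rows with gaps removed must equal the source sequences, in order.")
    }
    alphabet <- alphabet %||% seqset_alphabet(source)
  }
  src <- seq_set(tibble(id = x$id, seq = degapped), alphabet = alphabet)
  structure(x,
    alphabet = seqset_alphabet(src),
    n_col = lens[1],
    class = c("msa_alignment", class(tibble())))
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat("<alignment> ", nrow(x), " x ", attr(x, "n_col"), "\n", sep = "")
  cat(paste0("  ", format(x$id), "  ", x$aligned, collapse = "\n"), "\n")
  invisible(x)
}

#' The aligned character matrix of an alignment
#'
#' @param aln An [as_alignment()] object.
#' @return A k-by-l character matrix, rownames the sequence ids.
#' @export
alignment_matrix <- function(aln) {
  aln <- as_alignment(aln)
  m <- do.call(rbind, split_chars(aln$aligned))
  rownames(m) <- aln$id
  m
}

#' The source sequence set of an alignment
#'
#' @param aln An [as_alignment()] object.
#' @return The [seq_set()] obtained by removing every gap from each row.
#' @export
alignment_source <- function(aln) {
  aln <- as_alignment(aln)
  seq_set(tibble(id = aln$id, seq = gsub(gap_char(), "", aln$aligned, fixed = TRUE)),
    alphabet = attr(aln, "alphabet"))
}

#' The trivial (gapless) alignment of an equal-length sequence set
#'
#' Writes the sequences under one another without inserting any gaps. It is
#' only defined when all sequences share one length; unequal lengths raise
#' an error rather than being silently padded.
#'
#' @param seqs A [seq_set()] (or anything [seq_set()] accepts) of
#'   equal-length sequences.
#' @return An [as_alignment()] with zero gaps.
#' @examples
#' trivial_alignment(c("CG", "GC", "GG"))
#' @export
trivial_alignment <- function(seqs) {
  seqs <- seq_set(seqs)
  lens <- nchar(seqs$seq)
  if (length(unique(lens)) != 1) {
    abort("The trivial alignment is only defined for equal-length sequences.")
  }
  as_alignment(tibble(id = seqs$id, aligned = seqs$seq),
    source = seqs)
}

#' Drop all-gap columns from an alignment
#'
#' All-gap columns cost nothing (d(-, -) = 0 for every valid scheme), so
#' the canonical form of an alignment removes them. Costs are unchanged and
#' every row still de-gaps to its source sequence.
#'
#' @param aln An [as_alignment()] object.
#' @return The canonical alignment; idempotent.
#' @export
normalize_alignment <- function(aln) {
  aln <- as_alignment(aln)
  m <- alignment_matrix(aln)
  keep <- colSums(m != gap_char()) > 0
  if (all(keep)) return(aln)
  as_alignment(m[, keep, drop = FALSE], alphabet = attr(aln, "alphabet"))
}
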