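#' Build a sequence set
#'
#' A sequence set is an ordered multiset of sequences over one alphabet,
#' held as a tibble with columns `id` and `seq`. Duplicate sequence content
#' is allowed (identical sequences are aligned identically in any optimal
#' alignment and contribute zero cost to each other); duplicate ids are not.
#'
#' @param x A character vector of sequences, or a data frame with columns
#'   `id` and `seq`. Sequences are uppercased; the gap character is rejected.
#' @param alphabet Optional [alphabet()]. Inferred from the sequences when
#'   omitted; when given, every character must belong to it.
#' @param ids Optional character vector of ids for a character-vector `x`
#'   (defaults to `seq1`, `seq2`, ...).
#' @return A tibble of class `"seq_set"` with columns `id`, `seq` and an
#'   `alphabet` attribute.
#' @examples
#' seq_set(c("CCG", "GCG", "CGC"))
#' @export
seq_set <- function(x, alphabet = NULL, ids = NULL) {
  if (inherits(x, "seq_set") && is.null(alphabet) && is.null(ids)) {
    return(x)
  }
  if (is.character(x)) {
    ids <- ids %||% names(x) %||% paste0("seq", seq_along(x))
    x <- tibble(id = ids, seq = unname(x))
  }
  if (!is.data.frame(x)) {
    abort("`x` must be a character vector or a data frame with columns `id` and `seq`.")
  }
  x <- as_tibble(x)
  if (!"seq" %in% names(x)) {
    abort("`x` must have a `seq` column.")
  }
  if (!"id" %in% names(x)) {
    x$id <- ids %||% paste0("seq", seq_len(nrow(x)))
  }
  x <- x[c("id", "seq")]
  x$id <- as.character(x$id)
  x$seq <- toupper(normalize_gaps(as.character(x$seq)))
  if (nrow(x) == 0) abort("A sequence set must contain at least one sequence.")
  if (anyDuplicated(x$id)) abort("Sequence ids must be unique.")
  if (any(nchar(x$seq) == 0)) abort("Empty sequences are not allowed.")
  if (any(grepl(gap_char(), x$seq, fixed = TRUE))) {
    abort("Input sequences may not contain the reserved gap character \"-\".")
  }
  seen <- infer_alphabet(x$seq)
  if (is.null(alphabet)) {
    alphabet <- seen
  } else {
    alphabet <- as_alphabet(alphabet)
    extra <- setdiff(unclass(seen), unclass(alphabet))
    if (length(extra)) {
      abort(paste0(
        "Sequences contain symbols outside the declared alphabet: ",
        paste(extra, collapse = ", ")
      ))
    }
  }
  structure(x,
    alphabet = alphabet,
    class = c("seq_set", class(tibble())))
}

#' @export
print.seq_set <- function(x, ...) {
  ab <- attr(x, "alphabet")
  cat("<seq_set> ", nrow(x), " sequence(s) over {",
    paste(unclass(ab), collapse = ", "), "}\n", sep = "")
  print(as_tibble(unclass_seqset(x)), ...)
  invisible(x)
}

unclass_seqset <- function(x) {
  class(x) <- setdiff(class(x), "seq_set")
  attr(x, "alphabet") <- NULL
  x
}

seqset_alphabet <- function(x) attr(x, "alphabet")

`%||%` <- function(a, b) if (is.null(a)) b else a
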