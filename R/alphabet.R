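#' The reserved gap character
#'
#' Alignments use the ASCII hyphen `"-"` as the gap symbol. The typographic
#' dashes that sometimes appear in printed matrices (en dash, em dash, minus
#' sign) are normalized to it on input.
#'
#' @return A single character, `"-"`.
#' @export
gap_char <- function() "-"

# en dash, em dash, unicode minus, figure dash -> ASCII hyphen
normalize_gaps <- function(x) {
  gsub("[‐‒–—−]", "-", x)
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)

#' Declare a finite alphabet
#'
#' An alphabet is an ordered set of unique single characters over which
#' sequences are written. The gap character is reserved for alignments and
#' may not be a member.
#'
#' @param symbols Character vector of single characters (lowercase is
#'   uppercased).
#' @return A character vector of class `"msa_alphabet"`.
#' @examples
#' alphabet(c("C", "G"))
#' @export
alphabet <- function(symbols) {
  symbols <- toupper(normalize_gaps(as.character(symbols)))
  if (length(symbols) == 0) {
    abort("An alphabet must contain at least one symbol.")
  }
  if (any(nchar(symbols) != 1)) {
    abort("Alphabet symbols must be single characters.")
  }
  if (anyDuplicated(symbols)) {
    abort("Alphabet symbols must be unique.")
  }
  if (gap_char() %in% symbols) {
    abort("The gap character \"-\" is reserved and cannot be an alphabet symbol.")
  }
  structure(symbols, class = "msa_alphabet")
}

#' @export
print.msa_alphabet <- function(x, ...) {
  cat("<alphabet> {", paste(unclass(x), collapse = ", "), "}\n")
  invisible(x)
}

as_alphabet <- function(x) {
  if (inherits(x, "msa_alphabet")) x else alphabet(x)
}

infer_alphabet <- function(seqs) {
  alphabet(sort(unique(unlist(split_chars(seqs)))))
}
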