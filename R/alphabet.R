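# Internal nucleotide-alphabet helpers. All module code works on RNA
# (T -> U on input); the DNA/RNA origin of each record is remembered so
# writers can round-trip the original alphabet.

RNA_ALPHABET <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to uppercase RNA
#'
#' Uppercases and converts T to U. Idempotent.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over \code{A,C,G,U,N}.
#' @examples
#' rna_normalize(c("acgt", "ACGU"))
#' @export
rna_normalize <- function(x) {
  chartr("Tt", "Uu", toupper(chartr("t", "T", x)))
}

#' Reverse complement of RNA sequences
#'
#' @param x character vector of RNA sequences (A/C/G/U, N allowed).
#' @return character vector of reverse complements, RNA alphabet.
#' @examples
#' rna_revcomp("UGAGG")
#' @export
rna_revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(x)))
}

# Stop unless sequences use the strict RNA alphabet (no N).
assert_rna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,U}: %s",
                 what, x[which(bad)[1L]]), call. = FALSE)
  }
  invisible(x)
}
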