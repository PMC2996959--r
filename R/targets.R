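# targets: miRNA target prediction by ungapped antiparallel
# complementarity with a mismatch budget; G:U wobbles are scored as
# pairings, not mismatches (they are drawn as pairing circles in cleavage
# diagrams), unless the caller opts to count them toward the budget.

#' Classify a base combination in an antiparallel duplex
#'
#' @param a miRNA nucleotide(s), `{A,C,G,U}`.
#' @param b site nucleotide(s) opposite `a`.
#' @return character vector in `{watson_crick, wobble, mismatch}`.
#' @examples
#' pair_class("G", "U")
#' @export
pair_class <- function(a, b) {
  assert_rna(a, "pair_class 'a'")
  assert_rna(b, "pair_class 'b'")
  p <- paste0(a, b)
  out <- rep("mismatch", length(p))
  out[p %in% c("AU", "UA", "GC", "CG")] <- "watson_crick"
  out[p %in% c("GU", "UG")] <- "wobble"
  out
}

#' Count mismatches and wobbles in a miRNA:site duplex
#'
#' The miRNA (5'->3') is aligned antiparallel to the site (5'->3'): miRNA
#' position i faces site position L+1-i. Watson-Crick and wobble pairs and
#' mismatches partition the positions; wobbles are reported separately and
#' are not counted as mismatches.
#'
#' @param mirna,site equal-length RNA strings, both 5'->3'.
#' @return list with integer elements `mismatches`, `wobbles`,
#'   `watson_crick`.
#' @examples
#' count_mismatches("UUAAGAUUGAGUUACCAUCAU", "AUGAUGGUAACUCAAUCUUAA")
#' @export
count_mismatches <- function(mirna, site) {
  stopifnot(is.character(mirna), is.character(site),
            length(mirna) == 1L, length(site) == 1L)
  if (nchar(mirna) != nchar(site)) {
    stop("count_mismatches: miRNA and site must have equal length",
         call. = FALSE)
  }
  a <- strsplit(mirna, "")[[1]]
  b <- rev(strsplit(site, "")[[1]])
  cls <- pair_class(a, b)
  list(mismatches = sum(cls == "mismatch"),
       wobbles = sum(cls == "wobble"),
       watson_crick = sum(cls == "watson_crick"))
}

#' Render a miRNA:site duplex as text
#'
#' Three lines in the conventional cleavage-diagram layout: site 5'->3' on
#' top, pairing symbols (`|` Watson-Crick, `o` wobble, space mismatch),
#' miRNA 3'->5' below.
#'
#' @inheritParams count_mismatches
#' @return single string with embedded newlines.
#' @export
render_duplex <- function(mirna, site) {
  a <- strsplit(mirna, "")[[1]]
  b <- rev(strsplit(site, "")[[1]])
  sym <- c(watson_crick = "|", wobble = "o", mismatch = " ")[pair_class(a, b)]
  paste0("5' ", site, " 3'\n",
         "   ", paste(rev(sym), collapse = ""), "\n",
         "3' ", paste(rev(a), collapse = ""), " 5'")
}

#' Scan transcripts for miRNA-complementary target sites
#'
#' Slides a window of miRNA length over each transcript (given orientation
#' only, unless `scan_revcomp`) and reports windows whose antiparallel
#' duplex with the miRNA has at most `max_mismatch` mismatches (and, if
#' set, at most `max_wobble` wobbles). The default budget of 3 is the
#' strict reading of a "fewer than four mismatches" rule.
#'
#' @param mirna RNA string, 18-25 nt.
#' @param transcripts data.frame with columns `id`, `seq`.
#' @param max_mismatch maximum mismatch count (default 3).
#' @param max_wobble optional maximum wobble count (default `Inf`).
#' @param scan_revcomp also scan the reverse complement of each transcript
#'   (for unoriented ESTs); hit coordinates then refer to the reverse
#'   complement and `strand` is `-`.
#' @return data.frame with columns `mirna_seq`, `transcript_id`, `strand`,
#'   `site_start`, `site_end` (1-based inclusive), `site_seq` (5'->3'),
#'   `mismatches`, `wobbles`; sorted by (mismatches, transcript_id,
#'   site_start).
#' @export
scan_targets <- function(mirna, transcripts, max_mismatch = 3L,
                         max_wobble = Inf, scan_revcomp = FALSE) {
  stopifnot(nchar(mirna) >= 18L, nchar(mirna) <= 25L)
  assert_rna(mirna, "scan_targets miRNA")
  L <- nchar(mirna)
  a <- strsplit(mirna, "")[[1]]
  hits <- list()
  scan_one <- function(tid, tseq, strand) {
    n <- nchar(tseq)
    if (n < L) return(NULL)
    chars <- strsplit(tseq, "")[[1]]
    # pair class of miRNA nt i against each transcript character
    res <- vector("list", n - L + 1L)
    for (s in seq_len(n - L + 1L)) {
      b <- chars[(s + L - 1L):s]             # site read 3'->5' against miRNA
      cls <- pair_class(a, b)
      mm <- sum(cls == "mismatch")
      wb <- sum(cls == "wobble")
      if (mm <= max_mismatch && wb <= max_wobble) {
        res[[s]] <- data.frame(
          mirna_seq = mirna, transcript_id = tid, strand = strand,
          site_start = s, site_end = s + L - 1L,
          site_seq = substr(tseq, s, s + L - 1L),
          mismatches = mm, wobbles = wb, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, res[!vapply(res, is.null, TRUE)])
  }
  for (r in seq_len(nrow(transcripts))) {
    hits[[length(hits) + 1L]] <-
      scan_one(transcripts$id[r], transcripts$seq[r], "+")
    if (scan_revcomp) {
      hits[[length(hits) + 1L]] <-
        scan_one(transcripts$id[r], rna_revcomp(transcripts$seq[r]), "-")
    }
  }
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (length(hits) == 0L) {
    return(data.frame(mirna_seq = character(0), transcript_id = character(0),
                      strand = character(0), site_start = integer(0),
                      site_end = integer(0), site_seq = character(0),
                      mismatches = integer(0), wobbles = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$mismatches, out$transcript_id, out$site_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
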