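# conserved: identify conserved miRNAs by perfect match to a known mature
# set, group them into miR<number> families, profile family abundance.

#' Match reads against a known mature miRNA set
#'
#' A read matches iff its sequence is identical (same length, same
#' sequence) to a known mature sequence -- the strict reading of
#' "perfect match" conserved-miRNA identification. An optional 3' trim
#' tolerance admits reads shorter by up to `allow_3p_trim` nt at the 3'
#' end, since sRNA libraries commonly contain 3'-trimmed isoforms
#' (default 0: strict).
#'
#' @param reads collapsed reads data.frame (`seq`, `count`).
#' @param known data.frame of known matures with columns `name`
#'   (miRBase-style identifier) and `seq` (RNA, 18-26 nt).
#' @param allow_3p_trim non-negative integer, maximum 3' shortening.
#' @return data.frame with one row per (read, known entry) pair: columns
#'   `seq`, `count`, `name`, `known_seq`, `family`.
#' @export
match_known <- function(reads, known, allow_3p_trim = 0L) {
  stopifnot(nrow(known) > 0L, all(c("name", "seq") %in% names(known)))
  known <- data.frame(name = known$name, known_seq = rna_normalize(known$seq),
                      stringsAsFactors = FALSE)
  known <- unique(known)
  out <- merge(reads[, c("seq", "count")],
               data.frame(seq = known$known_seq, name = known$name,
                          known_seq = known$known_seq,
                          stringsAsFactors = FALSE),
               by = "seq")
  if (allow_3p_trim > 0L) {
    for (d in seq_len(allow_3p_trim)) {
      trimmed <- data.frame(seq = substr(known$known_seq, 1L,
                                         nchar(known$known_seq) - d),
                            name = known$name, known_seq = known$known_seq,
                            stringsAsFactors = FALSE)
      extra <- merge(reads[, c("seq", "count")], trimmed, by = "seq")
      out <- rbind(out, extra)
    }
    out <- unique(out)
  }
  if (nrow(out) > 0L) out$family <- assign_family(out$name)
  else out$family <- character(0)
  out <- out[order(out$seq, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the family token from a miRBase-style name
#'
#' Strips species prefix and letter/variant suffixes: `ath-miR156a` and
#' `ptc-miR156b-5p` both map to `miR156`.
#'
#' @param name character vector of miRNA names containing a `miR<number>`
#'   token.
#' @return character vector of family tokens (`miR` + leading integer).
#' @export
assign_family <- function(name) {
  m <- regexpr("miR[0-9]+", name)
  if (any(m < 0L)) {
    stop(sprintf("assign_family: no miR<number> token in '%s'",
                 name[m < 0L][1L]), call. = FALSE)
  }
  regmatches(name, m)
}

#' Abundance profile of conserved miRNA families
#'
#' Per family: number of distinct matched read sequences, summed redundant
#' counts and the fraction of all conserved redundant counts; sorted by
#' descending redundant reads. Fractions across families sum to 1. A read
#' matching several same-family entries is counted once toward the family.
#'
#' @param matches output of [match_known()], non-empty.
#' @return data.frame with columns `family`, `member_count`,
#'   `redundant_reads`, `fraction_of_conserved`.
#' @export
family_abundance <- function(matches) {
  stopifnot(nrow(matches) > 0L)
  # one row per (family, read sequence): duplicate known entries collapse
  u <- unique(matches[, c("family", "seq", "count")])
  fam <- split(u, u$family)
  out <- data.frame(
    family = names(fam),
    member_count = vapply(fam, function(d) length(unique(d$seq)), 0L),
    redundant_reads = vapply(fam, function(d) sum(d$count), 0),
    stringsAsFactors = FALSE
  )
  out$fraction_of_conserved <- out$redundant_reads / sum(out$redundant_reads)
  out <- out[order(-out$redundant_reads, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}
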