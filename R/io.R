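# smallrna_io: readers/writers for the sequence and tabular formats the
# other stages consume. Sequences are held internally as RNA; the original
# alphabet (DNA vs RNA) is recorded per file so writers can round-trip it.

# Light structural validation of a FASTA file so parse errors can name a
# line number; actual parsing is delegated to Biostrings.
validate_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    stop(sprintf("FASTA parse error in '%s': file is empty", path), call. = FALSE)
  }
  if (!startsWith(lines[nonblank[1L]], ">")) {
    stop(sprintf("FASTA parse error in '%s' at line %d: expected '>' header",
                 path, nonblank[1L]), call. = FALSE)
  }
  is_header <- startsWith(lines, ">")
  for (i in which(is_header)) {
    nxt <- if (i < length(lines)) lines[i + 1L] else ""
    if (!nzchar(trimws(nxt)) || startsWith(nxt, ">")) {
      stop(sprintf("FASTA parse error in '%s' at line %d: header '%s' has no sequence",
                   path, i, lines[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read sequence records from FASTA or FASTQ
#'
#' Records are returned in file order with sequences uppercased and
#' normalized to RNA (T converted to U). Whether the original record used
#' the DNA alphabet is recorded in the `dna` column so that
#' [write_sequences()] can round-trip the file. FASTQ qualities are ignored.
#'
#' @param path path to an existing FASTA or FASTQ file.
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return data.frame with columns `id` (header up to first whitespace),
#'   `seq` (RNA, uppercase) and `dna` (logical: original record contained T).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  if (format == "fasta") validate_fasta_lines(path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) {
      stop(sprintf("%s parse error in '%s': %s", toupper(format), path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  raw <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate record id '%s' in '%s'",
                 ids[anyDuplicated(ids)], path), call. = FALSE)
  }
  out <- data.frame(
    id = ids,
    seq = rna_normalize(raw),
    dna = grepl("T", raw, fixed = TRUE),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$seq))) {
    stop(sprintf("empty sequence for record '%s' in '%s'",
                 out$id[!nzchar(out$seq)][1L], path), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write sequence records to FASTA
#'
#' Records whose `dna` flag is set are written back in the DNA alphabet
#' (U converted to T); others are written as RNA.
#'
#' @param records data.frame with columns `id`, `seq` and optionally `dna`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  dna <- if ("dna" %in% names(records)) records$dna else rep(FALSE, nrow(records))
  seqs <- ifelse(dna, chartr("U", "T", records$seq), records$seq)
  writeLines(as.vector(rbind(paste0(">", records$id), seqs)), path)
  invisible(path)
}

#' Read a collapsed small-RNA FASTA
#'
#' The collapsed dialect stores the redundant read count as a header suffix,
#' `>id_count` (e.g. `>sr1_42`): one record per distinct read sequence.
#'
#' @param path path to a collapsed FASTA file.
#' @return data.frame with columns `id`, `seq` (RNA) and `count` (integer
#'   >= 1), one row per unique sequence.
#' @export
read_collapsed_fasta <- function(path) {
  recs <- read_sequences(path, "fasta")
  m <- regmatches(recs$id, regexec("^(.*)_([0-9]+)$", recs$id))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop(sprintf("collapsed FASTA format error in '%s': header '%s' lacks a '_<count>' suffix",
                 path, recs$id[bad][1L]), call. = FALSE)
  }
  counts <- as.integer(vapply(m, `[`, "", 3L))
  if (any(counts < 1L)) {
    stop(sprintf("collapsed FASTA format error in '%s': count must be >= 1 (header '%s')",
                 path, recs$id[counts < 1L][1L]), call. = FALSE)
  }
  if (anyDuplicated(recs$seq)) {
    stop(sprintf("collapsed FASTA validation error in '%s': duplicate sequence '%s'",
                 path, recs$seq[anyDuplicated(recs$seq)]), call. = FALSE)
  }
  data.frame(
    id = vapply(m, `[`, "", 2L),
    seq = recs$seq,
    count = counts,
    stringsAsFactors = FALSE
  )
}

#' Write a collapsed small-RNA FASTA
#'
#' @param reads data.frame with columns `seq` and `count` (and optionally
#'   `id`; ids default to `sr1`, `sr2`, ...).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(reads, path) {
  stopifnot(all(c("seq", "count") %in% names(reads)))
  if (anyDuplicated(reads$seq)) {
    stop("collapsed set contains duplicate sequences", call. = FALSE)
  }
  ids <- if ("id" %in% names(reads)) reads$id else paste0("sr", seq_len(nrow(reads)))
  writeLines(as.vector(rbind(paste0(">", ids, "_", reads$count), reads$seq)), path)
  invisible(path)
}

#' Write a data frame as a tab-separated table
#'
#' Tab-separated UTF-8 with a header row and the data frame's column order;
#' no quoting, no row names, so round-trips preserve cell strings.
#'
#' @param rows data.frame to write (zero rows allowed: header-only file).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-separated table written by [write_table()]
#'
#' @param path input path.
#' @param colClasses passed to [utils::read.delim()]; default keeps all
#'   cells as character strings for exact round-trips.
#' @return data.frame.
#' @export
read_table <- function(path, colClasses = "character") {
  utils::read.delim(path, sep = "\t", colClasses = colClasses,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
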