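# preprocess: collapse raw reads, apply the 18-30 nt size window and
# compute per-length unique/redundant statistics.

#' Collapse raw reads into unique sequences with redundant counts
#'
#' One output row per distinct sequence, with `count` equal to the number of
#' raw occurrences (or the sum of incoming counts if the input is already
#' collapsed, which makes the operation idempotent). Output is sorted by
#' descending count, ties broken lexicographically by sequence, so
#' downstream files are reproducible.
#'
#' @param raw data.frame with a `seq` column; an optional `count` column is
#'   summed (absent counts are taken as 1 per row).
#' @return data.frame with columns `id` (`sr1`, `sr2`, ... in sort order),
#'   `seq`, `count`.
#' @export
collapse_reads <- function(raw) {
  stopifnot("seq" %in% names(raw))
  counts <- if ("count" %in% names(raw)) raw$count else rep(1L, nrow(raw))
  if (nrow(raw) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  tab <- tapply(counts, raw$seq, sum)
  out <- data.frame(seq = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  out <- data.frame(id = paste0("sr", seq_len(nrow(out))),
                    seq = out$seq, count = out$count,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Partition reads by length window
#'
#' Keeps reads whose length is within `[min_len, max_len]` inclusive;
#' the two returned sets partition the input.
#'
#' @param reads data.frame with a `seq` column.
#' @param min_len,max_len inclusive length bounds (defaults 18 and 30 nt,
#'   the size window retained after adapter removal in plant sRNA surveys).
#' @return list with elements `kept` and `discarded`, both data.frames.
#' @export
filter_by_length <- function(reads, min_len = 18L, max_len = 30L) {
  stopifnot(min_len <= max_len)
  len <- nchar(reads$seq)
  keep <- len >= min_len & len <= max_len
  list(
    kept = {x <- reads[keep, , drop = FALSE]; rownames(x) <- NULL; x},
    discarded = {x <- reads[!keep, , drop = FALSE]; rownames(x) <- NULL; x}
  )
}

#' Per-length unique/redundant read statistics
#'
#' For each length in `[min_len, max_len]` reports the number of unique
#' sequences, the summed redundant count and the redundancy ratio
#' (redundant / unique; NA when no reads of that length exist).
#'
#' @param reads collapsed reads data.frame (`seq`, `count`), all within the
#'   length window.
#' @inheritParams filter_by_length
#' @return data.frame with columns `length`, `unique_count`,
#'   `redundant_count`, `redundancy_ratio`.
#' @export
length_distribution <- function(reads, min_len = 18L, max_len = 30L) {
  stopifnot(all(c("seq", "count") %in% names(reads)))
  len <- nchar(reads$seq)
  if (any(len < min_len | len > max_len)) {
    stop(sprintf("length_distribution: read length outside [%d,%d]",
                 min_len, max_len), call. = FALSE)
  }
  lengths <- min_len:max_len
  uc <- vapply(lengths, function(L) sum(len == L), 0L)
  rc <- vapply(lengths, function(L) sum(reads$count[len == L]), 0)
  data.frame(
    length = lengths,
    unique_count = uc,
    redundant_count = as.integer(rc),
    redundancy_ratio = ifelse(uc > 0L, rc / uc, NA_real_)
  )
}
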