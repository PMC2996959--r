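# annotate: partition collapsed reads into ncRNA classes by priority-ordered
# reference matching, flag polyA artifacts, pass un-annotated reads on.

#' Annotation class labels
#'
#' The fixed, exhaustive label set used to partition a library. Reference
#' matching only ever assigns the first seven; `known_miRNA` and
#' `novel_candidate` are assigned by the conserved and novel stages.
#' @export
ANNOTATION_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "exon", "intron",
                        "repeat", "known_miRNA", "novel_candidate",
                        "unannotated", "polyA_artifact")

# Classes a reference index may carry.
REFERENCE_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "exon", "intron",
                       "repeat")

#' Default annotation priority
#'
#' Follows the usual removal order of plant sRNA annotation (structural
#' RNAs first); configurable because published pipelines disagree on it.
#' @export
DEFAULT_PRIORITY <- REFERENCE_CLASSES

#' Build a per-class reference index for read annotation
#'
#' Supports exact substring membership queries per class against both each
#' reference sequence and its reverse complement (the strand convention of
#' Rfam-style reference sets is not guaranteed).
#'
#' @param class_refs named list: class label -> either a FASTA path or a
#'   data.frame of sequences (`seq` column) / character vector. May be
#'   empty, in which case every read is unannotated.
#' @return object of class `annotation_index`.
#' @export
build_reference_index <- function(class_refs = list()) {
  labs <- names(class_refs)
  if (length(class_refs) > 0L && (is.null(labs) || any(!nzchar(labs)))) {
    stop("build_reference_index: class_refs must be a named list", call. = FALSE)
  }
  unknown <- setdiff(labs, REFERENCE_CLASSES)
  if (length(unknown) > 0L) {
    stop(sprintf("build_reference_index: unknown annotation class '%s'",
                 unknown[1L]), call. = FALSE)
  }
  idx <- lapply(class_refs, function(x) {
    seqs <- if (is.character(x) && length(x) == 1L && file.exists(x)) {
      read_sequences(x)$seq
    } else if (is.data.frame(x)) {
      x$seq
    } else {
      as.character(x)
    }
    seqs <- rna_normalize(seqs)
    unique(c(seqs, rna_revcomp(seqs)))
  })
  structure(idx, class = "annotation_index")
}

#' Is a read a polyA artifact?
#'
#' True iff the A fraction is at least `min_frac` or the read ends in a run
#' of at least `min_tail` consecutive A. Thresholds are the package's
#' defaults (the upstream filtering prose gives none).
#'
#' @param seq character vector of RNA reads.
#' @param min_frac minimum overall A fraction (default 0.9).
#' @param min_tail minimum 3'-terminal A-run length (default 10).
#' @return logical vector.
#' @export
is_polyA_artifact <- function(seq, min_frac = 0.9, min_tail = 10L) {
  n_a <- nchar(seq) - nchar(gsub("A", "", seq, fixed = TRUE))
  frac <- ifelse(nchar(seq) > 0L, n_a / nchar(seq), 0)
  frac >= min_frac | grepl(sprintf("A{%d}$", min_tail), seq)
}

#' Classify reads into annotation classes
#'
#' The polyA-artifact test is applied first; otherwise a read receives the
#' first class in `priority` order whose reference set contains it as an
#' exact, ungapped, full-read substring (either orientation), and
#' `unannotated` if none does. Classification of a read depends only on the
#' read and the index, so it is stable under permutation of the input.
#'
#' @param reads data.frame with a `seq` column (or a character vector).
#' @param index an `annotation_index` from [build_reference_index()].
#' @param priority ordered subset of the index's classes.
#' @param polyA_min_frac,polyA_min_tail polyA thresholds, see
#'   [is_polyA_artifact()].
#' @return character vector of class labels, one per read.
#' @export
classify_reads <- function(reads, index, priority = DEFAULT_PRIORITY,
                           polyA_min_frac = 0.9, polyA_min_tail = 10L) {
  stopifnot(inherits(index, "annotation_index"))
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  priority <- priority[priority %in% names(index)]
  if (length(setdiff(priority, names(index))) > 0L) {
    stop("classify_reads: priority lists a class absent from the index",
         call. = FALSE)
  }
  out <- rep("unannotated", length(seqs))
  pa <- is_polyA_artifact(seqs, polyA_min_frac, polyA_min_tail)
  out[pa] <- "polyA_artifact"
  todo <- which(!pa)
  for (cls in priority) {
    if (length(todo) == 0L) break
    refs <- index[[cls]]
    if (length(refs) == 0L) next
    hit <- vapply(seqs[todo],
                  function(s) any(grepl(s, refs, fixed = TRUE)),
                  logical(1L), USE.NAMES = FALSE)
    out[todo[hit]] <- cls
    todo <- todo[!hit]
  }
  out
}

#' Per-class unique/redundant annotation summary
#'
#' Tallies unique and redundant read counts per annotation class plus a
#' `Total` row; the class rows partition the library totals.
#'
#' @param reads collapsed reads data.frame (`seq`, `count`).
#' @param class character vector of class labels, parallel to `reads`.
#' @return data.frame with columns `class`, `unique_reads`,
#'   `redundant_reads`; classes in `ANNOTATION_CLASSES` order, `Total` last.
#' @export
annotation_summary <- function(reads, class) {
  stopifnot(length(class) == nrow(reads))
  bad <- setdiff(unique(class), ANNOTATION_CLASSES)
  if (length(bad) > 0L) {
    stop(sprintf("annotation_summary: unknown class '%s'", bad[1L]),
         call. = FALSE)
  }
  uc <- vapply(ANNOTATION_CLASSES, function(k) sum(class == k), 0L)
  rc <- vapply(ANNOTATION_CLASSES, function(k) sum(reads$count[class == k]), 0)
  out <- data.frame(
    class = c(ANNOTATION_CLASSES, "Total"),
    unique_reads = c(uc, sum(uc)),
    redundant_reads = as.integer(c(rc, sum(rc))),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
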