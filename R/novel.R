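# novel: discover novel miRNA candidates by mapping un-annotated,
# non-conserved reads onto transcripts, excising and folding candidate
# precursor windows, applying stem-loop quality criteria, and detecting
# miRNA* support.

#' Hairpin acceptance criteria for novel-miRNA candidates
#'
#' All thresholds of [evaluate_candidate()] in one configurable object.
#' `min_mfei` is calibrated to the built-in per-pair energy model of
#' [fold_energy_model()], not to thermodynamic (Turner-model) MFEI values
#' such as the 0.85 used with ViennaRNA-style folders: the energy scales
#' differ.
#'
#' @param max_unpaired_mature maximum unpaired mature positions (default 6).
#' @param max_duplex_mismatches maximum unpaired positions in the star
#'   region of the mature:star duplex (default 6).
#' @param min_lp,max_lp precursor (window) length bounds in nt
#'   (defaults 50, 300).
#' @param min_au,max_au A+U percentage bounds (defaults 20, 80).
#' @param min_mfei minimum MFEI under the built-in energy model
#'   (default 0.5).
#' @param max_flank maximum excision flank in nt (default 250).
#' @param require_star if `TRUE`, candidates without a sequenced miRNA*
#'   are dropped (default `FALSE`: star support is reported, not required).
#' @param star_tolerance +/- nt tolerance at each star terminus when
#'   searching the read set for miRNA* support (default 1).
#' @return named list of criteria.
#' @export
novel_criteria <- function(max_unpaired_mature = 6L,
                           max_duplex_mismatches = 6L,
                           min_lp = 50L, max_lp = 300L,
                           min_au = 20, max_au = 80,
                           min_mfei = 0.5, max_flank = 250L,
                           require_star = FALSE, star_tolerance = 1L) {
  list(max_unpaired_mature = max_unpaired_mature,
       max_duplex_mismatches = max_duplex_mismatches,
       min_lp = min_lp, max_lp = max_lp, min_au = min_au, max_au = max_au,
       min_mfei = min_mfei, max_flank = max_flank,
       require_star = require_star, star_tolerance = star_tolerance)
}

#' Map a read to its exact occurrences on a transcript set
#'
#' Reports all exact, ungapped occurrences of the read in each transcript,
#' searching the given sequence and its reverse complement; positions are
#' 1-based, inclusive, on the transcript's given orientation.
#'
#' @param read RNA string, 18-30 nt.
#' @param transcripts data.frame with columns `id`, `seq`.
#' @return data.frame with columns `transcript_id`, `start`, `strand`.
#' @export
map_to_transcripts <- function(read, transcripts) {
  stopifnot(nchar(read) >= 18L, nchar(read) <= 30L)
  out <- list()
  probes <- c("+" = read, "-" = rna_revcomp(read))
  for (r in seq_len(nrow(transcripts))) {
    for (strand in c("+", "-")) {
      occ <- gregexpr(probes[[strand]], transcripts$seq[r], fixed = TRUE)[[1]]
      if (occ[1L] != -1L) {
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = transcripts$id[r], start = as.integer(occ),
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(transcript_id = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Excise candidate precursor windows around a mature locus
#'
#' A deterministic ladder of windows containing the mature span: flank
#' lengths `{20, 40, ..., max_flank}` on each side independently, clipped
#' at the transcript ends and deduplicated.
#'
#' @param transcript_seq transcript sequence (given orientation).
#' @param start 1-based start of the mature occurrence.
#' @param mature_len mature length in nt.
#' @param max_flank maximum flank length (default 250).
#' @return data.frame with columns `win_start`, `win_end`, `seq`,
#'   `mature_offset` (1-based mature start within the window).
#' @export
excise_candidate_windows <- function(transcript_seq, start, mature_len,
                                     max_flank = 250L) {
  n <- nchar(transcript_seq)
  stopifnot(start >= 1L, start + mature_len - 1L <= n)
  flanks <- unique(c(seq(20L, max_flank, by = 20L), max_flank))
  grid <- expand.grid(up = flanks, down = flanks)
  ws <- pmax(1L, start - grid$up)
  we <- pmin(n, start + mature_len - 1L + grid$down)
  keep <- !duplicated(paste(ws, we))
  ws <- ws[keep]; we <- we[keep]
  data.frame(win_start = ws, win_end = we,
             seq = substring(transcript_seq, ws, we),
             mature_offset = start - ws + 1L,
             stringsAsFactors = FALSE)
}

#' Evaluate a precursor window against the hairpin criteria
#'
#' Folds the window and accepts it iff all criteria hold: the structure is
#' a single hairpin; the mature lies on one arm (it may overlap the
#' unpaired terminal-loop region by its duplex overhang, but must not
#' straddle the loop onto the other arm nor lie wholly within the loop);
#' at most `max_unpaired_mature` mature positions are unpaired; at most
#' `max_duplex_mismatches` positions of the inferred star region are
#' unpaired; window length, A+U% and MFEI are within bounds. Rejections
#' carry a machine-readable reason code: `lp_out_of_range`, `not_hairpin`,
#' `mfei_undefined`, `mature_in_loop`, `au_out_of_range`, `mfei_low`,
#' `mature_unpaired`, `duplex_mismatches`, `no_duplex`.
#'
#' @param window_seq window (candidate precursor) RNA sequence.
#' @param mature_start 1-based mature start within the window.
#' @param mature_len mature length.
#' @param criteria criteria list from [novel_criteria()].
#' @param model energy model from [fold_energy_model()].
#' @return list with `accepted` (logical), `reason` (`NA` if accepted),
#'   and, when folding was performed, `structure`, `metrics`, `arm`
#'   (`"5'"`/`"3'"`), `star_span` (c(start, end) within the window, `NA` if
#'   not computable), `unpaired_mature`, `duplex_mismatches`.
#' @export
evaluate_candidate <- function(window_seq, mature_start, mature_len,
                               criteria = novel_criteria(),
                               model = fold_energy_model()) {
  lp <- nchar(window_seq)
  ms <- mature_start
  me <- mature_start + mature_len - 1L
  stopifnot(ms >= 1L, me <= lp)
  rejection <- function(reason, ...) {
    c(list(accepted = FALSE, reason = reason), list(...))
  }
  if (lp < criteria$min_lp || lp > criteria$max_lp) {
    return(rejection("lp_out_of_range"))
  }
  st <- fold_rna(window_seq, model)
  hp <- is_hairpin(st)
  if (!hp$is_hairpin) {
    return(rejection("not_hairpin", structure = st))
  }
  n_gc <- lp - nchar(gsub("[GC]", "", window_seq))
  if (n_gc == 0L) {
    return(rejection("mfei_undefined", structure = st))
  }
  metrics <- hairpin_metrics(st)
  base <- list(structure = st, metrics = metrics)
  a <- hp$loop_span[1L] - 1L   # innermost pair left side
  b <- hp$loop_span[2L] + 1L   # innermost pair right side
  mm <- ms:me
  on5 <- any(mm <= a)
  on3 <- any(mm >= b)
  if ((on5 && on3) || (!on5 && !on3)) {
    return(do.call(rejection, c(list("mature_in_loop"), base)))
  }
  arm <- if (on5) "5'" else "3'"
  base$arm <- arm
  if (metrics$au_percent < criteria$min_au ||
      metrics$au_percent > criteria$max_au) {
    return(do.call(rejection, c(list("au_out_of_range"), base)))
  }
  if (metrics$mfei < criteria$min_mfei) {
    return(do.call(rejection, c(list("mfei_low"), base)))
  }
  ptn <- dotbracket_pairs(st$dotbracket)
  unpaired_mature <- sum(ptn[mm] == 0L)
  base$unpaired_mature <- unpaired_mature
  if (unpaired_mature > criteria$max_unpaired_mature) {
    return(do.call(rejection, c(list("mature_unpaired"), base)))
  }
  span <- star_span(ptn, ms, me, arm, lp)
  base$star_span <- span
  if (anyNA(span)) return(do.call(rejection, c(list("no_duplex"), base)))
  # star 3' overhang (last two positions of the span) is unpaired by
  # construction and not counted as a duplex defect
  core <- span[1L]:max(span[1L], span[2L] - 2L)
  duplex_mismatches <- sum(ptn[core] == 0L)
  base$duplex_mismatches <- duplex_mismatches
  if (duplex_mismatches > criteria$max_duplex_mismatches) {
    return(do.call(rejection, c(list("duplex_mismatches"), base)))
  }
  c(list(accepted = TRUE, reason = NA_character_), base)
}

# Star region of the mature:star duplex, from the partner vector, with a
# 2-nt 3' overhang on each strand: star spans [partner(me-2), partner(ms)+2]
# (both arms follow the same formula under antiparallel geometry).
# Anchors falling on unpaired mature positions are extrapolated from the
# nearest paired position whose partner lies on the opposite arm.
star_span <- function(ptn, ms, me, arm, lp) {
  opp <- if (arm == "5'") function(p) p > me else function(p) p < ms
  mm <- ms:me
  anchored <- mm[ptn[mm] > 0L & opp(ptn[mm])]
  if (length(anchored) == 0L) return(c(NA_integer_, NA_integer_))
  i1 <- anchored[anchored <= me - 2L]
  i1 <- if (length(i1) > 0L) max(i1) else min(anchored)
  i2 <- min(anchored)
  ss <- ptn[i1] - ((me - 2L) - i1)
  se <- ptn[i2] + (i2 - ms) + 2L
  if (is.na(ss) || is.na(se) || ss > se) return(c(NA_integer_, NA_integer_))
  c(max(1L, ss), min(lp, se))
}

#' Search the read set for miRNA* support of an accepted candidate
#'
#' The star region sequence is taken from the candidate's structure (see
#' [evaluate_candidate()]); a star is "sequenced" if a read exactly equal
#' to that sequence, allowing +/- `star_tolerance` nt at each terminus,
#' exists in the read set. Smaller terminal deviations are preferred.
#'
#' @param precursor_seq the accepted window sequence.
#' @param star_span integer c(start, end) of the star region within the
#'   window.
#' @param reads collapsed reads data.frame (`seq`, `count`).
#' @param star_tolerance per-terminus tolerance in nt (default 1).
#' @return list with `star_seq` (`NA` if absent) and `star_count` (0 if
#'   absent).
#' @export
find_star <- function(precursor_seq, star_span, reads, star_tolerance = 1L) {
  if (anyNA(star_span)) return(list(star_seq = NA_character_, star_count = 0L))
  offs <- 0L
  if (star_tolerance > 0L) offs <- c(0L, as.vector(rbind(-seq_len(star_tolerance),
                                                         seq_len(star_tolerance))))
  grid <- expand.grid(ds = offs, de = offs)
  grid <- grid[order(abs(grid$ds) + abs(grid$de), abs(grid$ds), abs(grid$de)), ]
  n <- nchar(precursor_seq)
  for (r in seq_len(nrow(grid))) {
    s <- star_span[1L] + grid$ds[r]
    e <- star_span[2L] + grid$de[r]
    if (s < 1L || e > n || s > e) next
    cand <- substr(precursor_seq, s, e)
    hit <- match(cand, reads$seq)
    if (!is.na(hit)) {
      return(list(star_seq = cand, star_count = reads$count[hit]))
    }
  }
  list(star_seq = NA_character_, star_count = 0L)
}

#' Discover novel miRNA candidates from reads and transcripts
#'
#' End-to-end composition of mapping, window excision, hairpin evaluation
#' and miRNA* detection. Reads matching a known mature sequence are
#' excluded (conserved-first triage); for each mapped locus the accepted
#' window with the highest MFEI wins; candidates are deduplicated by
#' mature sequence; when two candidates are each other's mature/star
#' partners the more abundant arm is kept as the mature. Output is sorted
#' by descending read count.
#'
#' @param reads collapsed, annotation-filtered reads (`seq`, `count`).
#' @param transcripts data.frame with columns `id`, `seq` (EST set).
#' @param known data.frame of known matures (`name`, `seq`) to exclude;
#'   may have zero rows.
#' @param criteria criteria list from [novel_criteria()].
#' @param model energy model from [fold_energy_model()].
#' @return data.frame with one row per candidate: `mature_seq`,
#'   `precursor_id`, `strand`, `precursor_seq`, `arm`, `lm`, `lp`,
#'   `au_percent`, `mfe_abs`, `amfe`, `mfei`, `read_count`, `star_seq`,
#'   `star_count`, `five_prime_u`, `dotbracket`.
#' @export
discover_novel <- function(reads, transcripts, known = NULL,
                           criteria = novel_criteria(),
                           model = fold_energy_model()) {
  known_seqs <- if (!is.null(known) && nrow(known) > 0L) {
    rna_normalize(known$seq)
  } else character(0)
  len <- nchar(reads$seq)
  cand_reads <- reads[!(reads$seq %in% known_seqs) & len >= 18L & len <= 25L, ,
                      drop = FALSE]
  if (nrow(cand_reads) == 0L) return(empty_candidates())
  # fast pre-screen: only reads occurring somewhere in the transcript
  # space (either orientation) are mapped in detail
  haystack <- paste(c(transcripts$seq, rna_revcomp(transcripts$seq)),
                    collapse = "#")
  present <- vapply(cand_reads$seq, function(s) grepl(s, haystack, fixed = TRUE),
                    logical(1L), USE.NAMES = FALSE)
  cand_reads <- cand_reads[present, , drop = FALSE]
  if (nrow(cand_reads) == 0L) return(empty_candidates())

  rows <- list()
  for (r in seq_len(nrow(cand_reads))) {
    mature <- cand_reads$seq[r]
    lm <- nchar(mature)
    loci <- map_to_transcripts(mature, transcripts)
    best <- NULL
    for (l in seq_len(nrow(loci))) {
      tid <- loci$transcript_id[l]
      tseq <- transcripts$seq[match(tid, transcripts$id)]
      start <- loci$start[l]
      if (loci$strand[l] == "-") {
        # work on the reverse complement so the mature reads sense
        start <- nchar(tseq) - (start + lm - 1L) + 1L
        tseq <- rna_revcomp(tseq)
      }
      wins <- excise_candidate_windows(tseq, start, lm, criteria$max_flank)
      for (w in seq_len(nrow(wins))) {
        ev <- evaluate_candidate(wins$seq[w], wins$mature_offset[w], lm,
                                 criteria, model)
        if (!ev$accepted) next
        if (is.null(best) || ev$metrics$mfei > best$ev$metrics$mfei) {
          best <- list(ev = ev, window = wins[w, ], tid = tid,
                       strand = loci$strand[l])
        }
      }
    }
    if (is.null(best)) next
    star <- find_star(best$window$seq, best$ev$star_span, reads,
                      criteria$star_tolerance)
    rows[[length(rows) + 1L]] <- data.frame(
      mature_seq = mature, precursor_id = best$tid, strand = best$strand,
      precursor_seq = best$window$seq, arm = best$ev$arm, lm = lm,
      lp = nchar(best$window$seq),
      au_percent = best$ev$metrics$au_percent,
      mfe_abs = best$ev$metrics$mfe_abs,
      amfe = best$ev$metrics$amfe, mfei = best$ev$metrics$mfei,
      read_count = cand_reads$count[r],
      star_seq = star$star_seq, star_count = star$star_count,
      five_prime_u = startsWith(mature, "U"),
      dotbracket = best$ev$structure$dotbracket,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty_candidates())
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$mature_seq), , drop = FALSE]
  # arm selection: when two candidates are the two strands of one duplex
  # (either one's detected star is the other's mature), keep the more
  # abundant strand as the mature
  drop <- rep(FALSE, nrow(out))
  for (i in seq_len(nrow(out))) {
    j <- match(out$mature_seq[i], out$star_seq)
    if (is.na(j) && !is.na(out$star_seq[i])) {
      j <- match(out$star_seq[i], out$mature_seq)
    }
    if (!is.na(j) && j != i) {
      if (out$read_count[i] < out$read_count[j] ||
          (out$read_count[i] == out$read_count[j] &&
           out$mature_seq[i] > out$mature_seq[j])) {
        drop[i] <- TRUE
      }
    }
  }
  out <- out[!drop, , drop = FALSE]
  if (criteria$require_star) {
    out <- out[!is.na(out$star_seq), , drop = FALSE]
  }
  out <- out[order(-out$read_count, out$mature_seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(mature_seq = character(0), precursor_id = character(0),
             strand = character(0), precursor_seq = character(0),
             arm = character(0), lm = integer(0), lp = integer(0),
             au_percent = numeric(0), mfe_abs = numeric(0),
             amfe = numeric(0), mfei = numeric(0), read_count = integer(0),
             star_seq = character(0), star_count = integer(0),
             five_prime_u = logical(0), dotbracket = character(0),
             stringsAsFactors = FALSE)
}
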