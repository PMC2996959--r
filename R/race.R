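# race: map 5'-RACE clone ends onto a target mRNA and call the
# miRNA-guided cleavage site. Plant miRNA cleavage canonically falls
# opposite the miRNA's tenth nucleotide from its 5' end.

#' Map 5'-RACE clone ends onto a target
#'
#' A clone maps iff its first `anchor_len` nt occur exactly once in the
#' target; the clone's 5' terminus is that occurrence's start (1-based).
#' Ambiguous (multi-hit) and unmatched clones are reported separately.
#'
#' @param clones data.frame with columns `id`, `seq` (clone cDNA, sense
#'   strand of the target), or a character vector of sequences.
#' @param target target mRNA sequence (RNA string).
#' @param anchor_len prefix length used for exact matching (default 20).
#' @return list with `termini` (data.frame `id`, `position`), `ambiguous`
#'   and `unmatched` (character vectors of clone ids).
#' @export
map_clone_ends <- function(clones, target, anchor_len = 20L) {
  if (!is.data.frame(clones)) {
    clones <- data.frame(id = paste0("clone", seq_along(clones)),
                         seq = as.character(clones), stringsAsFactors = FALSE)
  }
  stopifnot(nrow(clones) >= 1L, nchar(target) >= anchor_len)
  pos <- integer(0); ids <- character(0)
  ambiguous <- character(0); unmatched <- character(0)
  for (r in seq_len(nrow(clones))) {
    anchor <- substr(clones$seq[r], 1L, anchor_len)
    if (nchar(anchor) < anchor_len) {
      unmatched <- c(unmatched, clones$id[r]); next
    }
    occ <- gregexpr(anchor, target, fixed = TRUE)[[1]]
    if (occ[1L] == -1L) {
      unmatched <- c(unmatched, clones$id[r])
    } else if (length(occ) > 1L) {
      ambiguous <- c(ambiguous, clones$id[r])
    } else {
      ids <- c(ids, clones$id[r]); pos <- c(pos, as.integer(occ[1L]))
    }
  }
  list(termini = data.frame(id = ids, position = pos, stringsAsFactors = FALSE),
       ambiguous = ambiguous, unmatched = unmatched)
}

#' Tally clone 5' termini around a miRNA-complementary site
#'
#' Retains termini within the window centered on the site midpoint
#' (`window/2` nt each side, boundaries inclusive; midpoint of an
#' even-length site is `floor((start+end)/2)`) and tallies counts per
#' position.
#'
#' @param termini data.frame from [map_clone_ends()] (`position` column)
#'   or an integer vector of positions.
#' @param site_start,site_end complementary-site coordinates on the target
#'   (1-based, inclusive).
#' @param window window width in nt (default 100).
#' @return list of class `cleavage_profile`: `site_start`, `site_end`,
#'   `center`, `window`, `counts` (data.frame `position`, `count`),
#'   `total_clones`, `in_window_clones`.
#' @export
cleavage_profile <- function(termini, site_start, site_end, window = 100L) {
  stopifnot(site_start >= 1L, site_end >= site_start)
  pos <- if (is.data.frame(termini)) termini$position else as.integer(termini)
  center <- floor((site_start + site_end) / 2)
  lo <- center - window / 2
  hi <- center + window / 2
  inw <- pos[pos >= lo & pos <= hi]
  counts <- if (length(inw) > 0L) {
    tab <- table(inw)
    data.frame(position = as.integer(names(tab)), count = as.integer(tab))
  } else {
    data.frame(position = integer(0), count = integer(0))
  }
  structure(list(site_start = site_start, site_end = site_end,
                 center = center, window = window, counts = counts,
                 total_clones = length(pos), in_window_clones = length(inw)),
            class = "cleavage_profile")
}

#' Call the miRNA-guided cleavage position from a clone-end profile
#'
#' The modal terminus is the most frequent in-window clone 5' end (ties
#' resolved toward the coordinate pairing the miRNA's tenth nucleotide,
#' then toward the smaller coordinate). The miRNA pairing index follows
#' antiparallel geometry: the site's 3'-most position pairs miRNA nt 1, so
#' a terminus at position p has index `site_end - p + 1`. The call is
#' validated when the modal count and modal fraction meet the thresholds.
#'
#' @param profile a `cleavage_profile`.
#' @param mirna the guiding miRNA sequence (RNA string).
#' @param min_clones minimum modal clone count for validation (default 3).
#' @param min_fraction minimum modal fraction of in-window clones
#'   (default 0.3).
#' @return list of class `cleavage_call`: `modal_position`,
#'   `modal_count`, `modal_fraction`, `mirna_pairing_index`, `validated`.
#' @export
call_cleavage <- function(profile, mirna, min_clones = 3L,
                          min_fraction = 0.3) {
  stopifnot(inherits(profile, "cleavage_profile"))
  if (profile$in_window_clones < 1L) {
    stop("call_cleavage: no in-window clone termini to call from",
         call. = FALSE)
  }
  counts <- profile$counts
  canonical <- profile$site_end - 10L + 1L  # position pairing miRNA nt 10
  best <- counts[counts$count == max(counts$count), , drop = FALSE]
  best <- best[order(abs(best$position - canonical), best$position), ,
               drop = FALSE]
  modal <- best$position[1L]
  modal_count <- best$count[1L]
  idx <- profile$site_end - modal + 1L
  if (idx < 1L || idx > nchar(mirna)) {
    idx <- NA_integer_  # modal terminus outside the complementary site
  }
  frac <- modal_count / profile$in_window_clones
  structure(list(modal_position = modal, modal_count = modal_count,
                 modal_fraction = frac, mirna_pairing_index = idx,
                 validated = !is.na(idx) && modal_count >= min_clones &&
                   frac >= min_fraction),
            class = "cleavage_call")
}

#' Render a cleavage profile as a text diagram
#'
#' The miRNA:site duplex with clone-fraction arrows above the positions
#' where in-window clone 5' ends fall within the complementary site.
#'
#' @param profile a `cleavage_profile`.
#' @param mirna the guiding miRNA.
#' @param target the target mRNA sequence.
#' @return single string with embedded newlines.
#' @export
render_cleavage_diagram <- function(profile, mirna, target) {
  site <- substr(target, profile$site_start, profile$site_end)
  L <- nchar(site)
  marks <- rep(" ", L)
  lab <- character(0)
  for (r in seq_len(nrow(profile$counts))) {
    p <- profile$counts$position[r]
    if (p >= profile$site_start && p <= profile$site_end) {
      marks[p - profile$site_start + 1L] <- "v"
      lab <- c(lab, sprintf("pos %d: %d/%d", p, profile$counts$count[r],
                            profile$in_window_clones))
    }
  }
  paste0("   ", paste(marks, collapse = ""), "\n",
         render_duplex(mirna, site),
         if (length(lab) > 0L) paste0("\n", paste(lab, collapse = "; ")) else "")
}
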