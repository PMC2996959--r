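# fold: minimum-free-energy secondary-structure prediction under a
# simplified per-pair energy model, plus the hairpin quality metrics
# (AMFE, MFEI, A+U%) standard in plant miRNA precursor assessment.

#' Default per-pair energy model for the built-in folder
#'
#' A Nussinov-style dynamic program scores each admissible base pair with a
#' fixed energy (kcal/mol): G:C -3, A:U -2, G:U wobble -1, with a minimum
#' hairpin loop of 3 unpaired nt. Energies are on the model's own scale,
#' not the Turner nearest-neighbor scale; MFEI thresholds downstream are
#' calibrated to this model.
#'
#' @param gc,au,gu pair energies (must be negative).
#' @param min_loop minimum hairpin loop size in nt.
#' @return list with elements `gc`, `au`, `gu`, `min_loop`.
#' @export
fold_energy_model <- function(gc = -3, au = -2, gu = -1, min_loop = 3L) {
  stopifnot(gc < 0, au < 0, gu < 0, min_loop >= 0L)
  list(gc = gc, au = au, gu = gu, min_loop = as.integer(min_loop))
}

#' Fold an RNA sequence to its minimum-energy nested structure
#'
#' Dynamic-programming optimum over all nested (pseudoknot-free)
#' structures under the per-pair energy model. Ties are broken
#' deterministically: during traceback, pairing the leftmost position with
#' the smallest admissible partner is preferred over leaving it unpaired,
#' so outputs are bit-stable across platforms.
#'
#' @param seq RNA string over `{A,C,G,U}`, length 1 to 1000.
#' @param model energy model from [fold_energy_model()].
#' @return object of class `rna_structure`: list with `seq`, `dotbracket`
#'   and `energy` (kcal/mol, <= 0).
#' @examples
#' fold_rna("GGGAAACCC")
#' @export
fold_rna <- function(seq, model = fold_energy_model()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < 1L || nchar(seq) > 1000L) {
    stop("fold_rna: sequence length must be in [1, 1000]", call. = FALSE)
  }
  assert_rna(seq, "fold_rna input")
  res <- nussinov_fold_cpp(seq, model$gc, model$au, model$gu, model$min_loop)
  structure(list(seq = seq, dotbracket = res$dotbracket,
                 energy = res$energy),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$seq, "\n", x$dotbracket, "  (", format(x$energy), " kcal/mol)\n",
      sep = "")
  invisible(x)
}

# Partner vector from a dot-bracket string: 0 = unpaired.
dotbracket_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  n <- length(chars)
  ptn <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ptn[i] <- j
      ptn[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket", call. = FALSE)
  ptn
}

#' Hairpin quality metrics of a folded sequence
#'
#' The standard plant-miRNA precursor statistics: `mfe_abs` = |MFE|
#' (kcal/mol), `amfe` = |MFE| / length x 100 (the length-adjusted MFE),
#' `mfei` = AMFE / GC% (the minimal folding free energy index), and
#' `au_percent` = (A+U) / length x 100. MFEI is an error when GC% is 0.
#'
#' @param structure an `rna_structure` from [fold_rna()].
#' @return list with elements `mfe_abs`, `amfe`, `mfei`, `au_percent`,
#'   `gc_percent`, `precursor_len`.
#' @export
hairpin_metrics <- function(structure) {
  stopifnot(inherits(structure, "rna_structure"))
  seq <- structure$seq
  len <- nchar(seq)
  n_gc <- len - nchar(gsub("[GC]", "", seq))
  gc_percent <- n_gc / len * 100
  au_percent <- 100 - gc_percent
  mfe_abs <- abs(structure$energy)
  amfe <- mfe_abs / len * 100
  if (gc_percent == 0) {
    stop("hairpin_metrics: MFEI undefined for a sequence with GC% = 0",
         call. = FALSE)
  }
  list(mfe_abs = mfe_abs, amfe = amfe, mfei = amfe / gc_percent,
       au_percent = au_percent, gc_percent = gc_percent,
       precursor_len = len)
}

#' Is a structure a single hairpin, and where are its arms?
#'
#' A single hairpin has exactly one terminal loop: its base pairs are
#' totally ordered by containment (no two pairs are disjoint, so there is
#' no multiloop). The arm map labels every position `5arm` (at or before
#' the innermost pair's left side), `loop` (strictly inside the innermost
#' pair) or `3arm`.
#'
#' @param structure an `rna_structure`.
#' @return list with `is_hairpin` (logical), `arm_map` (character vector,
#'   length = sequence length; all `"loop"`... is only returned for
#'   pair-free structures, where `is_hairpin` is `FALSE` and the map is
#'   `NA`), and `loop_span` (c(start, end) of the terminal loop, or `NA`).
#' @export
is_hairpin <- function(structure) {
  stopifnot(inherits(structure, "rna_structure"))
  ptn <- dotbracket_pairs(structure$dotbracket)
  n <- length(ptn)
  left <- which(ptn > seq_len(n))   # opening positions i with partner j > i
  if (length(left) == 0L) {
    return(list(is_hairpin = FALSE, arm_map = rep(NA_character_, n),
                loop_span = c(NA_integer_, NA_integer_)))
  }
  i_sorted <- sort(left)
  j_sorted <- ptn[i_sorted]
  # chain of containment: i ascending must give j strictly descending
  single <- !is.unsorted(rev(j_sorted), strictly = TRUE)
  a <- i_sorted[length(i_sorted)]   # innermost pair (a, b)
  b <- ptn[a]
  arm <- rep("3arm", n)
  arm[seq_len(a)] <- "5arm"
  if (b - a > 1L) arm[(a + 1L):(b - 1L)] <- "loop"
  list(is_hairpin = single, arm_map = arm, loop_span = c(a + 1L, b - 1L))
}
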