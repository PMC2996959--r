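# Independent oracles and small generators shared across the test files.
# Each oracle is a deliberately naive re-derivation, kept independent of
# the package's implementation paths.

rand_rna <- function(len, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

naive_revcomp <- function(s) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Exhaustive minimum energy over all nested structures (tiny n only).
brute_force_fold_energy <- function(seq, gc = -3, au = -2, gu = -1,
                                    min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  pen <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("GC", "CG")) gc
    else if (p %in% c("AU", "UA")) au
    else if (p %in% c("GU", "UG")) gu
    else NA_real_
  }
  rec <- function(i, j) {
    if (i >= j) return(0)
    best <- rec(i + 1, j)
    ks <- if (i + min_loop + 1 <= j) (i + min_loop + 1):j else integer(0)
    for (k in ks) {
      e <- pen(ch[i], ch[k])
      if (!is.na(e)) {
        v <- e + rec(i + 1, k - 1) + rec(k + 1, j)
        if (v < best) best <- v
      }
    }
    best
  }
  rec(1, n)
}

# Naive per-window duplex mismatch/wobble recount (independent of
# pair_class / count_mismatches).
naive_duplex_counts <- function(mirna, site) {
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  a <- strsplit(mirna, "")[[1]]
  b <- rev(strsplit(site, "")[[1]])
  mm <- 0L; wb <- 0L
  for (i in seq_along(a)) {
    if (wc[[a[i]]] == b[i]) next
    if ((a[i] == "G" && b[i] == "U") || (a[i] == "U" && b[i] == "G")) {
      wb <- wb + 1L
    } else {
      mm <- mm + 1L
    }
  }
  c(mismatches = mm, wobbles = wb)
}

# Naive full target scan by sliding window.
naive_scan <- function(mirna, tid, tseq, max_mismatch) {
  L <- nchar(mirna)
  out <- list()
  for (s in seq_len(max(0L, nchar(tseq) - L + 1L))) {
    site <- substr(tseq, s, s + L - 1L)
    cnt <- naive_duplex_counts(mirna, site)
    if (cnt[["mismatches"]] <= max_mismatch) {
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = tid, site_start = s,
        mismatches = cnt[["mismatches"]], wobbles = cnt[["wobbles"]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(transcript_id = character(0), site_start = integer(0),
                      mismatches = integer(0), wobbles = integer(0)))
  }
  do.call(rbind, out)
}

# A small simulated study used by several files (kept light).
small_sim <- function(seed = 7L, n_novel = 3L) {
  simulate_library(sim_config(
    seed = seed, n_conserved = 5L, n_novel = n_novel, n_decoy_reads = 60L,
    ncrna_class_reads = c(rRNA = 30L, tRNA = 15L, snRNA = 8L),
    n_polyA = 6L, n_known = 30L, n_est = max(5L, n_novel)))
}
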