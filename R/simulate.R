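# synthetic_data: generate every input the pipeline needs, with a
# ground-truth ledger, emulating the structure of a deep-sequenced plant
# small-RNA library: planted conserved miRNAs, novel hairpin precursors
# embedded in EST-like transcripts with miRNA* partners, ncRNA fragments,
# polyA artifacts, a heavy-tailed (Zipf) abundance distribution, and
# 5'-RACE clone sets with a dominant planted terminus.
#
# EST backgrounds, hairpin flanks, loops and star overhangs are drawn from
# a non-self-pairing A/C alphabet so that the planted stem is the unique
# minimum-energy structure under the simplified pair-energy model; see the
# methods vignette for what this does and does not emulate.

BACKGROUND_ALPHABET <- "A"
LOOP_ALPHABET <- c("A", "C")

# Hairpin flanks are a C/G clamp: a pure-C 5' flank paired to a pure-G 3'
# flank forms a lower stem (as real pre-miRNAs have below the duplex) that
# cannot interact with the poly-A background; together with the crossing
# constraints of nested structures this makes the planted stem-loop the
# unique minimum-energy structure, so recovery tests measure the
# pipeline's criteria rather than folding ambiguity.

# One random RNA string.
random_rna <- function(len, alphabet = RNA_ALPHABET) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Zipf-distributed counts: P(count = k) proportional to k^-s, truncated.
rzipf <- function(n, s = 1.2, kmax = 10000L) {
  k <- seq_len(kmax)
  sample(k, n, replace = TRUE, prob = k^(-s))
}

# Default read-length distribution over 18..30 nt with the two major size
# classes at 24 nt (44.1%) and 21 nt (13.2%) typical of plant libraries.
default_length_probs <- function() {
  lens <- 18:30
  p <- rep(NA_real_, length(lens))
  p[lens == 24] <- 0.441
  p[lens == 21] <- 0.132
  p[is.na(p)] <- (1 - 0.441 - 0.132) / sum(is.na(p))
  stats::setNames(p, lens)
}

#' Configuration of the synthetic small-RNA library
#'
#' Defaults define the study conditions used throughout the test suite:
#' 20 planted conserved miRNAs, 10 planted novel precursors, 5000 decoy
#' reads, Zipf(1.2) abundances, a read-length distribution with modes at
#' 21 and 24 nt, and a 50% miRNA* emission probability.
#'
#' @param seed integer RNG seed; identical seed + config gives
#'   byte-identical outputs.
#' @param n_conserved number of planted known-mature reads.
#' @param n_novel number of planted novel hairpin precursors.
#' @param n_decoy_reads number of random un-annotated decoy reads.
#' @param ncrna_class_reads named integer vector: planted fragment reads
#'   per ncRNA class.
#' @param n_polyA number of planted polyA-artifact reads.
#' @param n_known size of the synthetic known-mature registry.
#' @param n_est,est_len number and length of EST-like transcripts.
#' @param zipf_exponent Zipf abundance exponent (default 1.2).
#' @param length_probs named probability vector over read lengths 18..30.
#' @param star_emission_prob probability a planted precursor's miRNA* is
#'   sequenced (default 0.5).
#' @param loop_len,flank_len,stem_mismatches hairpin construction
#'   parameters passed to [make_hairpin_precursor()].
#' @param noise_fraction RACE clone noise fraction (default 0.2).
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L, n_conserved = 20L, n_novel = 10L,
                       n_decoy_reads = 5000L,
                       ncrna_class_reads = c(rRNA = 400L, tRNA = 200L,
                                             snRNA = 80L, snoRNA = 50L,
                                             exon = 30L, intron = 20L,
                                             "repeat" = 20L),
                       n_polyA = 40L, n_known = 200L,
                       n_est = 20L, est_len = 600L,
                       zipf_exponent = 1.2,
                       length_probs = default_length_probs(),
                       star_emission_prob = 0.5,
                       loop_len = 6L, flank_len = 15L,
                       stem_mismatches = 0L, noise_fraction = 0.2) {
  stopifnot(n_conserved >= 0L, n_novel >= 0L, n_decoy_reads >= 0L,
            star_emission_prob >= 0, star_emission_prob <= 1,
            noise_fraction >= 0, noise_fraction <= 1,
            n_est >= n_novel, n_known >= n_conserved)
  structure(list(seed = seed, n_conserved = n_conserved, n_novel = n_novel,
                 n_decoy_reads = n_decoy_reads,
                 ncrna_class_reads = ncrna_class_reads, n_polyA = n_polyA,
                 n_known = n_known, n_est = n_est, est_len = est_len,
                 zipf_exponent = zipf_exponent, length_probs = length_probs,
                 star_emission_prob = star_emission_prob,
                 loop_len = loop_len, flank_len = flank_len,
                 stem_mismatches = stem_mismatches,
                 noise_fraction = noise_fraction),
            class = "sim_config")
}

#' Construct a stem-loop precursor around a mature sequence
#'
#' The precursor is `flank + mature + loop + star + flank` (5' arm) or
#' `flank + star + loop + mature + flank` (3' arm). The star strand is the
#' reverse complement of the mature's first `L-2` nt followed by a 2-nt
#' 3' overhang, so the mature:star duplex carries the canonical 2-nt 3'
#' overhang on each strand. `stem_mismatches` point substitutions are
#' placed at RNG-chosen non-terminal star positions, each chosen so the
#' facing bases cannot pair. The loop is drawn from a non-self-pairing A/C
#' alphabet, the overhang is `AA`, and the flanks are a pure-C (5') /
#' pure-G (3') clamp forming a lower stem below the duplex.
#'
#' @param mature mature RNA string, 18-25 nt.
#' @param arm `"5'"` or `"3'"`: the arm carrying the mature.
#' @param loop_len terminal loop length, >= 4 nt.
#' @param stem_mismatches number of star-side point substitutions.
#' @param flank_len flank length on each side.
#' @return list with `precursor` (RNA string), `mature_span`, `star_span`
#'   (both 1-based inclusive c(start, end) on the precursor), `star_seq`,
#'   `arm`.
#' @export
make_hairpin_precursor <- function(mature, arm = c("5'", "3'"),
                                   loop_len = 6L, stem_mismatches = 0L,
                                   flank_len = 15L) {
  arm <- match.arg(arm)
  L <- nchar(mature)
  stopifnot(L >= 18L, L <= 25L, loop_len >= 4L, flank_len >= 0L,
            stem_mismatches >= 0L)
  assert_rna(mature, "mature")
  if (stem_mismatches > L - 4L) {
    stop("make_hairpin_precursor: more stem mismatches than non-terminal stem positions",
         call. = FALSE)
  }
  core <- strsplit(rna_revcomp(substr(mature, 1L, L - 2L)), "")[[1]]
  if (stem_mismatches > 0L) {
    # non-terminal core positions; core position t faces mature nt L-1-t
    pos <- sample(2:(length(core) - 1L), stem_mismatches)
    for (t in pos) {
      facing <- substr(mature, L - 1L - t, L - 1L - t)
      choices <- RNA_ALPHABET[pair_class(rep(facing, 4L), RNA_ALPHABET) == "mismatch"]
      core[t] <- sample(choices, 1L)
    }
  }
  star <- paste0(paste(core, collapse = ""), "AA")
  loop <- random_rna(loop_len, LOOP_ALPHABET)
  f5 <- strrep("C", flank_len)
  f3 <- strrep("G", flank_len)
  if (arm == "5'") {
    precursor <- paste0(f5, mature, loop, star, f3)
    mature_span <- c(flank_len + 1L, flank_len + L)
    star_span <- c(flank_len + L + loop_len + 1L,
                   flank_len + L + loop_len + L)
  } else {
    precursor <- paste0(f5, star, loop, mature, f3)
    star_span <- c(flank_len + 1L, flank_len + L)
    mature_span <- c(flank_len + L + loop_len + 1L,
                     flank_len + L + loop_len + L)
  }
  list(precursor = precursor, mature_span = mature_span,
       star_span = star_span, star_seq = star, arm = arm)
}

# TRUE iff the constructed precursor, in poly-A transcript context,
# is accepted by the default hairpin criteria with the planted arm and the
# exact planted star region (poly-A context is structurally inert, so this
# predicts the evaluation outcome for any excised window containing the
# full precursor).
planted_fold_ok <- function(hp, lm) {
  ctx <- paste0(strrep("A", 40L), hp$precursor, strrep("A", 40L))
  ev <- evaluate_candidate(ctx, 40L + hp$mature_span[1L], lm)
  isTRUE(ev$accepted) && identical(ev$arm, hp$arm) &&
    !anyNA(ev$star_span) && all(ev$star_span - 40L == hp$star_span)
}

# Draw a read length from the configured distribution.
draw_length <- function(n, probs) {
  as.integer(sample(names(probs), n, replace = TRUE, prob = probs))
}

#' Simulate a complete small-RNA study input bundle
#'
#' Generates, deterministically under `config$seed`: a collapsed read
#' library (conserved miRNA reads, novel mature and star reads, ncRNA
#' fragments, polyA artifacts, decoys, all with Zipf-drawn counts), the
#' per-class ncRNA reference sets, a known-mature registry, the EST set
#' with embedded precursors, and a ground-truth ledger covering every
#' emitted read exactly once.
#'
#' @param config a `sim_config`.
#' @return list with elements `reads` (collapsed data.frame), `known`
#'   (`name`, `seq`, `family`), `ests` (`id`, `seq`), `ncrna_refs` (named
#'   list of data.frames), `truth` (list: `reads` ledger with true origin
#'   and expected annotation class, `novel`, `conserved`), and `config`.
#' @export
simulate_library <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  zipf <- function(n) rzipf(n, config$zipf_exponent)
  taken <- new.env(parent = emptyenv())
  claim <- function(seq) {
    if (is.null(taken[[seq]])) { taken[[seq]] <- TRUE; TRUE } else FALSE
  }
  fresh <- function(gen) {
    for (i in 1:1000) { s <- gen(); if (claim(s)) return(s) }
    stop("simulate_library: could not draw a fresh unique sequence")
  }

  # known-mature registry
  fam_pool <- c(156, 159, 160, 162, 164, 165, 166, 167, 168, 169, 171, 172,
                319, 390, 393, 394, 395, 396, 397, 398, 399, 403, 408, 414,
                419, 482, 530, 535, 827, 828, 835, 844, 861, 902, 950, 1027,
                1044, 1310, 1426, 1436, 1446)
  species <- c("ath", "osa", "ptc", "vvi", "gma", "csi")
  known_names <- character(0)
  while (length(known_names) < config$n_known) {
    nm <- sprintf("%s-miR%d%s", sample(species, 1L), sample(fam_pool, 1L),
                  sample(letters[1:6], 1L))
    if (!nm %in% known_names) known_names <- c(known_names, nm)
  }
  known <- data.frame(
    name = known_names,
    seq = vapply(seq_along(known_names),
                 function(i) fresh(function() random_rna(sample(20:22, 1L))),
                 ""),
    stringsAsFactors = FALSE)
  known$family <- assign_family(known$name)

  ledger <- list()
  add_reads <- function(seq, count, class, annotation_class, source) {
    data.frame(seq = seq, count = as.integer(count), class = class,
               annotation_class = annotation_class, source = source,
               stringsAsFactors = FALSE)
  }

  # conserved plants: reads identical to known matures
  conserved_idx <- sort(sample(config$n_known, config$n_conserved))
  if (config$n_conserved > 0L) {
    ledger[["conserved"]] <- add_reads(
      known$seq[conserved_idx], zipf(config$n_conserved) + 1L,
      "conserved_mirna", "unannotated", known$name[conserved_idx])
  }

  # EST backbone (non-pairing background) and embedded novel precursors
  ests <- data.frame(
    id = sprintf("est%02d", seq_len(config$n_est)),
    seq = vapply(seq_len(config$n_est),
                 function(i) random_rna(config$est_len, BACKGROUND_ALPHABET),
                 ""),
    stringsAsFactors = FALSE)
  novel <- NULL
  if (config$n_novel > 0L) {
    rows <- list()
    for (i in seq_len(config$n_novel)) {
      lm <- sample(c(21L, 24L), 1L, prob = c(0.9, 0.1))
      arm <- sample(c("5'", "3'"), 1L)
      # draw matures subject to the planted precursor folding to the
      # intended single hairpin in transcript context (some sequence
      # compositions admit equal-energy alternative structures under the
      # simplified model; those are redrawn)
      for (try in 1:200) {
        mature <- fresh(function() random_rna(lm))
        hp <- make_hairpin_precursor(mature, arm, config$loop_len,
                                     config$stem_mismatches, config$flank_len)
        if (planted_fold_ok(hp, lm)) break
        rm(list = mature, envir = taken)
        hp <- NULL
      }
      if (is.null(hp)) {
        stop("simulate_library: could not construct a cleanly folding precursor")
      }
      lp <- nchar(hp$precursor)
      embed <- sample(config$est_len - lp + 1L, 1L)
      est_seq <- ests$seq[i]
      substr(est_seq, embed, embed + lp - 1L) <- hp$precursor
      ests$seq[i] <- est_seq
      star_count <- zipf(1L)
      mature_count <- star_count + zipf(1L)
      star_emitted <- stats::runif(1L) < config$star_emission_prob
      claim(hp$star_seq)
      rows[[i]] <- data.frame(
        mature_seq = mature, star_seq = hp$star_seq,
        star_emitted = star_emitted, est_id = ests$id[i],
        precursor_start = embed, precursor_end = embed + lp - 1L,
        mature_start = embed + hp$mature_span[1L] - 1L,
        arm = arm, lp = lp, lm = lm,
        mature_count = mature_count,
        star_count = if (star_emitted) star_count else 0L,
        stringsAsFactors = FALSE)
    }
    novel <- do.call(rbind, rows)
    ledger[["novel_mature"]] <- add_reads(
      novel$mature_seq, novel$mature_count, "novel_mature", "unannotated",
      novel$est_id)
    if (any(novel$star_emitted)) {
      sub <- novel[novel$star_emitted, , drop = FALSE]
      ledger[["novel_star"]] <- add_reads(
        sub$star_seq, sub$star_count, "novel_star", "unannotated",
        sub$est_id)
    }
  }

  # ncRNA references and planted fragment reads
  ncrna_refs <- list()
  for (cls in names(config$ncrna_class_reads)) {
    n_reads <- config$ncrna_class_reads[[cls]]
    refs <- data.frame(
      id = sprintf("%s_ref%d", cls, 1:3),
      seq = vapply(1:3, function(i) random_rna(sample(150:400, 1L)), ""),
      stringsAsFactors = FALSE)
    ncrna_refs[[cls]] <- refs
    if (n_reads > 0L) {
      seqs <- vapply(seq_len(n_reads), function(i) {
        fresh(function() {
          ref <- refs$seq[sample(nrow(refs), 1L)]
          len <- draw_length(1L, config$length_probs)
          s <- sample(nchar(ref) - len + 1L, 1L)
          substr(ref, s, s + len - 1L)
        })
      }, "")
      ledger[[paste0("ncrna_", cls)]] <- add_reads(
        seqs, zipf(n_reads), cls, cls, cls)
    }
  }

  # polyA artifacts: random prefix with a terminal A run of >= 10 nt
  if (config$n_polyA > 0L) {
    seqs <- vapply(seq_len(config$n_polyA), function(i) {
      fresh(function() {
        len <- draw_length(1L, config$length_probs)
        tail_len <- sample(10L:max(10L, len - 5L), 1L)
        paste0(random_rna(len - tail_len), strrep("A", tail_len))
      })
    }, "")
    ledger[["polyA"]] <- add_reads(seqs, zipf(config$n_polyA),
                                   "polyA_artifact", "polyA_artifact",
                                   "polyA")
  }

  # decoys: random un-annotated reads
  if (config$n_decoy_reads > 0L) {
    seqs <- vapply(seq_len(config$n_decoy_reads), function(i) {
      fresh(function() random_rna(draw_length(1L, config$length_probs)))
    }, "")
    ledger[["decoy"]] <- add_reads(seqs, zipf(config$n_decoy_reads),
                                   "decoy", "unannotated", "decoy")
  }

  truth_reads <- do.call(rbind, ledger)
  rownames(truth_reads) <- NULL
  reads <- collapse_reads(truth_reads[, c("seq", "count")])

  list(reads = reads, known = known, ests = ests, ncrna_refs = ncrna_refs,
       truth = list(reads = truth_reads, novel = novel,
                    conserved = if (config$n_conserved > 0L)
                      known[conserved_idx, , drop = FALSE] else NULL),
       config = config)
}

#' Write a simulated bundle to disk
#'
#' Writes `reads.fa` (collapsed dialect), `known.fa`, `ests.fa`, one
#' `ncrna_<class>.fa` per reference class, the ground-truth ledgers as TSV
#' and the configuration as YAML. Output bytes are a pure function of the
#' bundle, so identical configurations produce identical files.
#'
#' @param sim output of [simulate_library()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_collapsed_fasta(sim$reads, file.path(dir, "reads.fa"))
  write_sequences(data.frame(id = sim$known$name, seq = sim$known$seq),
                  file.path(dir, "known.fa"))
  write_sequences(sim$ests, file.path(dir, "ests.fa"))
  for (cls in names(sim$ncrna_refs)) {
    write_sequences(sim$ncrna_refs[[cls]],
                    file.path(dir, paste0("ncrna_", cls, ".fa")))
  }
  write_table(sim$truth$reads, file.path(dir, "ledger_reads.tsv"))
  if (!is.null(sim$truth$novel)) {
    write_table(sim$truth$novel, file.path(dir, "ledger_novel.tsv"))
  }
  cfg <- sim$config
  class(cfg) <- NULL
  cfg$length_probs <- as.list(cfg$length_probs)
  cfg$ncrna_class_reads <- as.list(cfg$ncrna_class_reads)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Simulate 5'-RACE clones for a miRNA-complementary site
#'
#' Canonical mode places `ceiling((1 - noise_fraction) * n_clones)` clone
#' 5' ends at the target coordinate pairing the miRNA's tenth nucleotide
#' (the canonical plant cleavage position); the remaining ends fall
#' uniformly within the 100-nt window around the site. Each clone is the
#' target suffix starting at its terminus.
#'
#' @param target target mRNA sequence (RNA string).
#' @param site_start,site_end complementary-site coordinates (1-based,
#'   inclusive).
#' @param mirna the guiding miRNA.
#' @param n_clones number of clones (default 15).
#' @param noise_fraction fraction of non-canonical termini (default 0.2).
#' @param seed optional RNG seed; `NULL` continues the current stream.
#' @param anchor_len minimum mapped clone length margin (clones are at
#'   least `anchor_len + 10` nt).
#' @return list with `clones` (data.frame `id`, `seq`), and `truth`
#'   (list: `cleavage_position`, `pairing_index` = 10, `termini`).
#' @export
simulate_race_clones <- function(target, site_start, site_end, mirna,
                                 n_clones = 15L, noise_fraction = 0.2,
                                 seed = NULL, anchor_len = 20L) {
  stopifnot(site_end <= nchar(target), site_end - site_start + 1L >= 10L,
            noise_fraction >= 0, noise_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  canonical <- site_end - 10L + 1L
  n_canon <- ceiling((1 - noise_fraction) * n_clones)
  n_noise <- n_clones - n_canon
  center <- floor((site_start + site_end) / 2)
  max_pos <- nchar(target) - (anchor_len + 10L) + 1L
  lo <- max(1L, center - 50L)
  hi <- min(max_pos, center + 50L)
  termini <- c(rep(canonical, n_canon),
               if (n_noise > 0L) sample(lo:hi, n_noise, replace = TRUE))
  clones <- data.frame(id = sprintf("clone%02d", seq_along(termini)),
                       seq = substring(target, termini),
                       stringsAsFactors = FALSE)
  list(clones = clones,
       truth = list(cleavage_position = canonical, pairing_index = 10L,
                    termini = termini))
}

#' Simulate a full RACE experiment: target, planted site and clones
#'
#' Builds a random target mRNA with one planted miRNA-complementary site
#' (the exact reverse complement of a random miRNA) and simulates the
#' clone set with [simulate_race_clones()].
#'
#' @param seed RNG seed.
#' @param target_len target length (default 300 nt).
#' @param mirna_len miRNA length (default 21 nt).
#' @param n_clones,noise_fraction passed to [simulate_race_clones()].
#' @return list with `target`, `mirna`, `site_start`, `site_end`,
#'   `clones`, `truth`.
#' @export
simulate_race_bundle <- function(seed, target_len = 300L, mirna_len = 21L,
                                 n_clones = 15L, noise_fraction = 0.2) {
  set.seed(seed)
  mirna <- random_rna(mirna_len)
  target <- random_rna(target_len)
  site_start <- sample(101:160, 1L)
  site_end <- site_start + mirna_len - 1L
  substr(target, site_start, site_end) <- rna_revcomp(mirna)
  sim <- simulate_race_clones(target, site_start, site_end, mirna,
                              n_clones, noise_fraction, seed = NULL)
  c(list(target = target, mirna = mirna, site_start = site_start,
         site_end = site_end), sim)
}
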