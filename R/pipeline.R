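# cli_report: orchestrate the full pipeline over an input bundle and
# render the per-stage tables; plus candidate summary statistics and
# loaders for the packaged published-candidate fixtures.

#' Pipeline configuration
#'
#' All stage thresholds in one validated object. Unknown keys are
#' rejected. A resolved copy is written next to the outputs of
#' [run_pipeline()] for provenance.
#'
#' @param ... overrides of the defaults: `min_len` (18), `max_len` (30),
#'   `priority` ([DEFAULT_PRIORITY]), `polyA_min_frac` (0.9),
#'   `polyA_min_tail` (10), `allow_3p_trim` (0), `criteria`
#'   ([novel_criteria()]), `model` ([fold_energy_model()]),
#'   `max_mismatch` (3), `max_wobble` (Inf), `race_min_clones` (3),
#'   `race_min_fraction` (0.3).
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(min_len = 18L, max_len = 30L, priority = DEFAULT_PRIORITY,
              polyA_min_frac = 0.9, polyA_min_tail = 10L,
              allow_3p_trim = 0L, criteria = novel_criteria(),
              model = fold_energy_model(), max_mismatch = 3L,
              max_wobble = Inf, race_min_clones = 3L,
              race_min_fraction = 0.3)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop(sprintf("pipeline_config: unknown option '%s'", unknown[1L]),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full discovery pipeline over an input bundle
#'
#' Executes, in order: read loading and collapsing, length filtering,
#' ncRNA annotation, conserved-miRNA matching, novel-candidate discovery
#' and target scanning, writing one TSV per stage plus a summary and the
#' resolved configuration to `out_dir`. Deterministic given the inputs and
#' configuration: re-running produces byte-identical outputs.
#'
#' @param input_dir directory in the layout written by
#'   [write_sim_bundle()]: `reads.fa` (collapsed dialect), `known.fa`,
#'   `ests.fa` and optional `ncrna_<class>.fa` files.
#' @param out_dir output directory (created if needed).
#' @param config a `pipeline_config`.
#' @return invisibly, a list with the per-stage results (`distribution`,
#'   `annotation`, `families`, `candidates`, `targets`, `summary`,
#'   `stage_counts`).
#' @export
run_pipeline <- function(input_dir, out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reads_path <- file.path(input_dir, "reads.fa")
  if (!file.exists(reads_path)) {
    stop(sprintf("preprocess: missing input '%s'", reads_path), call. = FALSE)
  }
  reads <- tryCatch(read_collapsed_fasta(reads_path), error = function(e) {
    stop(sprintf("preprocess: %s", conditionMessage(e)), call. = FALSE)
  })
  if (nrow(reads) == 0L) {
    stop("preprocess: empty read file", call. = FALSE)
  }
  reads <- collapse_reads(reads)
  total_redundant <- sum(reads$count)

  flt <- filter_by_length(reads, config$min_len, config$max_len)
  stopifnot(nrow(flt$kept) + nrow(flt$discarded) == nrow(reads))
  kept <- flt$kept
  dist <- length_distribution(kept, config$min_len, config$max_len)
  write_table(dist, file.path(out_dir, "length_distribution.tsv"))

  ncrna_files <- list.files(input_dir, pattern = "^ncrna_.*\\.fa$",
                            full.names = TRUE)
  class_refs <- stats::setNames(
    as.list(ncrna_files),
    sub("^ncrna_(.*)\\.fa$", "\\1", basename(ncrna_files)))
  index <- build_reference_index(class_refs)
  cls <- classify_reads(kept, index, config$priority,
                        config$polyA_min_frac, config$polyA_min_tail)
  ann <- annotation_summary(kept, cls)
  write_table(ann, file.path(out_dir, "annotation_summary.tsv"))
  write_table(data.frame(id = kept$id, seq = kept$seq, count = kept$count,
                         class = cls, stringsAsFactors = FALSE),
              file.path(out_dir, "read_classes.tsv"))

  known_path <- file.path(input_dir, "known.fa")
  known <- if (file.exists(known_path)) {
    k <- read_sequences(known_path)
    data.frame(name = k$id, seq = k$seq, stringsAsFactors = FALSE)
  } else {
    data.frame(name = character(0), seq = character(0))
  }
  clean <- kept[cls == "unannotated", , drop = FALSE]
  matches <- if (nrow(known) > 0L) {
    match_known(clean, known, config$allow_3p_trim)
  } else {
    NULL
  }
  families <- if (!is.null(matches) && nrow(matches) > 0L) {
    family_abundance(matches)
  } else {
    data.frame(family = character(0), member_count = integer(0),
               redundant_reads = numeric(0),
               fraction_of_conserved = numeric(0))
  }
  write_table(families, file.path(out_dir, "conserved_families.tsv"))

  ests_path <- file.path(input_dir, "ests.fa")
  candidates <- if (file.exists(ests_path)) {
    ests <- read_sequences(ests_path)
    discover_novel(clean, data.frame(id = ests$id, seq = ests$seq),
                   known, config$criteria, config$model)
  } else {
    empty_candidates()
  }
  cand_out <- candidates
  if (nrow(cand_out) > 0L) {
    cand_out <- cbind(id = sprintf("cand%d", seq_len(nrow(cand_out))),
                      cand_out)
  }
  write_table(cand_out, file.path(out_dir, "novel_candidates.tsv"))
  if (nrow(candidates) > 0L) {
    writeLines(as.vector(rbind(paste0(">", cand_out$id, " ",
                                      candidates$precursor_id),
                               candidates$precursor_seq,
                               candidates$dotbracket)),
               file.path(out_dir, "novel_structures.txt"))
  }

  target_hits <- empty_target_hits()
  if (nrow(candidates) > 0L && file.exists(ests_path)) {
    ests <- read_sequences(ests_path)
    tdf <- data.frame(id = ests$id, seq = ests$seq, stringsAsFactors = FALSE)
    hits <- lapply(candidates$mature_seq, scan_targets, transcripts = tdf,
                   max_mismatch = config$max_mismatch,
                   max_wobble = config$max_wobble)
    target_hits <- do.call(rbind, hits)
  }
  write_table(target_hits, file.path(out_dir, "target_hits.tsv"))

  summary <- summarize_candidates(candidates)
  stage_counts <- data.frame(
    stage = c("input_unique", "input_redundant", "kept_unique",
              "unannotated_unique", "conserved_matched_unique",
              "novel_candidates", "target_hits"),
    n = c(nrow(reads), total_redundant, nrow(kept), nrow(clean),
          if (is.null(matches)) 0L else length(unique(matches$seq)),
          nrow(candidates), nrow(target_hits)),
    stringsAsFactors = FALSE)
  write_table(stage_counts, file.path(out_dir, "stage_counts.tsv"))
  write_table(data.frame(
    n_candidates = summary$n_candidates,
    n_five_prime_u = summary$n_five_prime_u,
    n_star_supported = summary$n_star_supported,
    star_supported_percent = summary$star_supported_percent),
    file.path(out_dir, "candidate_summary.tsv"))

  resolved <- unclass(config)
  resolved$priority <- as.list(resolved$priority)
  resolved$max_wobble <- if (is.infinite(resolved$max_wobble)) ".inf" else
    resolved$max_wobble
  yaml::write_yaml(resolved, file.path(out_dir, "config_resolved.yaml"))

  invisible(list(distribution = dist, annotation = ann,
                 families = families, candidates = candidates,
                 targets = target_hits, summary = summary,
                 stage_counts = stage_counts))
}

empty_target_hits <- function() {
  data.frame(mirna_seq = character(0), transcript_id = character(0),
             strand = character(0), site_start = integer(0),
             site_end = integer(0), site_seq = character(0),
             mismatches = integer(0), wobbles = integer(0),
             stringsAsFactors = FALSE)
}

#' Summary statistics of a novel-candidate set
#'
#' Tallies the candidate count, how many matures begin with a 5' uridine
#' (a hallmark of plant miRNAs) and how many carry sequenced miRNA*
#' support. Accepts either a [discover_novel()] result (`mature_seq`,
#' `star_seq` columns) or a table with `sequence` and a yes/no or logical
#' `star` column, such as the packaged published-candidate fixture.
#'
#' @param candidates candidate data.frame (zero rows allowed).
#' @return list with `n_candidates`, `n_five_prime_u`, `n_star_supported`,
#'   `star_supported_percent` (`NA` for an empty set).
#' @export
summarize_candidates <- function(candidates) {
  seqs <- if ("mature_seq" %in% names(candidates)) candidates$mature_seq
          else candidates$sequence
  star <- if ("star_seq" %in% names(candidates)) {
    !is.na(candidates$star_seq)
  } else if ("star" %in% names(candidates)) {
    if (is.logical(candidates$star)) candidates$star
    else tolower(candidates$star) %in% c("yes", "true", "1")
  } else {
    rep(FALSE, nrow(candidates))
  }
  n <- nrow(candidates)
  n5u <- sum(startsWith(rna_normalize(seqs), "U"))
  nstar <- sum(star)
  list(n_candidates = n, n_five_prime_u = n5u, n_star_supported = nstar,
       star_supported_percent = if (n > 0L) 100 * nstar / n else NA_real_)
}

#' The ten published novel miRNA candidates of trifoliate orange
#'
#' The reported novel candidate table for *Citrus trifoliata*: mature
#' sequence, precursor EST accession, A+U%, the reported folding score,
#' precursor arm, mature and precursor lengths, read count, and whether a
#' miRNA* was sequenced. Packaged for regression tests of the
#' desk-reproducible sequence facts.
#'
#' @return data.frame with 10 rows.
#' @export
published_novel_candidates <- function() {
  path <- system.file("extdata", "ctrifoliata_novel_mirnas.tsv",
                      package = "mirseekr", mustWork = TRUE)
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  out$star <- out$star == "Yes"
  out
}

#' The four published validated miRNA:target duplexes of trifoliate orange
#'
#' Mature miRNA and target-site sequences (both 5'->3') for the four
#' RACE-validated target sites, with the reported mismatch count.
#'
#' @return data.frame with 4 rows: `mirna_id`, `mirna_seq`,
#'   `target_unigene`, `site_seq`, `reported_mismatches`.
#' @export
published_target_duplexes <- function() {
  path <- system.file("extdata", "ctrifoliata_target_duplexes.tsv",
                      package = "mirseekr", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
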