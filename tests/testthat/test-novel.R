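test_that("reads map to exact transcript occurrences on both strands", {
  set.seed(61)
  read <- rand_rna(21)
  est <- paste0(rand_rna(100), read, rand_rna(100))
  ests <- data.frame(id = c("est1", "est2"),
                     seq = c(est, rand_rna(150)))
  loci <- map_to_transcripts(read, ests)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$transcript_id, "est1")
  expect_equal(loci$start, 101L)
  expect_equal(loci$strand, "+")

  # an occurrence of the reverse complement is reported on '-'
  rc_est <- data.frame(id = "est3",
                       seq = paste0(rand_rna(50), naive_revcomp(read),
                                    rand_rna(30)))
  rc <- map_to_transcripts(read, rc_est)
  expect_equal(rc$start, 51L)
  expect_equal(rc$strand, "-")

  expect_equal(nrow(map_to_transcripts(rand_rna(22), ests)), 0L)
})

test_that("window excision clips at transcript ends and respects the ladder", {
  tseq <- rand_rna(400)
  near_end <- excise_candidate_windows(tseq, start = 10, mature_len = 21)
  expect_true(all(near_end$win_start == 1L))        # upstream clipped to 9 nt
  expect_true(all(near_end$mature_offset == 10L))

  small <- excise_candidate_windows(tseq, 200, 21, max_flank = 40L)
  expect_lte(nrow(small), 4L)                       # {20,40} x {20,40}

  set.seed(62)
  for (t in 1:20) {
    s <- sample(380, 1)
    wins <- excise_candidate_windows(tseq, s, 21)
    expect_true(all(wins$win_start <= s & wins$win_end >= s + 20))
    expect_false(any(duplicated(paste(wins$win_start, wins$win_end))))
  }
})

test_that("planted precursors are accepted with the planted arm and star", {
  set.seed(63)
  for (arm in c("5'", "3'")) {
    hp <- make_hairpin_precursor(rand_rna(21), arm)
    window <- paste0(strrep("A", 30), hp$precursor, strrep("A", 30))
    ev <- evaluate_candidate(window, 30 + hp$mature_span[1], 21)
    expect_true(ev$accepted)
    expect_equal(ev$arm, arm)
    expect_equal(ev$star_span - 30L, hp$star_span)
    expect_lte(ev$unpaired_mature, 6L)
    expect_lte(ev$duplex_mismatches, 6L)
  }
})

test_that("a mature straddling the terminal loop is rejected", {
  set.seed(64)
  hp <- make_hairpin_precursor(rand_rna(21), "5'")
  # centre a 21-nt span on the loop: it has positions on both arms
  loop_centre <- hp$mature_span[2] + 4L
  ev <- evaluate_candidate(hp$precursor, loop_centre - 10L, 21)
  expect_false(ev$accepted)
  expect_equal(ev$reason, "mature_in_loop")
})

test_that("windows of random sequence are almost always rejected", {
  set.seed(1234)
  rejected <- 0L
  for (t in 1:100) {
    w <- rand_rna(100)
    ev <- evaluate_candidate(w, 40, 21)
    if (!ev$accepted) rejected <- rejected + 1L
  }
  expect_gte(rejected, 95L)
})

test_that("rejection reasons are machine-readable", {
  expect_equal(evaluate_candidate(rand_rna(40), 10, 21)$reason,
               "lp_out_of_range")
  set.seed(65)
  ev <- evaluate_candidate(strrep("A", 60), 20, 21)
  expect_equal(ev$reason, "not_hairpin")
})

test_that("the computed star region carries a 2-nt 3' overhang", {
  set.seed(66)
  for (arm in c("5'", "3'")) {
    mature <- rand_rna(21)
    hp <- make_hairpin_precursor(mature, arm)
    ev <- evaluate_candidate(hp$precursor, hp$mature_span[1], 21)
    star <- substr(hp$precursor, ev$star_span[1], ev$star_span[2])
    # star core is the reverse complement of mature[1..19]; the final two
    # positions are the unpaired 3' overhang
    expect_equal(substr(star, 1, 19), naive_revcomp(substr(mature, 1, 19)))
    expect_equal(nchar(star), 21L)
    reads <- data.frame(seq = c(star, rand_rna(21)), count = c(9L, 1L))
    found <- find_star(hp$precursor, ev$star_span, reads)
    expect_equal(found$star_seq, star)
    expect_equal(found$star_count, 9L)
    absent <- find_star(hp$precursor, ev$star_span,
                        data.frame(seq = rand_rna(21), count = 1L))
    expect_true(is.na(absent$star_seq))
    expect_equal(absent$star_count, 0L)
  }
})

test_that("reads matching known matures are excluded from discovery", {
  sim <- small_sim(seed = 67, n_novel = 2)
  known_as_reads <- data.frame(seq = sim$known$seq[1:10],
                               count = rep(5L, 10))
  out <- discover_novel(known_as_reads, sim$ests, sim$known)
  expect_equal(nrow(out), 0L)
})

test_that("noise-free planted libraries are recovered perfectly across seeds", {
  for (seed in c(7L, 101L)) {
    sim <- simulate_library(sim_config(
      seed = seed, n_conserved = 0L, n_novel = 10L, n_decoy_reads = 0L,
      ncrna_class_reads = c(rRNA = 0L), n_polyA = 0L, n_known = 20L))
    out <- discover_novel(sim$reads, sim$ests, sim$known)
    truth <- sim$truth$novel
    expect_setequal(out$mature_seq, truth$mature_seq)
    m <- match(out$mature_seq, truth$mature_seq)
    expect_equal(out$precursor_id, truth$est_id[m])
    expect_equal(out$arm, truth$arm[m])
    expect_equal(out$read_count, truth$mature_count[m])
    expect_equal(out$five_prime_u, startsWith(out$mature_seq, "U"))
    # star support equals the generator's emission decisions
    expect_equal(!is.na(out$star_seq), truth$star_emitted[m])
    expect_equal(out$star_count[truth$star_emitted[m]],
                 truth$star_count[m][truth$star_emitted[m]])
    # the reported arm matches the structural side of the terminal loop
    for (i in seq_len(nrow(out))) {
      h <- is_hairpin(fold_rna(out$precursor_seq[i]))
      ms <- regexpr(out$mature_seq[i], out$precursor_seq[i], fixed = TRUE)
      side <- h$arm_map[as.integer(ms)]
      expect_equal(unname(side), if (out$arm[i] == "5'") "5arm" else "3arm")
    }
    expect_false(is.unsorted(rev(out$read_count)))  # sorted descending
  }
})

test_that("tightening any single criterion never accepts more windows", {
  set.seed(68)
  windows <- list()
  for (t in 1:8) {
    hp <- make_hairpin_precursor(rand_rna(21), sample(c("5'", "3'"), 1))
    windows[[t]] <- list(seq = paste0(strrep("A", 15), hp$precursor,
                                      strrep("A", 15)),
                         off = 15 + hp$mature_span[1])
  }
  for (t in 9:16) {
    windows[[t]] <- list(seq = rand_rna(120), off = 50)
  }
  n_accept <- function(criteria) {
    sum(vapply(windows, function(w) {
      isTRUE(evaluate_candidate(w$seq, w$off, 21, criteria)$accepted)
    }, logical(1)))
  }
  base <- n_accept(novel_criteria())
  tighter <- list(
    novel_criteria(min_mfei = 0.9),
    novel_criteria(max_unpaired_mature = 1L),
    novel_criteria(max_duplex_mismatches = 1L),
    novel_criteria(min_lp = 100L),
    novel_criteria(max_lp = 90L),
    novel_criteria(min_au = 45),
    novel_criteria(max_au = 55))
  for (crit in tighter) expect_lte(n_accept(crit), base)
})
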