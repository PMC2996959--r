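test_that("precursor construction follows the stem-loop arithmetic", {
  set.seed(91)
  hp <- make_hairpin_precursor(rand_rna(21), "5'", loop_len = 6,
                               stem_mismatches = 0, flank_len = 15)
  expect_equal(nchar(hp$precursor), 21 + 6 + 21 + 30)  # 78 nt
  expect_true(hp$mature_span[2] < hp$star_span[1])     # 5' arm: mature first
  hp3 <- make_hairpin_precursor(rand_rna(21), "3'")
  expect_true(hp3$star_span[2] < hp3$mature_span[1])
  expect_equal(substr(hp$precursor, hp$mature_span[1], hp$mature_span[2]),
               substr(hp$precursor, 16, 36))
  expect_error(make_hairpin_precursor(rand_rna(10), "5'"))
  expect_error(make_hairpin_precursor(rand_rna(21), "5'", loop_len = 3),
               "loop_len")
})

test_that("stem mismatches place non-pairing substitutions in the star", {
  set.seed(92)
  mature <- rand_rna(21)
  hp <- make_hairpin_precursor(mature, "5'", stem_mismatches = 3)
  core <- substr(hp$star_seq, 1, 19)
  clean <- naive_revcomp(substr(mature, 1, 19))
  diff <- which(strsplit(core, "")[[1]] != strsplit(clean, "")[[1]])
  expect_equal(length(diff), 3L)
  expect_false(1L %in% diff || 19L %in% diff)  # non-terminal positions
})

test_that("identical configurations write byte-identical bundles", {
  cfg <- sim_config(seed = 17L, n_conserved = 3L, n_novel = 2L,
                    n_decoy_reads = 30L,
                    ncrna_class_reads = c(rRNA = 10L), n_polyA = 3L,
                    n_known = 10L, n_est = 3L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim_bundle(simulate_library(cfg), d1)
  write_sim_bundle(simulate_library(cfg), d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_setequal(f1, f2)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # a different seed changes the reads
  cfg2 <- cfg; cfg2$seed <- 18L
  d3 <- withr::local_tempdir()
  write_sim_bundle(simulate_library(cfg2), d3)
  expect_false(unname(tools::md5sum(file.path(d1, "reads.fa"))) ==
               unname(tools::md5sum(file.path(d3, "reads.fa"))))
})

test_that("the ledger covers every emitted read exactly once", {
  sim <- small_sim(seed = 93)
  truth <- sim$truth$reads
  expect_equal(anyDuplicated(truth$seq), 0L)
  expect_setequal(sim$reads$seq, truth$seq)
  m <- match(sim$reads$seq, truth$seq)
  expect_equal(sim$reads$count, truth$count[m])
  expect_true(all(truth$class %in%
    c("conserved_mirna", "novel_mature", "novel_star", "rRNA", "tRNA",
      "snRNA", "snoRNA", "exon", "intron", "repeat", "polyA_artifact",
      "decoy")))
})

test_that("read lengths have their two largest modes at 21 and 24 nt", {
  sim <- simulate_library(sim_config(
    seed = 94L, n_conserved = 0L, n_novel = 0L, n_decoy_reads = 3000L,
    ncrna_class_reads = c(rRNA = 0L), n_polyA = 0L, n_known = 5L,
    n_est = 1L))
  tab <- table(nchar(sim$reads$seq))
  top2 <- names(sort(tab, decreasing = TRUE))[1:2]
  expect_setequal(top2, c("21", "24"))
  expect_equal(names(which.max(tab)), "24")
})

test_that("degenerate configurations produce only the planted reads", {
  sim <- simulate_library(sim_config(
    seed = 95L, n_conserved = 2L, n_novel = 2L, n_decoy_reads = 0L,
    ncrna_class_reads = c(rRNA = 0L), n_polyA = 0L, n_known = 5L,
    n_est = 2L))
  expect_true(all(sim$truth$reads$class %in%
    c("conserved_mirna", "novel_mature", "novel_star")))
  expect_equal(sum(sim$truth$reads$class == "novel_mature"), 2L)
})

test_that("race clone simulation plants the canonical terminus", {
  set.seed(96)
  target <- rand_rna(300)
  mirna <- rand_rna(21)
  substr(target, 150, 170) <- naive_revcomp(mirna)
  sim <- simulate_race_clones(target, 150L, 170L, mirna, n_clones = 15L,
                              noise_fraction = 0.2, seed = 97L)
  expect_equal(nrow(sim$clones), 15L)
  expect_equal(sim$truth$cleavage_position, 170L - 10L + 1L)
  expect_equal(sum(sim$truth$termini == sim$truth$cleavage_position) >= 12L,
               TRUE)  # ceiling(0.8 * 15) canonical clones
  expect_true(all(substring(target, sim$truth$termini) == sim$clones$seq))
  # zero noise: one terminus only
  s0 <- simulate_race_clones(target, 150L, 170L, mirna, noise_fraction = 0,
                             seed = 98L)
  expect_equal(length(unique(s0$truth$termini)), 1L)
})
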