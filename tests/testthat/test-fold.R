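test_that("sequences with no possible pair fold to the open chain", {
  f <- fold_rna("AAAAAAA")
  expect_equal(f$dotbracket, ".......")
  expect_equal(f$energy, 0)
})

test_that("a perfect short stem folds to its known optimum", {
  f <- fold_rna("GGGAAACCC")
  expect_equal(f$dotbracket, "(((...)))")
  expect_equal(f$energy, -9)
})

test_that("DP optimum equals exhaustive enumeration on small sequences", {
  set.seed(2024)
  for (t in 1:100) {
    s <- rand_rna(sample(5:12, 1))
    expect_equal(fold_rna(s)$energy, brute_force_fold_energy(s),
                 tolerance = 1e-12, info = s)
  }
})

test_that("structures are well-formed over random inputs", {
  set.seed(3)
  for (t in 1:50) {
    s <- rand_rna(sample(10:60, 1))
    f <- fold_rna(s)
    expect_equal(nchar(f$dotbracket), nchar(s))
    ch <- strsplit(f$dotbracket, "")[[1]]
    expect_equal(sum(ch == "("), sum(ch == ")"))
    expect_lte(f$energy, 0)
    # every pair is WC or wobble and hairpin loops span >= 3 nt
    ptn <- mirseekr:::dotbracket_pairs(f$dotbracket)
    sch <- strsplit(s, "")[[1]]
    for (i in which(ptn > seq_along(ptn))) {
      expect_true(pair_class(sch[i], sch[ptn[i]]) != "mismatch")
      expect_gte(ptn[i] - i - 1, 3)
    }
  }
})

test_that("energy decreases (weakly) as pair energies strengthen", {
  set.seed(4)
  strong <- fold_energy_model(gc = -6, au = -4, gu = -2)
  for (t in 1:20) {
    s <- rand_rna(40)
    expect_lte(fold_rna(s, strong)$energy, fold_rna(s)$energy)
  }
})

test_that("fold input validation rejects bad alphabets and lengths", {
  expect_error(fold_rna("ACGT"), "A,C,G,U")
  expect_error(fold_rna(""), "length")
  expect_error(fold_rna(strrep("A", 1001)), "length")
})

test_that("hairpin metrics follow their defining formulas", {
  # forced arithmetic: length 100, energy -50, GC 50%
  st <- structure(list(seq = strrep("GCAU", 25),
                       dotbracket = strrep(".", 100), energy = -50),
                  class = "rna_structure")
  m <- hairpin_metrics(st)
  expect_equal(m$amfe, 50)
  expect_equal(m$mfei, 1)
  expect_equal(m$au_percent, 50)
  expect_equal(m$precursor_len, 100)

  all_au <- structure(list(seq = strrep("AU", 10),
                           dotbracket = strrep(".", 20), energy = 0),
                      class = "rna_structure")
  expect_error(hairpin_metrics(all_au), "GC")
})

test_that("metrics agree with independent recomputation on folded RNAs", {
  set.seed(5)
  for (t in 1:50) {
    s <- rand_rna(sample(40:120, 1))
    f <- fold_rna(s)
    m <- hairpin_metrics(f)
    ch <- strsplit(s, "")[[1]]
    gc_pct <- 100 * sum(ch %in% c("G", "C")) / length(ch)
    expect_equal(m$au_percent, 100 - gc_pct, tolerance = 1e-9)
    expect_equal(m$amfe, abs(f$energy) * 100 / length(ch), tolerance = 1e-9)
    expect_equal(m$mfei, m$amfe / gc_pct, tolerance = 1e-9)
  }
})

test_that("hairpin detection and arm map follow the terminal loop", {
  hp <- is_hairpin(fold_rna("GGGAAACCC"))
  expect_true(hp$is_hairpin)
  expect_equal(hp$arm_map, c(rep("5arm", 3), rep("loop", 3), rep("3arm", 3)))
  expect_equal(hp$loop_span, c(4L, 7L - 1L))

  two_stems <- structure(list(seq = "GGAAACCGGAAACC",
                              dotbracket = "((...))((...))", energy = -8),
                         class = "rna_structure")
  expect_false(is_hairpin(two_stems)$is_hairpin)
  open <- structure(list(seq = "AAAA", dotbracket = "....", energy = 0),
                    class = "rna_structure")
  expect_false(is_hairpin(open)$is_hairpin)
})

test_that("generator-planted precursors fold to single hairpins with the planted arm", {
  # the generator's emitted precursors (extracted back out of the ESTs)
  # must satisfy the structural contract recorded in its ledger
  n_checked <- 0L
  for (seed in c(131L, 132L)) {
    sim <- simulate_library(sim_config(
      seed = seed, n_conserved = 0L, n_novel = 50L, n_decoy_reads = 0L,
      ncrna_class_reads = c(rRNA = 0L), n_polyA = 0L, n_known = 5L,
      n_est = 50L))
    truth <- sim$truth$novel
    for (i in seq_len(nrow(truth))) {
      est_seq <- sim$ests$seq[sim$ests$id == truth$est_id[i]]
      prec <- substr(est_seq, truth$precursor_start[i], truth$precursor_end[i])
      h <- is_hairpin(fold_rna(prec))
      expect_true(h$is_hairpin)
      anchor <- truth$mature_start[i] - truth$precursor_start[i] + 1L
      anchor <- if (truth$arm[i] == "5'") anchor else anchor + truth$lm[i] - 1L
      expect_equal(unname(h$arm_map[anchor]),
                   if (truth$arm[i] == "5'") "5arm" else "3arm")
      n_checked <- n_checked + 1L
    }
  }
  expect_equal(n_checked, 100L)
})
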