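test_that("clone ends map by unique anchor prefix", {
  set.seed(81)
  target <- rand_rna(300)
  clones <- data.frame(id = c("c1", "c2"),
                       seq = c(substring(target, 120), substring(target, 45)))
  mp <- map_clone_ends(clones, target)
  expect_equal(mp$termini$position[mp$termini$id == "c1"], 120L)
  expect_equal(mp$termini$position[mp$termini$id == "c2"], 45L)

  # a clone whose anchor occurs twice is ambiguous and excluded
  dup_target <- paste0(substr(target, 1, 40), substr(target, 1, 40),
                       rand_rna(100))
  amb <- map_clone_ends(data.frame(id = "c3", seq = substr(target, 1, 60)),
                        dup_target)
  expect_equal(nrow(amb$termini), 0L)
  expect_equal(amb$ambiguous, "c3")
  # unmapped clones are reported separately
  um <- map_clone_ends(data.frame(id = "c4", seq = rand_rna(40)), target)
  expect_equal(um$unmatched, "c4")
})

test_that("the cleavage window is centred, inclusive, and tallies counts", {
  pr <- cleavage_profile(c(150L), 140L, 160L, window = 100L)
  expect_equal(pr$center, 150L)
  expect_equal(pr$in_window_clones, 1L)
  # 51 nt past the midpoint is outside a 100-nt window; 50 nt is inside
  pr2 <- cleavage_profile(c(201L, 200L, 99L), 140L, 160L, window = 100L)
  expect_equal(pr2$in_window_clones, 1L)
  expect_equal(pr2$counts$position, 200L)
  expect_equal(pr2$total_clones, 3L)

  set.seed(82)
  pos <- sample(1:400, 200, replace = TRUE)
  pr3 <- cleavage_profile(pos, 140L, 160L)
  naive <- pos[pos >= 100 & pos <= 200]
  expect_equal(pr3$in_window_clones, length(naive))
  expect_equal(sum(pr3$counts$count), pr3$in_window_clones)
  expect_setequal(pr3$counts$position, unique(naive))
})

test_that("cleavage calls report the modal terminus and pairing index", {
  mirna <- strrep("U", 21)
  # all 15 clones at the position pairing miRNA nt 10
  site_start <- 140L; site_end <- 160L
  pos <- rep(site_end - 10L + 1L, 15L)
  cl <- call_cleavage(cleavage_profile(pos, site_start, site_end), mirna)
  expect_equal(cl$mirna_pairing_index, 10L)
  expect_equal(cl$modal_fraction, 1)
  expect_true(cl$validated)

  # two clones never validate under the default min_clones = 3
  cl2 <- call_cleavage(cleavage_profile(rep(151L, 2L), site_start, site_end),
                       mirna)
  expect_false(cl2$validated)
  expect_error(call_cleavage(cleavage_profile(integer(0), site_start,
                                              site_end), mirna),
               "no in-window")
})

test_that("the pairing index is invariant under coordinate translation", {
  set.seed(83)
  termini <- sample(130:170, 30, replace = TRUE)
  base <- call_cleavage(cleavage_profile(termini, 140L, 160L), strrep("A", 21))
  for (shift in c(50L, 1000L)) {
    moved <- call_cleavage(cleavage_profile(termini + shift, 140L + shift,
                                            160L + shift), strrep("A", 21))
    expect_equal(moved$mirna_pairing_index, base$mirna_pairing_index)
    expect_equal(moved$modal_fraction, base$modal_fraction)
  }
})

test_that("simulated clone sets recover the planted cleavage site", {
  for (seed in 6:8) {
    b <- simulate_race_bundle(seed)
    mp <- map_clone_ends(b$clones, b$target)
    expect_equal(length(mp$ambiguous), 0L)
    pr <- cleavage_profile(mp$termini, b$site_start, b$site_end)
    cl <- call_cleavage(pr, b$mirna)
    expect_equal(cl$modal_position, b$truth$cleavage_position)
    expect_equal(cl$mirna_pairing_index, b$truth$pairing_index)
  }
  # zero noise puts every terminus at the planted coordinate
  b0 <- simulate_race_bundle(9, noise_fraction = 0)
  mp0 <- map_clone_ends(b0$clones, b0$target)
  expect_equal(length(unique(mp0$termini$position)), 1L)
  cl0 <- call_cleavage(cleavage_profile(mp0$termini, b0$site_start,
                                        b0$site_end), b0$mirna)
  expect_equal(cl0$modal_fraction, 1)
})

test_that("the cleavage diagram marks in-site termini", {
  b <- simulate_race_bundle(10)
  mp <- map_clone_ends(b$clones, b$target)
  pr <- cleavage_profile(mp$termini, b$site_start, b$site_end)
  txt <- render_cleavage_diagram(pr, b$mirna, b$target)
  expect_match(txt, "v")
  expect_match(txt, "pos [0-9]+: [0-9]+/")
})
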