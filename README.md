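# mirseekr

Discovery of conserved and novel plant miRNAs from deep-sequenced small-RNA
libraries, for species without a reference genome.

Plant miRNA surveys in non-model species — the motivating case is trifoliate
orange (*Citrus trifoliata*), an important citrus rootstock — follow a
standard desk workflow once the sequencing provider hands back
adapter-trimmed reads:

1. **Preprocess** — collapse raw reads into unique sequences with redundant
   counts and keep the 18–30 nt size window.
2. **Annotate** — partition reads into ncRNA classes (rRNA, tRNA, snRNA,
   snoRNA, exon, intron, repeat) by exact substring matching against
   per-class reference sets, remove polyA artifacts, and pass un-annotated
   reads on.
3. **Conserved miRNAs** — a read is a conserved miRNA iff it is *identical*
   to a known mature sequence (miRBase-style set); matches are grouped into
   `miR<number>` families and profiled by abundance.
4. **Novel miRNAs** — because no genome is available, un-annotated,
   non-conserved reads are mapped onto EST/transcript sequences; windows
   around each locus are excised, folded, and kept when they form a single
   stem-loop satisfying the standard plant precursor criteria
   (precursor length, A+U%, and MFEI = AMFE / GC%, where
   AMFE = |MFE| / length x 100), with detection of sequenced miRNA*
   partners (2-nt 3' overhang geometry).
5. **Targets** — candidate miRNAs are scanned against transcripts by
   ungapped antiparallel complementarity with a mismatch budget
   (default < 4, i.e. at most 3), counting G:U wobbles as pairings rather
   than mismatches.
6. **RACE** — 5'-RACE clone ends are mapped onto a predicted target and the
   cleavage site is called; validated plant miRNA cleavage canonically falls
   opposite the miRNA's 10th nucleotide from its 5' end.

RNA folding uses an in-package Nussinov-style dynamic program over a
per-pair energy model (G:C −3, A:U −2, G:U −1 kcal/mol, minimum loop 3 nt)
with a deterministic traceback, so results are bit-stable; MFEI thresholds
are calibrated to this model (see the methods vignette). A synthetic-data
generator (`simulate_library`, `simulate_race_clones`) produces complete
input bundles with a ground-truth ledger, so every stage is testable by
planted-element recovery.

## Worked example

Simulate a small study, run the pipeline, and summarize:

```r
library(mirseekr)

sim <- simulate_library(sim_config(seed = 42, n_novel = 10,
                                   n_conserved = 20, n_decoy_reads = 5000))
dir.create("bundle"); dir.create("out")
write_sim_bundle(sim, "bundle")
res <- run_pipeline("bundle", "out")

res$stage_counts
#>                      stage       n
#> 1             input_unique    5877
#> 2          input_redundant 2500394
#> 3              kept_unique    5877
#> 4       unannotated_unique    5037
#> 5 conserved_matched_unique      20
#> 6         novel_candidates      10
#> 7              target_hits      10

res$summary
#> $n_candidates
#> [1] 10
#> $n_five_prime_u
#> [1] 2
#> $n_star_supported
#> [1] 7
#> $star_supported_percent
#> [1] 70
```

All 20 planted conserved miRNAs and all 10 planted novel precursors are
recovered (the ledger in `sim$truth` is the reference), each novel
candidate reporting its precursor, arm, MFEI and any sequenced miRNA*.
A single duplex check reproduces a published validated target site — the
NB-LRR disease-resistance transcript site of ctr-miRn2 — with zero
mismatches:

```r
count_mismatches("UUAAGAUUGAGUUACCAUCAU", "AUGAUGGUAACUCAAUCUUAA")
#> $mismatches
#> [1] 0
#> $wobbles
#> [1] 0
#> $watson_crick
#> [1] 21
```

And cleavage mapping on simulated RACE clones recovers the canonical
tenth-nucleotide rule:

```r
b <- simulate_race_bundle(seed = 7)
mp <- map_clone_ends(b$clones, b$target)
cl <- call_cleavage(cleavage_profile(mp$termini, b$site_start, b$site_end),
                    b$mirna)
cl$mirna_pairing_index
#> [1] 10
```

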