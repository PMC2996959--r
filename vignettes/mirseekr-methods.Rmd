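---
title: "Methods: models, criteria and design choices in mirseekr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, criteria and design choices in mirseekr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mirseekr implements the desk half of a plant small-RNA miRNA survey for a
species without a reference genome: annotation filtering of collapsed
reads, conserved-miRNA identification, hairpin-based novel-miRNA discovery
from transcripts, complementarity-based target prediction, and
5'-RACE cleavage-site mapping. This vignette records the models behind
each stage, the tunable parameters and their defaults, what the synthetic
data emulates, and the design choices that were genuinely open.

## Read preprocessing and annotation

Reads are collapsed to unique sequences carrying redundant counts and
restricted to the inclusive 18–30 nt window in which plant miRNAs and
siRNAs fall; both bounds are parameters (`min_len`, `max_len`). Collapsed
output is sorted by descending count with lexicographic tie-breaks so that
every downstream file is reproducible byte for byte.

Annotation assigns each read to at most one ncRNA class by **exact,
ungapped, full-read substring containment** in user-supplied per-class
reference sets, searched on both the given strand and its reverse
complement (reference strand conventions vary). Exact matching is the
strictest reproducible reading of "compared against ncRNA databases"; it
deliberately avoids alignment heuristics whose parameters would dominate
the outcome. Classes are tried in a configurable priority order (default
rRNA > tRNA > snRNA > snoRNA > exon > intron > repeat) because published
pipelines disagree on the removal order; the polyA-artifact test runs
first. A read is a polyA artifact when its A fraction is at least 0.9 or
it ends in a run of at least 10 A's — the filtering literature names the
artifact but no thresholds, so these are package defaults, both
configurable.

## Conserved miRNAs

A read is a conserved miRNA iff it is *identical* — same length, same
sequence — to an entry of the known mature set. This is the strict reading
of "perfect match" identification. Because sRNA libraries commonly contain
3'-trimmed isoforms, `allow_3p_trim` (default 0) optionally admits reads
shorter by up to N nt at the 3' end. Families are the `miR<number>` token
of the name with species prefix and variant suffixes stripped; related
families (e.g. miR165 vs miR166) are never merged, matching how surveys
list them separately.

## The folding model

Novel-miRNA discovery needs a secondary-structure predictor. mirseekr
ships its own: a Nussinov-style dynamic program minimizing a per-pair
energy over all nested structures, with defaults G:C −3, A:U −2, G:U −1
kcal/mol and a minimum hairpin loop of 3 unpaired nt. The traceback is
deterministic — pairing the leftmost position with its smallest admissible
partner is preferred over leaving it unpaired — so structures are
bit-stable across platforms. The dynamic program is verified against
exhaustive enumeration of all nested structures on small sequences.

This model is *not* the Turner nearest-neighbor model: it has no stacking,
no loop penalties, and its energies are not comparable to
thermodynamic MFEs. Two consequences matter:

* **MFEI calibration.** The standard plant precursor index
  MFEI = AMFE / GC% (AMFE = |MFE|/length × 100) is computed on this
  model's energy scale, so the acceptance threshold `min_mfei` defaults to
  0.5 rather than the 0.85 used with thermodynamic folders. A
  thermodynamic folder can be substituted by passing a different energy
  model or replacing `fold_rna` behind the same interface, in which case
  thermodynamic MFEI thresholds become appropriate.
* **Structural permissiveness.** Without stacking or loop penalties, any
  single admissible pair lowers the energy, so random flanking sequence
  folds into branched decorations far more readily than under a
  thermodynamic model. The synthetic-data design below exists to keep
  planted structures unambiguous despite this.

A *single hairpin* is a structure whose pairs are totally ordered by
containment (exactly one terminal loop, no multiloop). The arm map labels
positions 5'-arm / loop / 3'-arm relative to the innermost pair.

## Novel-candidate criteria

For each un-annotated, non-conserved read mapped exactly onto a transcript
(either orientation), a deterministic ladder of windows — flanks
{20, 40, …, `max_flank` = 250} nt on each side independently, clipped and
deduplicated — is excised and folded. A window is accepted iff all of:

* the structure is a single hairpin;
* the mature lies on one arm. It may overlap the unpaired terminal-loop
  region by a few nucleotides but must not straddle the loop onto the
  other arm nor lie wholly within the loop. The overlap allowance is
  deliberate: a mature:star duplex with canonical 2-nt 3' overhangs
  *necessarily* leaves the mature's terminal nucleotides unpaired adjacent
  to the loop, so demanding strict containment within the paired arm would
  reject every textbook precursor;
* at most `max_unpaired_mature` = 6 mature positions are unpaired, and at
  most `max_duplex_mismatches` = 6 positions of the inferred star region
  are unpaired;
* precursor length within [`min_lp` = 50, `max_lp` = 300] nt;
* A+U% within [`min_au` = 20, `max_au` = 80] — wide bounds, because
  published accepted candidates span roughly 47–71%;
* MFEI at least `min_mfei` = 0.5 (this model's scale, above).

Among a locus's accepted windows the highest MFEI wins. The star region is
derived from the structure by antiparallel duplex geometry — it spans
`[partner(mature_end − 2), partner(mature_start) + 2]`, the same formula
on either arm — and a star is "sequenced" when a read equal to that span
within ±1 nt per terminus (default `star_tolerance`) exists. Star support
is reported, not required (`require_star = FALSE`), since published
candidate sets include star-less entries; a flag enables the stricter
policy. When two candidates turn out to be the two strands of one duplex
(either one's detected star equals the other's mature), the more abundant
strand is reported as the mature — the standard arm-selection rule, and
necessary so sequenced star reads are not double-reported as independent
candidates.

## Target prediction

Targets are found by sliding a window of miRNA length along each
transcript and classifying each opposed base pair (miRNA antiparallel to
site): Watson-Crick, G:U wobble, or mismatch. Wobbles count as pairings,
not mismatches, by default — cleavage diagrams draw them as pairings, and
the published duplex mismatch counts are only consistent with this
convention. The budget `max_mismatch` defaults to 3, the strict reading of
"fewer than four mismatches"; `max_wobble` is unlimited unless set.
Ungapped exhaustive scanning replaces heuristic alignment: with a ≤3
mismatch budget over ~21 nt it is exact, deterministic, and free of an
external-tool dependency; no published duplex in this setting shows a gap.
Transcripts are scanned in the given orientation, with an option to add
the reverse complement for unoriented ESTs.

## RACE cleavage mapping

Clone 5' ends are mapped by exact unique occurrence of the clone's first
`anchor_len` = 20 nt in the target (RACE products are cDNA copies of the
cleaved mRNA, so exact prefix matching suffices at desk scale; ambiguous
and unmatched clones are reported, not guessed). Termini are tallied
within a 100-nt window centred on the complementary-site midpoint
(inclusive boundaries; even-length midpoint is floored). The modal
terminus is called, with ties resolved toward the coordinate pairing the
miRNA's tenth nucleotide and then toward the smaller coordinate; the
pairing index follows antiparallel geometry (the site's 3'-most position
pairs miRNA nt 1). A call is *validated* when the modal count is at least
`min_clones` = 3 and the modal fraction at least `min_fraction` = 0.3 —
thresholds chosen by this package, since the experimental convention
("at least 15 independent clones sequenced") describes effort, not a call
rule.

## What the synthetic data emulates — and what it does not

`simulate_library` generates a complete input bundle with a ground-truth
ledger: planted conserved reads (copies of known matures), novel hairpin
precursors embedded in EST-like transcripts with mature and star reads,
ncRNA fragments excised from per-class reference sequences, polyA
artifacts, and random decoys. Defaults define the study conditions used
throughout the tests: 20 conserved plants, 10 novel precursors, 5000
decoys, read lengths drawn with modes at 21 nt (13.2%) and 24 nt (44.1%)
as in deep-sequenced plant libraries, Zipf(1.2) redundant counts (deep
libraries are extremely skewed: most unique reads are sequenced a handful
of times while a few reach thousands), and a 50% star emission
probability, mirroring the roughly half-supported candidate sets that
surveys report. Mature lengths are drawn 90% 21 nt / 10% 24 nt; star
counts are drawn strictly below their mature's count, so arm selection by
abundance is well defined.

Planted precursors are `flank + mature + loop + star + flank` (arm
order swapped for 3'-arm plants) with the star equal to the reverse
complement of the mature's first L−2 nt plus a 2-nt overhang, giving the
canonical 2-nt 3' overhang on both duplex strands. Three deliberately
artificial choices keep the planted structure the *unique* energy optimum
under the permissive folding model (see above): transcript backgrounds are
poly-A, the flanks are a pure-C / pure-G clamp forming a lower stem, and
the loop is drawn from a non-self-pairing A/C alphabet. Matures are
additionally drawn subject to their constructed precursor actually
evaluating as a clean single hairpin (compositions admitting equal-energy
branched alternatives are redrawn). Real transcript context is nothing
like this: flanks are arbitrary sequence, precursors have bulged,
multi-branch neighborhoods, and a thermodynamic folder is what makes real
windows tractable. Passing recovery tests therefore demonstrates that the
pipeline's mapping, excision, criteria, star geometry and bookkeeping are
correct — not that the simplified folder would discover miRNAs in real
EST data. The generator also omits sequencing error, quality scores and
adapter read-through by design.

`simulate_race_clones` places `ceiling((1 − noise) × n)` clone ends at the
coordinate pairing the miRNA's tenth nucleotide and scatters the rest
uniformly in the 100-nt window; with the default 15 clones and 20% noise
the planted mode always dominates, and with noise 0 the modal fraction
is 1.

## Numerical and degenerate-input choices

* Energy comparisons in the folding DP use a 1e-9 tolerance so traceback
  is robust to user-supplied fractional pair energies.
* MFEI is an error for GC-free sequences (division by zero); candidate
  evaluation reports such windows as rejections (`mfei_undefined`) rather
  than erroring, since poly-A windows arise legitimately.
* Empty inputs: an empty read file fails the pipeline with a named
  preprocess error; an empty candidate set summarizes as zeros with an
  undefined (NA) star percentage; an empty reference index annotates
  everything as unannotated.
* All randomness flows through a single seed per simulated bundle;
  identical configurations produce byte-identical files, which the tests
  assert by checksum.

## Problem sizes used by the test suite

The suite exercises the full default study (10 novel plants, 20 conserved,
5000 decoys, seed 42) once, plus two noise-free 10-plant recovery runs at
other seeds, 100 generator-emitted precursor folds, 100-case folding
oracle comparisons, and 50-case target-scan equivalence checks — sizes at
which every oracle is exact and the whole suite completes in a few
minutes on one core.

## Known limitations

* The built-in folder is a pedagogical-grade energy model; for real data,
  plug in a thermodynamic folder and recalibrate `min_mfei`.
* Annotation is exact-substring only: no mismatch tolerance against ncRNA
  references, no covariance-model scanning, no genome mapping.
* Star detection searches reads within ±1 nt of the structurally inferred
  span; a mature that also maps over its own star core on the opposite
  strand can occasionally win window selection there and miss its star
  read (the duplex is still reported once, via arm arbitration).
* Target prediction is complementarity only — no conservation filtering,
  no functional annotation of targets.
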