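Package: mirseekr
Title: Discovery of Conserved and Novel Plant miRNAs from Small RNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a plant microRNA discovery
    workflow for deep-sequenced small RNA libraries from species without a
    reference genome, such as trifoliate orange. Collapses and size-selects
    reads (18-30 nt), partitions them into non-coding RNA classes by
    reference matching, identifies conserved miRNAs by perfect match to a
    known mature set, discovers novel miRNA candidates by excising and
    folding hairpin precursor windows from transcript (EST) sequences under
    MFEI-style stem-loop criteria with miRNA* support detection, predicts
    targets by ungapped G:U-wobble-aware complementarity, and maps
    miRNA-guided cleavage sites from 5'-RACE clones. Includes a synthetic
    library generator with a ground-truth ledger for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
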